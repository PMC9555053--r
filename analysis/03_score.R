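#!/usr/bin/env Rscript
# Enrichment scoring: per-replicate ES, replicate means, fitness and
# phenotype classes, plus per-position summaries; then compare estimated
# ES against the simulation ground truth.

source(file.path("analysis", "00_common.R"))

counts <- read_tsv_meta(file.path(res_dir, "counts_recovered.tsv"))
n_gen <- generations(14, 1.4, 20.2)
cat(sprintf("selection growth: %d generations (14 h, 1.4 h lag, 20.2 min doubling)\n",
            n_gen))
scores <- score_library(counts, min_unselected_reads = 20,
                        n_generations = n_gen)
write_tsv_meta(scores, file.path(res_dir, "scores.tsv"),
               list(stage = "score", n_generations = n_gen))

cat(sprintf("scored %d of %d variants (unselected-read cutoff 20)\n",
            sum(!is.na(scores$es_mean)), nrow(scores)))
print(table(scores$phenotype, useNA = "ifany"))
cat(sprintf("inactive fraction among scored: %.2f\n",
            mean(scores$phenotype[!is.na(scores$phenotype)] == "inactive")))

truth <- jsonlite::read_json(file.path(res_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$variants
tr <- merge(scores, truth[, c("variant_id", "true_survival")],
            by = "variant_id")
ok <- !is.na(tr$es_mean) & tr$es_mean > 0 & tr$true_survival > 0
cat(sprintf("log-ES vs log-true-survival Pearson r: %.3f (n = %d)\n",
            cor(log(tr$es_mean[ok]), log(tr$true_survival[ok])), sum(ok)))

ps <- position_class_fractions(scores)
write_tsv_meta(ps, file.path(res_dir, "position_summary.tsv"),
               list(stage = "score"))
cat(sprintf("%d of %d positions have >10 scored mutants\n",
            sum(!ps$excluded), nrow(ps)))
cd <- avg_pairwise_codon_delta(scores)
write_tsv_meta(cd, file.path(res_dir, "codon_delta.tsv"),
               list(stage = "score"))
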