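#!/usr/bin/env Rscript
# Simulate the NNK saturation library: enumerate variants, assign
# ground-truth survivals, draw selected/unselected counts, emit paired
# FASTQ.

source(file.path("analysis", "00_common.R"))

variants <- enumerate_nnk_variants(study_spec)
cat(sprintf("library: %d NNK variants over %d positions (%s)\n",
            nrow(variants), length(study_spec$mutagenized_positions),
            paste(names(table(variants$class)), table(variants$class),
                  sep = "=", collapse = ", ")))
cat(sprintf("expected NNK-borne WT fraction: %.4f; with 7.3%% template carryover: %.4f\n",
            expected_wt_fraction(study_spec, 0),
            expected_wt_fraction(study_spec, 0.073)))

lib <- assign_true_effects(variants, study_model, study_usage,
                           wt_fraction = 0.10)
counts <- simulate_counts(lib, study_sim)
write_ground_truth(lib, file.path(res_dir, "ground_truth.json"))
write_tsv_meta(counts, file.path(res_dir, "counts_simulated.tsv"),
               list(stage = "simulate", seed = study_sim$seed))

mf <- emit_fastq(lib, study_spec, counts, study_sim,
                 file.path(res_dir, "fastq"))
write_tsv_meta(mf, file.path(res_dir, "fastq_manifest.tsv"),
               list(stage = "simulate"))
cat(sprintf("wrote %d read pairs across %d FASTQ file pairs\n",
            sum(mf$n_reads), nrow(mf)))
cat(sprintf("true survivals span %.2g - %.2g\n",
            min(lib$variants$true_survival),
            max(lib$variants$true_survival)))
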