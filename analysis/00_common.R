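# Shared study definition for the analysis scripts.
#
# A 72-codon toy operonic gene with all 71 non-start codons saturated by
# NNK mutagenesis, the last two codons doubling as the downstream gene's
# RBS — the library geometry of a single-codon saturation screen of an
# antitoxin in its operon. Ground-truth survival follows the log-linear
# codon-optimality model (survival ~ RCU^2 with lognormal noise), ~10% WT
# pool mass, three replicates at 10^5 usable reads each.

suppressMessages(library(operonDMS))

res_dir <- file.path("results")
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

# WT codons drawn with probability proportional to genomic usage, giving a
# frequent-codon-rich gene: most NNK substitutions then introduce rarer
# codons, the situation that makes such a screen mutation-sensitive.
study_gene <- local({
  u <- load_usage_table()
  sense <- setdiff(names(u$fraction)[u$amino_acid != "*"], "ATG")
  set.seed(2020)
  paste0("ATG", paste(sample(sense, 71, replace = TRUE,
                             prob = u$fraction[sense]), collapse = ""))
})

study_spec <- operon_spec("toy_antitoxin", study_gene,
                          mutagenized_positions = 2:72,
                          rbs_region = c(70, 71))

study_model <- effect_model(baseline_survival = 1, rcu_coefficient = 2,
                            noise_sd = 1.2, seed = 2021)

study_sim <- sim_config(depth_per_replicate = 1e5, n_replicates = 3,
                        q_score_profile = 35, sequencing_error_rate = 0,
                        seed = 2022)

study_usage <- load_usage_table()
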