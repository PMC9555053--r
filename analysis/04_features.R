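#!/usr/bin/env Rscript
# Codon-optimality features for every variant: RCU, relative tRNA
# abundance, relative GC, base changes, relative stalling, relative CAI.
# The tRNA and stalling defaults are synthetic stand-in tables (see the
# files' headers); swap in measured tables for real analyses.

source(file.path("analysis", "00_common.R"))

variants <- enumerate_nnk_variants(study_spec)
feats <- variant_features(variants, study_spec, study_usage,
                          trna = load_trna_table(),
                          stall = load_stall_table())
write_tsv_meta(feats, file.path(res_dir, "features.tsv"),
               list(stage = "features",
                    usage_source = study_usage$source))
cat(sprintf("features for %d variants (%d nonsense flagged)\n",
            nrow(feats), sum(feats$nonsense)))
w <- cai_weights(study_usage)
cat(sprintf("WT gene CAI (genomic-usage weights): %.3f; single-codon relative CAI range: %.3f - %.3f\n",
            cai(study_spec$coding_sequence, w),
            min(feats$rel_cai, na.rm = TRUE),
            max(feats$rel_cai, na.rm = TRUE)))
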