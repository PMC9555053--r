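#!/usr/bin/env Rscript
# Anti-Shine-Dalgarno hybridization: (a) 10-window scans around mutated
# codons for synonymous variants (internal pause-site creation), and
# (b) predicted RBS strength of the downstream gene for variants at the
# RBS-overlapping codons.

source(file.path("analysis", "00_common.R"))

variants <- enumerate_nnk_variants(study_spec)
gene <- study_spec$coding_sequence

syn <- variants[variants$class == "synonymous" &
                variants$position >= 4 & variants$position <= 69, ]
scan <- lapply(seq_len(nrow(syn)), function(i)
  asd_scan(gene, syn$position[i], syn$wt_codon[i], syn$mut_codon[i]))
syn_tab <- tibble::tibble(variant_id = syn$variant_id,
                          mean_ddg = round(vapply(scan, `[[`, numeric(1),
                                                  "mean_ddg"), 1))
write_tsv_meta(syn_tab, file.path(res_dir, "asd_scan_synonymous.tsv"),
               list(stage = "sd_scan", asd = "CCUCCUAU", window = 8,
                    n_windows = 10))
cat(sprintf("scanned %d synonymous variants; mean ddG range %.1f to %.1f kcal/mol\n",
            nrow(syn_tab), min(syn_tab$mean_ddg), max(syn_tab$mean_ddg)))

rbs <- study_spec$rbs_region
rbs_nt <- c(max(1, 3 * (rbs[1] - 1) + 1 - 5),
            min(nchar(gene), 3 * rbs[2] + 5))
at_rbs <- variants[variants$position %in% rbs[1]:rbs[2] &
                   variants$class != "wt_identical", ]
dg <- vapply(seq_len(nrow(at_rbs)), function(i)
  rbs_strength(gene, rbs_nt, list(position = at_rbs$position[i],
                                  mut_codon = at_rbs$mut_codon[i])),
  numeric(1))
rbs_tab <- tibble::tibble(variant_id = at_rbs$variant_id,
                          dg_bind = round(dg, 1))
write_tsv_meta(rbs_tab, file.path(res_dir, "rbs_strength.tsv"),
               list(stage = "sd_scan"))
dg_wt <- rbs_strength(gene, rbs_nt)
cat(sprintf("WT RBS dG_bind %.1f kcal/mol; %d RBS variants, %d bind more strongly than WT\n",
            dg_wt, nrow(rbs_tab), sum(rbs_tab$dg_bind < round(dg_wt, 1))))
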