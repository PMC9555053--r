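test_that("duplex energies sum stacks plus initiation on a toy table", {
  # two-entry table: hand-score a 4-bp perfect duplex
  toy <- nn_params(stack_table = data.frame(
    top = c("GG", "GC"), bottom = c("CC", "CG"), dg = c(-3, -3.4)),
    init = 4, gu_stack = -0.5)
  # window GGGC pairs CCCG: stacks GG/CC, GG/CC, GC/CG = -3 -3 -3.4, +4 init
  expect_equal(duplex_dg("GGGCAAAA", asd = "GCCC", params = toy),
               -3 - 3 - 3.4 + 4)
})

test_that("the perfect aSD complement is the model minimum", {
  pars <- load_sd_params()
  perfect <- duplex_dg("AUAGGAGG")
  # hand sum over the seven Watson-Crick stacks of AUAGGAGG/CCUCCUAU
  stacks <- c("AU/UA", "UA/AU", "AG/UC", "GG/CC", "GA/CU", "AG/UC",
              "GG/CC")
  expect_equal(perfect, sum(pars$stacks[stacks]) + pars$init)
  # every single-mismatch window is weaker (less negative)
  w <- strsplit("AUAGGAGG", "")[[1]]
  for (i in 1:8) {
    for (b in setdiff(c("A", "C", "G", "U"), w[i])) {
      mutw <- w; mutw[i] <- b
      expect_gte(duplex_dg(paste(mutw, collapse = "")), perfect)
    }
  }
})

test_that("windows without a 2-nt complementary stretch score zero", {
  expect_equal(duplex_dg("AAAAAAAA"), 0)  # A cannot pair the aSD's C/U run
  expect_error(duplex_dg("AAAA"), "8 nt")
})

test_that("the codon scan evaluates ten windows and is null for WT", {
  g <- toy_gene(30)
  pos <- 15L
  wt <- substr(g, 3 * (pos - 1) + 1, 3 * pos)
  # WT-vs-WT comparison is exactly zero everywhere
  null_scan <- asd_scan(g, pos, wt, wt)
  expect_equal(nrow(null_scan$windows), 10)
  expect_true(all(null_scan$windows$ddg == 0))
  expect_equal(null_scan$mean_ddg, 0)
  # window starts bracket the codon: codon_start - 7 .. codon_start + 2
  cs <- 3 * (pos - 1) + 1
  expect_equal(null_scan$windows$window_start, seq(cs - 7, cs + 2))
  # translation invariance: shifting the frame leaves energies unchanged
  shifted <- asd_scan(paste0("GGGG", g), pos, wt, wt, cds_offset = 4)
  expect_equal(shifted$windows$dg_wt, null_scan$windows$dg_wt)
  # a mutation creating an internal SD-like AGG run strengthens pairing
  # (mean ddG < 0) when the surrounding context pairs weakly
  weak <- paste0("ATG", strrep("AAA", 29))
  scan_agg <- asd_scan(weak, 15L, "AAA", "AGG")
  expect_lt(scan_agg$mean_ddg, 0)
  # insufficient flank raises
  expect_error(asd_scan(g, 1L, substr(g, 1, 3), "AAA"), "flank")
})

test_that("RBS strength ranks consensus above the suboptimal operon RBS", {
  # embed the WT CcdB RBS (AGGGAC) and its consensus counterpart (AGGAGG)
  flank <- "CCACCA"
  wt_region <- paste0(flank, "AGGGAC", flank)
  cons_region <- paste0(flank, "AGGAGG", flank)
  dg_wt <- rbs_strength(wt_region, c(1, nchar(wt_region)))
  dg_cons <- rbs_strength(cons_region, c(1, nchar(cons_region)))
  expect_lt(dg_cons, dg_wt)  # consensus binds the aSD more strongly
  # codons 21-22 (GAC AGG) sit inside an 8-nt RBS window
  gene <- paste0("ATG", strrep("GCA", 19), "GACAGGGAC")
  rbs_nt <- c(59, 66)
  dg_wt <- rbs_strength(gene, rbs_nt)
  # re-installing the WT codon leaves dG unchanged
  expect_equal(rbs_strength(gene, rbs_nt,
                            variant = list(position = 21, mut_codon = "GAC")),
               dg_wt)
  # a consensus-creating mutation (yields AGGAGG in-window) binds at least
  # as strongly
  expect_lte(rbs_strength(gene, rbs_nt,
                          variant = list(position = 21, mut_codon = "AGG")),
             dg_wt)
  # variant must intersect the RBS window
  expect_error(rbs_strength(gene, rbs_nt,
                            variant = list(position = 2, mut_codon = "AAA")),
               "outside")
})

test_that("a toy RBS window is hand-scored against the packaged table", {
  pars <- load_sd_params()
  # GGAGGU vs aSD: best 8-nt window is the region itself padded
  region <- "AAGGAGGU"
  dg <- duplex_dg(region)
  # pairs GGAGGU against CCUCCUAU offsets; verify it is at least as strong
  # as the explicit 5-stack AGGAGG alignment
  stacks <- c("AG/UC", "GG/CC", "GA/CU", "AG/UC", "GG/CC")
  expect_lte(dg, sum(pars$stacks[stacks]) + pars$init)
})
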