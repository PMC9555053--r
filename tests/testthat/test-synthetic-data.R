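test_that("NNK enumeration yields 32 codons per position and one stop", {
  spec1 <- operon_spec("g", "ATGGAA", 2)
  v1 <- enumerate_nnk_variants(spec1)
  expect_equal(nrow(v1), 32)
  expect_setequal(unique(nchar(v1$mut_codon)), 3)

  # 71 mutagenized positions give the full 2272-variant library
  spec71 <- toy_spec(72)
  expect_equal(nrow(enumerate_nnk_variants(spec71)), 2272)

  # TAG is the only NNK stop codon; it is flagged nonsense everywhere
  stops <- v1[v1$mut_aa == "*", ]
  expect_equal(stops$mut_codon, "TAG")
  expect_equal(stops$class, "nonsense")

  # classes are mutually exclusive and exhaustive
  expect_true(all(v1$class %in% c("synonymous", "nonsynonymous",
                                  "nonsense", "wt_identical")))
  expect_error(operon_spec("g", "ATGGAA", 5), "out of range")
})

test_that("expected WT fraction follows the NNK pool arithmetic", {
  # all WT codons K-ending: every pool regenerates WT once in 32
  spec_k <- operon_spec("g", "ATGAAGGCGTTG", 2:4)
  expect_equal(expected_wt_fraction(spec_k, 0), 1 / 32)
  # no WT codon K-ending: NNK cannot regenerate WT
  spec_n <- operon_spec("g", "ATGAAAGCCTTA", 2:4)
  expect_equal(expected_wt_fraction(spec_n, 0), 0)
  # 2 of 4 positions K-ending
  spec_half <- operon_spec("g", "ATGAAGGCGTTACCA", 2:5)
  expect_equal(expected_wt_fraction(spec_half, 0), 2 / (4 * 32))
  # carryover adds linearly on the remaining mass
  expect_equal(expected_wt_fraction(spec_k, 0.073),
               0.073 + 0.927 / 32)
})

test_that("true effects follow the log-linear model deterministically", {
  spec <- toy_spec(6)
  v <- enumerate_nnk_variants(spec)
  usage <- load_usage_table()

  # neutral model: every survival equals baseline
  m0 <- effect_model(baseline_survival = 2, rcu_coefficient = 0,
                     noise_sd = 0)
  lib0 <- assign_true_effects(v, m0, usage)
  expect_true(all(lib0$variants$true_survival == 2))

  # rcu_coefficient 1, no noise: survival strictly increasing in RCU
  m1 <- effect_model(rcu_coefficient = 1, noise_sd = 0)
  lib1 <- assign_true_effects(v, m1, usage)
  nonn <- lib1$variants[lib1$variants$class != "nonsense", ]
  expect_equal(order(nonn$true_survival), order(nonn$rcu))

  # seeded determinism with noise
  mn <- effect_model(rcu_coefficient = 1, noise_sd = 0.5, seed = 42)
  expect_identical(assign_true_effects(v, mn, usage)$variants$true_survival,
                   assign_true_effects(v, mn, usage)$variants$true_survival)

  # region offsets act multiplicatively on the targeted interval
  mr <- effect_model(region_effects = data.frame(from = 2, to = 3,
                                                 offset = log(0.1)))
  libr <- assign_true_effects(v, mr, usage)
  inr <- libr$variants$position <= 3
  expect_equal(unique(libr$variants$true_survival[inr]), 0.1)
  expect_equal(unique(libr$variants$true_survival[!inr]), 1)

  # proportions form a simplex including WT
  expect_equal(sum(lib1$unselected_proportions), 1, tolerance = 1e-9)
  expect_equal(unname(lib1$unselected_proportions["WT"]), 0.1)
})

test_that("simulated counts conserve depth and respect selection", {
  st <- toy_study(n_codons = 6, depth = 5000, n_replicates = 2)
  sums <- tapply(st$counts$count,
                 paste(st$counts$condition, st$counts$replicate), sum)
  expect_true(all(sums == 5000))
  expect_error(simulate_counts(st$lib, sim_config(depth_per_replicate = 0)),
               "positive|depth")

  # neutral library: ES approximately 1 for well-covered variants
  spec <- toy_spec(6)
  v <- enumerate_nnk_variants(spec)
  lib <- assign_true_effects(v, effect_model(), load_usage_table())
  cfg <- sim_config(depth_per_replicate = 1e5, n_replicates = 3, seed = 2)
  sc <- score_library(simulate_counts(lib, cfg))
  es <- sc$es_mean[!is.na(sc$es_mean)]
  expect_gt(length(es), 100)
  expect_lt(abs(mean(es) - 1), 0.02)
  # a known 10x-depleted variant recovers its survival within 3 SE
  lib2 <- lib
  i <- which(lib2$variants$class == "nonsynonymous")[1]
  lib2$variants$true_survival[i] <- 0.1
  sc2 <- score_library(simulate_counts(lib2, cfg))
  est <- sc2$es_mean[sc2$variant_id == lib2$variants$variant_id[i]]
  pre_n <- 3e5 * lib2$unselected_proportions[[lib2$variants$variant_id[i]]]
  se <- 0.1 / sqrt(pre_n * 0.1)  # binomial error on the selected counts
  expect_lt(abs(est - 0.1), 3 * se)
})

test_that("FASTQ emission is tagged, seeded, and exactly invertible", {
  st <- toy_study(n_codons = 6, depth = 800, n_replicates = 2)
  d1 <- withr::local_tempdir()
  mf <- emit_fastq(st$lib, st$spec, st$counts, st$cfg, d1)
  expect_equal(nrow(mf), 4)  # 2 conditions x 2 replicates

  # every read starts with its condition's 6-base tag
  for (i in seq_len(nrow(mf))) {
    rd <- read_fastq(mf$r1[i])
    expect_true(all(substr(rd$sequence, 1, 6) ==
                    st$cfg$mid_tags[[mf$condition[i]]]))
  }

  # byte-identical reproducibility from the same config + seed
  d2 <- withr::local_tempdir()
  emit_fastq(st$lib, st$spec, st$counts, st$cfg, d2)
  expect_identical(unname(tools::md5sum(mf$r1)),
                   unname(tools::md5sum(file.path(d2, basename(mf$r1)))))

  # error rate 0: processing reproduces the simulated counts exactly
  proc <- process_fastq(mf[, c("replicate", "r1", "r2")],
                        st$spec$coding_sequence, st$cfg$mid_tags,
                        min_length = 10)
  sim <- st$counts[st$counts$count > 0, ]
  m <- merge(sim, proc$counts,
             by = c("variant_id", "condition", "replicate"))
  expect_equal(nrow(m), nrow(sim))
  expect_equal(m$count.x, m$count.y)
})
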