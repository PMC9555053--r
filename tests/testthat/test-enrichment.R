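test_that("survival score is a ratio of normalized read fractions", {
  expect_equal(survival_score(100, 100, 1000, 1000), 1)
  expect_equal(survival_score(100, 10, 1000, 1000), 0.1)
  # scale invariance: multiplying post counts and totals together cancels
  expect_equal(survival_score(100, 10 * 10, 1000, 1000 * 10), 0.1)
  expect_true(is.na(survival_score(0, 5, 1000, 1000)))
  expect_error(survival_score(10, 5, 0, 1000), "positive")
})

test_that("ES normalizes to WT and applies the unselected-read cutoff", {
  # WT against itself is exactly 1
  expect_equal(es_seq(1000, 1000, 1000, 1000), 1)
  expect_equal(es_seq(100, 10, 1000, 1000), 0.1)
  # below 20 unselected reads the replicate is missing
  expect_true(is.na(es_seq(19, 10, 1000, 1000)))
  expect_false(is.na(es_seq(20, 10, 1000, 1000)))
  # complete depletion is a measured 0, not missing
  expect_equal(es_seq(50, 0, 1000, 1000), 0)
  expect_error(es_seq(10, 5, 0, 1000), "WT")
  # invariance under uniform rescaling of a condition's counts
  expect_equal(es_seq(100, 10, 1000, 1000),
               es_seq(100, 10 * 7, 1000, 1000 * 7))
})

test_that("replicate averaging uses only passing replicates", {
  expect_equal(average_es(c(0.2, 0.4, NA)), 0.3)
  expect_equal(average_es(c(1, 1, 1)), 1)
  expect_true(is.na(average_es(c(NA_real_, NA_real_))))
})

test_that("generations come from lag-corrected growth time, floored", {
  expect_equal(generations(14, 1.4, 20.2), 37L)
  expect_equal(generations(2, 0, 30), 4L)
  expect_equal(generations(1.4, 1.4, 20.2), 0L)
  expect_error(generations(1, 2, 20), "lag")
})

test_that("fitness conversion matches the printed medians", {
  expect_equal(fitness(1, 37), 1)
  expect_equal(fitness(1, 5), 1)
  expect_equal(round(fitness(0.03, 37), 1), 0.9)
  expect_equal(round(fitness(0.004, 37), 2), 0.86)
  expect_equal(fitness(0, 37), 0)
  # strictly increasing in ES
  es <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(fitness(es, 37)) > 0))
  expect_error(fitness(-0.1, 37), "nonnegative")
})

test_that("phenotype bins partition the nonnegative axis as stated", {
  expect_equal(classify_phenotype(0.1), "inactive")
  expect_equal(classify_phenotype(0.5), "marginal")
  expect_equal(classify_phenotype(0.7), "active")
  expect_equal(classify_phenotype(1.5), "active")
  expect_equal(classify_phenotype(2.0), "hyperactive")
  expect_true(is.na(classify_phenotype(NA)))
  # no gaps or overlaps over a dense grid
  grid <- seq(0, 3, by = 1e-3)
  cls <- classify_phenotype(grid)
  expect_false(anyNA(cls))
  expect_equal(sum(rle(cls)$lengths), length(grid))
  expect_equal(rle(cls)$values,
               c("inactive", "marginal", "active", "hyperactive"))
})

test_that("position summaries apply the >10 mutant rule and sum to one", {
  rec <- tibble::tibble(
    position = c(rep(2L, 11), rep(3L, 10)),
    mut_codon = "AAA",
    es_mean = c(rep(0.05, 11), rep(1, 10)),
    phenotype = c(rep("inactive", 11), rep("active", 10)))
  ps <- position_class_fractions(rec)
  expect_equal(ps$frac_inactive[ps$position == 2], 1)
  expect_false(ps$excluded[ps$position == 2])   # 11 > 10
  expect_true(ps$excluded[ps$position == 3])    # exactly 10 is excluded
  fr <- ps[, c("frac_inactive", "frac_marginal", "frac_active",
               "frac_hyperactive")]
  expect_equal(unname(rowSums(fr)), rep(1, nrow(ps)))
})

test_that("average pairwise codon delta pools same-amino-acid pairs", {
  # Leu codons CTT/CTC with ES 0.5 and 0.1 -> single pair, delta 0.4
  rec2 <- tibble::tibble(position = 2L, mut_codon = c("CTT", "CTC"),
                         es_mean = c(0.5, 0.1))
  expect_equal(avg_pairwise_codon_delta(rec2)$avg_delta_es, 0.4)
  # three codons of one amino acid: (0.1 + 0.3 + 0.2) / 3
  rec3 <- tibble::tibble(position = 2L, mut_codon = c("CTT", "CTC", "CTA"),
                         es_mean = c(0.1, 0.2, 0.4))
  expect_equal(avg_pairwise_codon_delta(rec3)$avg_delta_es, 0.2)
  # identical ES values give 0; stop codons never pair
  rec0 <- tibble::tibble(position = 2L,
                         mut_codon = c("CTT", "CTC", "TAG"),
                         es_mean = c(0.3, 0.3, 0.0))
  out <- avg_pairwise_codon_delta(rec0)
  expect_equal(out$avg_delta_es, 0)
  expect_equal(out$n_pairs, 1L)
})

test_that("library scoring recovers known survivals on simulated data", {
  st <- toy_study()  # 512 variants, depth 1e5, 3 replicates
  sc <- score_library(st$counts)
  tr <- merge(sc, st$lib$variants[, c("variant_id", "true_survival")],
              by = "variant_id")
  ok <- !is.na(tr$es_mean) & tr$es_mean > 0
  expect_gt(sum(ok), 400)
  # median absolute relative error of the ES estimate vs truth <= 10%
  expect_lte(median(abs(tr$es_mean[ok] / tr$true_survival[ok] - 1)), 0.10)
})
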