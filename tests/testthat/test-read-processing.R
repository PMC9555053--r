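test_that("demultiplexing assigns by exact 6-base tag and conserves reads", {
  mid <- c(unselected = "ACGTAC", selected = "TGCATG")
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("ACGTACGGGAAA", "TGCATGCCCTTT", "AAAAAAGGGAAA"),
    quality = strrep("I", 12))
  out <- demultiplex(reads, mid)
  expect_equal(out$condition, c("unselected", "selected", "unassigned"))
  expect_equal(out$sequence[1], "GGGAAA")       # tag stripped
  expect_equal(out$sequence[3], "AAAAAAGGGAAA") # unassigned untouched
  expect_equal(nrow(out), nrow(reads))
  expect_error(demultiplex(reads, c(a = "ACGTAC", b = "ACGTAC")),
               "duplicate")
})

test_that("quality/length filter applies the cutoffs", {
  q <- function(qv, n) rawToChar(as.raw(rep(33L + qv, n)))
  reads <- tibble::tibble(
    sequence = c(strrep("A", 80), strrep("A", 74), strrep("A", 80)),
    quality = c(q(30, 80), q(40, 74), q(19, 80)))
  out <- quality_filter(reads, q_cutoff = 20, min_length = 75)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE))
  expect_equal(out$filter_reason, c(NA, "length", "quality"))
  # mean-vs-per-base convention: a read mixing Q10 and Q40 passes the mean
  mix <- tibble::tibble(sequence = strrep("A", 80),
                        quality = paste0(q(10, 40), q(40, 40)))
  expect_true(quality_filter(mix, min_length = 75)$keep)
  expect_false(quality_filter(mix, min_length = 75, per_base = TRUE)$keep)
})

test_that("pair merging requires an identical overlap", {
  g <- toy_gene(20)                      # 60 nt template
  fwd <- substr(g, 1, 40)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, 11, 60))))
  m <- merge_pair(fwd, rev)              # 30-base identical overlap
  expect_equal(m$merged, g)
  # one mismatch inside the overlap discards the pair
  fwd_bad <- fwd
  substr(fwd_bad, 25, 25) <- if (substr(fwd_bad, 25, 25) == "A") "C" else "A"
  expect_true(is.na(merge_pair(fwd_bad, rev)$merged))
  # overlap below the minimum is rejected as no_overlap
  m2 <- merge_pair(substr(g, 1, 12), "AAAAAAAAAAAA")
  expect_equal(m2$reason, "no_overlap")
})

test_that("local alignment matches scoring expectations and the DP oracle", {
  ref <- toy_gene(12)
  al <- align_read(ref, ref)
  expect_equal(al$score, 5 * nchar(ref))
  expect_equal(al$n_indel, 0)

  # one internal deletion produces a gapped alignment
  del <- paste0(substr(ref, 1, 14), substr(ref, 16, nchar(ref)))
  expect_gt(align_read(del, ref)$n_indel, 0)

  set.seed(11)
  for (k in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1),
                      replace = TRUE), collapse = "")
    sc <- align_read(a, b)$score
    expect_equal(sc, sw_oracle(a, b))
    expect_gte(sc, 0)
    expect_lte(sc, 5 * min(nchar(a), nchar(b)))
  }
  expect_error(align_read("", ref), "empty")
})

test_that("variant calling enforces the single-codon full-coverage rules", {
  ref <- toy_gene(10)
  # single codon change
  mut <- ref
  substr(mut, 13, 15) <- if (substr(ref, 13, 15) == "AAA") "CCC" else "AAA"
  cv <- call_variant(mut, ref)
  expect_equal(cv$status, "variant")
  expect_equal(cv$position, 5)
  expect_equal(cv$wt_codon, substr(ref, 13, 15))
  # identical read is WT
  expect_equal(call_variant(ref, ref)$status, "wt")
  # two changed codons rejected
  mut2 <- mut
  substr(mut2, 22, 22) <- if (substr(mut2, 22, 22) == "G") "T" else "G"
  expect_equal(call_variant(mut2, ref)$reason, "multi_codon")
  # reads not covering the full gene rejected
  expect_equal(call_variant(substr(ref, 1, 27), ref)$reason,
               "partial_coverage")
  # indel-containing reads rejected
  ins <- paste0(substr(ref, 1, 15), "ACGT", substr(ref, 16, nchar(ref)))
  expect_equal(call_variant(ins, ref)$reason, "indel")
  # ambiguous base inside the changed codon rejected
  mutn <- ref
  substr(mutn, 13, 15) <- "ANA"
  expect_equal(call_variant(mutn, ref)$reason, "ambiguous_base")
  # a terminal-codon mutation is still called (no local-alignment clipping)
  mutl <- ref
  substr(mutl, nchar(ref) - 2, nchar(ref)) <- "CCG"
  cvl <- call_variant(mutl, ref)
  expect_equal(cvl$status, "variant")
  expect_equal(cvl$position, 10)
})

test_that("tallying excludes rejected reads from counts and totals", {
  calls <- tibble::tibble(
    status = c(rep("variant", 7), "wt", "wt", "reject"),
    position = c(rep(3L, 7), NA, NA, NA),
    wt_codon = c(rep("AAA", 7), NA, NA, NA),
    mut_codon = c(rep("CCC", 7), NA, NA, NA))
  tab <- tally_counts(calls, "unselected", 1)
  expect_equal(tab$count[tab$variant_id == "WT"], 2L)
  expect_equal(tab$count[tab$variant_id == "p003_CCC"], 7L)
  expect_equal(sum(tab$count), 9L)
})

test_that("Phred error probabilities match the Q35 reciprocals", {
  p35 <- phred_error_prob(35)
  expect_equal(1 / p35$per_base, 3162, tolerance = 1e-3)
  expect_equal(1 / p35$per_substitution, 12649, tolerance = 1e-3)
  expect_equal(phred_error_prob(20)$per_base, 0.01)
  expect_equal(phred_error_prob(0)$per_base, 1)
  expect_equal(phred_error_prob(35, "third")$per_substitution,
               10^(-3.5) / 3)
  expect_error(phred_error_prob(-1), "nonnegative")
})

test_that("minimum-read threshold reproduces 13/14 and is monotone", {
  expect_equal(min_reads_threshold(1e5, 35, 0.05, "poisson_gt"), 13)
  expect_equal(min_reads_threshold(1e5, 35, 0.05, "poisson_ge"), 14)
  expect_equal(min_reads_threshold(1e5, 35, 0.05, "normal"), 13)
  # agrees with direct tail summation
  expect_equal(min_reads_threshold(1e5, 35), min_reads_oracle(1e5, 35))
  # non-increasing in q, non-decreasing in total reads
  th_q <- vapply(25:40, function(q) min_reads_threshold(1e5, q), integer(1))
  expect_true(all(diff(th_q) <= 0))
  th_n <- vapply(c(1e4, 5e4, 1e5, 5e5), function(n)
    min_reads_threshold(n, 35), integer(1))
  expect_true(all(diff(th_n) >= 0))
})

test_that("sequencing errors stay within the Poisson artifact bound", {
  # with substitution errors at rate e, any specific spurious single-base
  # variant should stay below the Poisson(D * e / 4) 99.9% quantile
  st <- toy_study(n_codons = 6, depth = 4000, n_replicates = 1,
                  rcu_coefficient = 0, noise_sd = 0)
  cfg <- sim_config(depth_per_replicate = 4000, n_replicates = 1,
                    sequencing_error_rate = 0.002, seed = 5)
  d <- withr::local_tempdir()
  mf <- emit_fastq(st$lib, st$spec, st$counts, cfg, d)
  proc <- process_fastq(mf[, c("replicate", "r1", "r2")],
                        st$spec$coding_sequence, cfg$mid_tags,
                        min_length = 10)
  known <- c("WT", st$lib$variants$variant_id)
  spurious <- proc$counts[!(proc$counts$variant_id %in% known), ]
  nbc <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                spurious$wt_codon, spurious$mut_codon)
  single_base <- spurious[nbc == 1, ]
  # effective per-read error after pair merging is at most the per-base rate
  bound <- qpois(0.999, 4000 * 0.002 / 4)
  expect_true(nrow(single_base) == 0 ||
                mean(single_base$count <= bound) >= 0.99)
})
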