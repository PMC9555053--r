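#' Survival score of a mutant
#'
#' Ratio of the mutant's read fraction after selection to its read fraction
#' before selection, where each total covers all single mutants plus WT
#' reads identified in the sample.
#'
#' @param mut_pre,mut_post mutant read counts before/after selection.
#' @param total_pre,total_post sample totals before/after selection (> 0).
#' @return survival score; `NA` when `mut_pre` is 0 (undefined).
#' @export
survival_score <- function(mut_pre, mut_post, total_pre, total_post) {
  if (any(total_pre <= 0) || any(total_post <= 0))
    stop("sample totals must be positive")
  ifelse(mut_pre > 0,
         (mut_post / total_post) / (mut_pre / total_pre),
         NA_real_)
}

#' Enrichment score (ES) of a mutant relative to wild type
#'
#' Ratio of mutant to WT survival scores; the sample totals cancel, so
#' `ES = (mut_post / wt_post) / (mut_pre / wt_pre)`. WT has ES 1 by
#' construction. A replicate contributes a score only when the mutant has at
#' least `min_unselected_reads` reads in the unselected (resistant-strain)
#' sample; below that the value is `NA` (missing). Zero selected reads with
#' a passing unselected count give ES 0, a real measurement of complete
#' depletion, not a missing value.
#'
#' @param mut_pre,mut_post mutant counts before/after selection (vectors).
#' @param wt_pre,wt_post WT counts before/after selection (> 0).
#' @param min_unselected_reads unselected-read cutoff (default 20).
#' @return ES values (vector), `NA` where the cutoff fails.
#' @export
es_seq <- function(mut_pre, mut_post, wt_pre, wt_post,
                   min_unselected_reads = 20) {
  if (any(wt_pre <= 0) || any(wt_post <= 0))
    stop("WT counts must be positive in both conditions")
  es <- (mut_post / wt_post) / (mut_pre / wt_pre)
  es[mut_pre < min_unselected_reads] <- NA_real_
  es
}

#' Average ES over replicates
#'
#' Arithmetic mean over the replicates that passed the unselected-read
#' cutoff; missing when no replicate passed.
#'
#' @param es_per_replicate numeric vector, `NA` for failing replicates.
#' @return mean ES or `NA`.
#' @export
average_es <- function(es_per_replicate) {
  if (all(is.na(es_per_replicate))) return(NA_real_)
  mean(es_per_replicate, na.rm = TRUE)
}

#' Number of generations during selection growth
#'
#' `floor((total_time - lag_time) / doubling_time)`: 14 h of growth on
#' plates with a 1.4 h lag and a 20.2 min doubling time give 37 generations.
#'
#' @param total_time_h total growth time in hours.
#' @param lag_time_h lag time in hours.
#' @param doubling_time_min doubling time in minutes.
#' @return integer number of generations.
#' @export
generations <- function(total_time_h = 14, lag_time_h = 1.4,
                        doubling_time_min = 20.2) {
  stopifnot(doubling_time_min > 0)
  eff <- (total_time_h - lag_time_h) * 60
  if (eff < 0) stop("lag time exceeds total growth time")
  as.integer(floor(eff / doubling_time_min))
}

#' Convert enrichment score to per-generation fitness
#'
#' `w = ES^(1 / generations)`; `w(0)` is defined as 0, and `w(1) = 1` for
#' any number of generations.
#'
#' @param es enrichment score(s), >= 0.
#' @param n_generations number of generations (>= 1).
#' @return fitness value(s).
#' @export
fitness <- function(es, n_generations = generations()) {
  if (any(es < 0, na.rm = TRUE)) stop("ES must be nonnegative")
  stopifnot(n_generations >= 1)
  es^(1 / n_generations)
}

#' Classify a mutant phenotype from its mean ES
#'
#' Bins: inactive (ES <= 0.1), marginal (0.1 < ES < 0.7), active
#' (0.7 <= ES <= 1.5), hyperactive (ES > 1.5). The bins partition the
#' nonnegative axis with closed boundaries as stated.
#'
#' @param es_mean mean ES value(s); `NA` gives `NA`.
#' @return character vector of classes.
#' @export
classify_phenotype <- function(es_mean) {
  ifelse(is.na(es_mean), NA_character_,
  ifelse(es_mean <= 0.1, "inactive",
  ifelse(es_mean < 0.7, "marginal",
  ifelse(es_mean <= 1.5, "active", "hyperactive"))))
}

#' Score a full library from a count table
#'
#' Computes per-replicate ES for every variant, the replicate-averaged ES,
#' fitness, and phenotype class. WT read counts normalize each replicate;
#' replicates failing the unselected-read cutoff are excluded from the
#' average and counted in `n_replicates_used`.
#'
#' @param counts count-table tibble (`variant_id`, `position`, `wt_codon`,
#'   `mut_codon`, `condition`, `replicate`, `count`) with a `WT` row per
#'   column, as produced by [simulate_counts()] or [process_fastq()].
#' @param min_unselected_reads unselected-read cutoff (default 20).
#' @param n_generations generations used for the fitness conversion.
#' @return tibble: one row per variant with `es_rep<k>` columns, `es_mean`,
#'   `n_replicates_used`, `fitness_w`, `phenotype`.
#' @export
score_library <- function(counts, min_unselected_reads = 20,
                          n_generations = generations()) {
  reps <- sort(unique(counts$replicate))
  ids <- unique(counts$variant_id[counts$variant_id != "WT"])
  meta <- counts[match(ids, counts$variant_id),
                 c("variant_id", "position", "wt_codon", "mut_codon")]
  es_mat <- matrix(NA_real_, nrow = length(ids), ncol = length(reps),
                   dimnames = list(ids, paste0("es_rep", reps)))
  for (j in seq_along(reps)) {
    r <- reps[j]
    get_counts <- function(cond) {
      cc <- counts[counts$replicate == r & counts$condition == cond, ]
      setNames(cc$count, cc$variant_id)
    }
    pre <- get_counts("unselected"); post <- get_counts("selected")
    if (is.na(pre["WT"]) || is.na(post["WT"]) ||
        pre[["WT"]] <= 0 || post[["WT"]] <= 0)
      stop("WT counts missing or zero in replicate ", r)
    mp <- ifelse(is.na(pre[ids]), 0L, pre[ids])
    ms <- ifelse(is.na(post[ids]), 0L, post[ids])
    es_mat[, j] <- es_seq(mp, ms, pre[["WT"]], post[["WT"]],
                          min_unselected_reads)
  }
  es_mean <- apply(es_mat, 1L, average_es)
  out <- tibble::as_tibble(cbind(meta, as.data.frame(es_mat)))
  out$es_mean <- unname(es_mean)
  out$n_replicates_used <- unname(rowSums(!is.na(es_mat)))
  out$fitness_w <- unname(fitness(es_mean, n_generations))
  out$phenotype <- unname(classify_phenotype(es_mean))
  out
}

#' Per-position phenotype-class fractions
#'
#' Fractions of scored mutants in each phenotype class at each codon
#' position; positions with `min_mutants` or fewer scored mutants are
#' flagged excluded (the reporting convention keeps only positions with
#' data for more than 10 mutants).
#'
#' @param records scored tibble from [score_library()].
#' @param min_mutants exclusion threshold (default 10; strict `>` applies).
#' @return tibble: `position`, `n_mutants`, one fraction column per class,
#'   `excluded`.
#' @export
position_class_fractions <- function(records, min_mutants = 10) {
  rec <- records[!is.na(records$phenotype), , drop = FALSE]
  classes <- c("inactive", "marginal", "active", "hyperactive")
  pos <- sort(unique(rec$position))
  rows <- lapply(pos, function(p) {
    ph <- rec$phenotype[rec$position == p]
    n <- length(ph)
    fr <- as.list(vapply(classes, function(cl) mean(ph == cl), numeric(1)))
    names(fr) <- paste0("frac_", classes)
    c(list(position = p, n_mutants = n), fr,
      list(excluded = n <= min_mutants))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

#' Average pairwise ES difference among codons at a position
#'
#' For one position, all unordered pairs of scored codons encoding the same
#' mutant amino acid are formed (pooled across amino acids; stop codons
#' excluded); the statistic is the mean of |ES_a - ES_b| over all such
#' pairs: `sum |ES_a - ES_b| / C(n, 2)` summed per amino-acid family.
#' Positions with no eligible pair get `NA`.
#'
#' @param records scored tibble (needs `position`, `mut_codon`, `es_mean`).
#' @return tibble: `position`, `n_pairs`, `avg_delta_es`.
#' @export
avg_pairwise_codon_delta <- function(records) {
  rec <- records[!is.na(records$es_mean), , drop = FALSE]
  rec$mut_aa <- translate_codons(rec$mut_codon)
  rec <- rec[rec$mut_aa != "*", , drop = FALSE]
  pos <- sort(unique(rec$position))
  rows <- lapply(pos, function(p) {
    sub <- rec[rec$position == p, , drop = FALSE]
    deltas <- numeric()
    for (aa in unique(sub$mut_aa)) {
      es <- sub$es_mean[sub$mut_aa == aa]
      if (length(es) >= 2) {
        prs <- combn(es, 2)
        deltas <- c(deltas, abs(prs[1, ] - prs[2, ]))
      }
    }
    data.frame(position = p, n_pairs = length(deltas),
               avg_delta_es = if (length(deltas)) mean(deltas) else NA_real_)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
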