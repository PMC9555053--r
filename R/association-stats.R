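#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. By default the exact null distribution is
#' used for small tie-free samples (combined n <= 12) and the normal
#' approximation with tie and continuity correction otherwise, mirroring
#' standard rank-sum practice. P-values come from [stats::wilcox.test()];
#' the U statistic reported is the number of (x, y) pairs with x > y plus
#' half the ties.
#'
#' @param x,y numeric samples (each nonempty).
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @return list with `u`, `p_value`, `method`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
                  auto = (length(x) + length(y) <= 12) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties)
    stop("exact method not available with ties")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_tie_corrected",
       n_x = length(x), n_y = length(y))
}

#' Split scored variants into active and inactive classes
#'
#' Inactive means mean ES at or below the threshold (default 0.1, the
#' inactive-phenotype cutoff); active means above it. Unscored variants are
#' dropped.
#'
#' @param records tibble with an `es_mean` column.
#' @param threshold ES cutoff (default 0.1).
#' @return list of two tibbles, `active` and `inactive`.
#' @export
split_by_activity <- function(records, threshold = 0.1) {
  rec <- records[!is.na(records$es_mean), , drop = FALSE]
  list(active = rec[rec$es_mean > threshold, , drop = FALSE],
       inactive = rec[rec$es_mean <= threshold, , drop = FALSE])
}

#' Box-plot summary statistics
#'
#' Median, quartiles (linear interpolation), IQR, whiskers at the most
#' extreme data points inside `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`, and the
#' values outside the whiskers as outliers.
#'
#' @param values numeric vector (>= 1 non-missing value).
#' @return list with `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = max(min(values), lo_fence),
       whisker_high = min(max(values), hi_fence),
       outliers = values[values < lo_fence | values > hi_fence],
       n = length(values))
}

#' Feature-by-feature association of sequence features with activity
#'
#' For each feature column, splits variants into active/inactive classes by
#' the ES threshold, removes variants missing that feature, and tests
#' whether the two feature distributions differ by a two-sided Mann-Whitney
#' test. No multiple-testing correction is applied to the calls (per-feature
#' p-values are reported as-is); a Bonferroni column is included for
#' transparency.
#'
#' @param records tibble joining scores (`es_mean`) with feature columns.
#' @param features character vector of feature column names (default: the
#'   standard six plus `dg_bind` when present).
#' @param threshold ES cutoff for the activity split.
#' @return tibble: one row per feature with group sizes, group medians, U,
#'   p, Bonferroni-adjusted p, method; features absent for all variants are
#'   flagged via `n_active`/`n_inactive` = 0 and `NA` statistics.
#' @export
feature_association_report <- function(records,
                                       features = intersect(
                                         c("rcu", "rel_trna", "rel_gc",
                                           "n_base_changes", "rel_stall",
                                           "rel_cai", "dg_bind"),
                                         names(records)),
                                       threshold = 0.1) {
  groups <- split_by_activity(records, threshold)
  rows <- lapply(features, function(f) {
    a <- groups$active[[f]]; a <- a[!is.na(a)]
    i <- groups$inactive[[f]]; i <- i[!is.na(i)]
    if (!length(a) || !length(i))
      return(tibble::tibble(feature = f, n_active = length(a),
                            n_inactive = length(i),
                            median_active = NA_real_,
                            median_inactive = NA_real_,
                            u = NA_real_, p_value = NA_real_,
                            method = NA_character_))
    mw <- mann_whitney_u(i, a)
    tibble::tibble(feature = f, n_active = length(a),
                   n_inactive = length(i),
                   median_active = median(a), median_inactive = median(i),
                   u = mw$u, p_value = mw$p_value, method = mw$method)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * sum(!is.na(out$p_value)))
  out
}
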