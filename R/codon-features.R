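#' Build a codon usage table
#'
#' Wraps a codon -> usage-fraction mapping (any consistent scale: fractions,
#' per-mille, counts) with the derived per-amino-acid maxima needed for
#' relative codon usage and CAI weights.
#'
#' @param df data.frame with columns `codon` and `fraction` (an
#'   `amino_acid` column is derived from the standard genetic code if
#'   absent).
#' @param source label recording where the numbers come from.
#' @return object of class `usage_table`.
#' @export
usage_table <- function(df, source = "user") {
  stopifnot(all(c("codon", "fraction") %in% names(df)))
  df$codon <- toupper(df$codon)
  if (anyDuplicated(df$codon)) stop("duplicate codon in usage table")
  if (any(df$fraction <= 0)) stop("usage fractions must be positive")
  if (is.null(df$amino_acid)) df$amino_acid <- translate_codons(df$codon)
  fam_max <- tapply(df$fraction, df$amino_acid, max)
  structure(list(fraction = setNames(df$fraction, df$codon),
                 amino_acid = setNames(df$amino_acid, df$codon),
                 family_max = fam_max,
                 source = source),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat("<usage_table>", length(x$fraction), "codons, source:", x$source, "\n")
  invisible(x)
}

lookup_codon <- function(tab, codon, what) {
  v <- tab[[what]][toupper(codon)]
  if (anyNA(v))
    stop("codon(s) missing from table: ",
         paste(codon[is.na(v)], collapse = ", "))
  v
}

#' Relative codon usage (RCU) of a mutation
#'
#' Usage fraction of the mutant codon normalized to the most common codon
#' of the mutant amino acid, divided by the same quantity for the WT codon:
#' `(CUF_mut / maxCUF_mutAA) / (CUF_wt / maxCUF_wtAA)`. RCU is 1 for a
#' silent non-change and whenever both codons are their families' most
#' common codons; values below 1 mean the mutation introduced a relatively
#' rarer codon.
#'
#' @param wt_codon,mut_codon 3-base codons (non-stop).
#' @param table a [usage_table()].
#' @return RCU value.
#' @export
rcu <- function(wt_codon, mut_codon, table) {
  stopifnot(inherits(table, "usage_table"))
  aas <- translate_codons(c(wt_codon, mut_codon))
  if (any(aas == "*"))
    stop("nonsense: RCU undefined for stop codons (", wt_codon, "->",
         mut_codon, ")")
  f <- lookup_codon(table, c(wt_codon, mut_codon), "fraction")
  m <- table$family_max[aas]
  unname((f[2] / m[2]) / (f[1] / m[1]))
}

#' Build a tRNA abundance table
#'
#' Maps each decoded codon to the abundance of its decoding tRNA(s); where
#' several tRNA species decode one codon their abundances are summed.
#'
#' @param df data.frame with columns `codon` and `abundance`.
#' @param source label.
#' @return object of class `trna_table`.
#' @export
trna_table <- function(df, source = "user") {
  stopifnot(all(c("codon", "abundance") %in% names(df)))
  df$codon <- toupper(df$codon)
  ab <- tapply(df$abundance, df$codon, sum)
  if (any(ab <= 0)) stop("tRNA abundances must be positive")
  structure(list(abundance = ab, source = source), class = "trna_table")
}

#' Relative tRNA abundance of a mutation
#'
#' Abundance of the tRNA decoding the mutant codon divided by that decoding
#' the WT codon.
#'
#' @param wt_codon,mut_codon 3-base codons.
#' @param table a [trna_table()].
#' @return ratio of abundances.
#' @export
relative_trna <- function(wt_codon, mut_codon, table) {
  stopifnot(inherits(table, "trna_table"))
  ab <- lookup_codon(table, c(wt_codon, mut_codon), "abundance")
  unname(ab[2] / ab[1])
}

#' Relative GC content and base changes of a codon substitution
#'
#' Relative GC is the fractional GC content of the mutant codon divided by
#' that of the WT codon (`NA` when the WT codon has no G/C); base changes
#' is the Hamming distance between the codons (0-3).
#'
#' @param wt_codon,mut_codon 3-base codons.
#' @return list with `rel_gc` and `n_base_changes`.
#' @export
codon_basic_features <- function(wt_codon, mut_codon) {
  stopifnot(nchar(wt_codon) == 3L, nchar(mut_codon) == 3L)
  gw <- gc_fraction(wt_codon); gm <- gc_fraction(mut_codon)
  list(rel_gc = if (gw > 0) gm / gw else NA_real_,
       n_base_changes = hamming_codon(wt_codon, mut_codon))
}

#' Build a ribosome stalling table
#'
#' Per-codon average ribosome pause values at the A site.
#'
#' @param df data.frame with columns `codon` and `pause`.
#' @param source label.
#' @return object of class `stall_table`.
#' @export
stall_table <- function(df, source = "user") {
  stopifnot(all(c("codon", "pause") %in% names(df)))
  df$codon <- toupper(df$codon)
  if (anyDuplicated(df$codon)) stop("duplicate codon in stall table")
  if (any(df$pause <= 0)) stop("pause values must be positive")
  structure(list(pause = setNames(df$pause, df$codon), source = source),
            class = "stall_table")
}

#' Relative ribosome stalling of a mutation
#'
#' Mutant codon pause value divided by the WT codon pause value; values
#' above 1 predict stronger ribosome pausing at the mutated codon.
#'
#' @param wt_codon,mut_codon 3-base codons.
#' @param table a [stall_table()].
#' @return pause ratio.
#' @export
relative_stalling <- function(wt_codon, mut_codon, table) {
  stopifnot(inherits(table, "stall_table"))
  p <- lookup_codon(table, c(wt_codon, mut_codon), "pause")
  unname(p[2] / p[1])
}

#' Relative-adaptiveness weights for CAI
#'
#' Sharp-Li weights: each codon's usage divided by the maximum usage within
#' its synonymous family, ideally computed from a highly-expressed reference
#' gene set.
#'
#' @param table a [usage_table()].
#' @return named numeric vector of weights in (0, 1].
#' @export
cai_weights <- function(table) {
  stopifnot(inherits(table, "usage_table"))
  w <- table$fraction / table$family_max[table$amino_acid]
  setNames(as.numeric(w), names(table$fraction))
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative-adaptiveness weights of the sequence's
#' codons, excluding single-codon families (Met, Trp) and stop codons per
#' the standard Sharp-Li convention.
#'
#' @param coding_sequence DNA string, length divisible by 3.
#' @param weights named weight vector from [cai_weights()].
#' @return CAI in (0, 1].
#' @export
cai <- function(coding_sequence, weights) {
  codons <- split_codons(coding_sequence)
  aas <- translate_codons(codons)
  keep <- !(aas %in% c("M", "W", "*"))
  codons <- codons[keep]
  if (!length(codons)) stop("no CAI-eligible codons in sequence")
  w <- weights[codons]
  if (anyNA(w) || any(w <= 0))
    stop("zero or missing weight for codon(s): ",
         paste(unique(codons[is.na(w) | w <= 0]), collapse = ", "))
  exp(mean(log(w)))
}

#' Relative CAI of a mutant sequence
#'
#' `CAI(mutant) / CAI(WT)`; for a single-codon substitution in an n-codon
#' gene this equals `(w_mut / w_wt)^(1/n)` over the eligible codons.
#'
#' @param mut_seq,wt_seq coding sequences.
#' @param weights named weight vector from [cai_weights()].
#' @return CAI ratio.
#' @export
relative_cai <- function(mut_seq, wt_seq, weights) {
  cai(mut_seq, weights) / cai(wt_seq, weights)
}

#' Compute the full feature set for every variant of a library
#'
#' One row per variant with RCU, relative tRNA abundance, relative GC, base
#' changes, relative stalling and relative CAI. Nonsense variants are
#' flagged and get `NA` for the translation-related features (RCU, tRNA,
#' CAI) rather than a silent gap.
#'
#' @param variants tibble from [enumerate_nnk_variants()] (wt_identical rows
#'   are skipped).
#' @param spec the [operon_spec()] (needed for sequence-level CAI).
#' @param usage a [usage_table()].
#' @param trna a [trna_table()] or NULL to skip.
#' @param stall a [stall_table()] or NULL to skip.
#' @param cai_ref_weights weights for CAI, default derived from `usage`
#'   (use weights from a highly-expressed gene set when available).
#' @return tibble keyed by `variant_id` with feature columns and a
#'   `nonsense` flag.
#' @export
variant_features <- function(variants, spec, usage, trna = NULL,
                             stall = NULL,
                             cai_ref_weights = cai_weights(usage)) {
  v <- variants[variants$class != "wt_identical", , drop = FALSE]
  n <- nrow(v)
  wt_cai <- cai(spec$coding_sequence, cai_ref_weights)
  out <- tibble::tibble(variant_id = v$variant_id, position = v$position,
                        wt_codon = v$wt_codon, mut_codon = v$mut_codon,
                        class = v$class,
                        nonsense = v$class == "nonsense",
                        rcu = NA_real_, rel_trna = NA_real_,
                        rel_gc = NA_real_, n_base_changes = NA_integer_,
                        rel_stall = NA_real_, rel_cai = NA_real_)
  for (i in seq_len(n)) {
    wt <- v$wt_codon[i]; mut <- v$mut_codon[i]
    basic <- codon_basic_features(wt, mut)
    out$rel_gc[i] <- basic$rel_gc
    out$n_base_changes[i] <- basic$n_base_changes
    if (!is.null(stall)) out$rel_stall[i] <- relative_stalling(wt, mut, stall)
    if (!out$nonsense[i]) {
      out$rcu[i] <- rcu(wt, mut, usage)
      if (!is.null(trna)) out$rel_trna[i] <- relative_trna(wt, mut, trna)
      mut_seq <- mutate_codon_in_gene(spec$coding_sequence, v$position[i], mut)
      out$rel_cai[i] <- cai(mut_seq, cai_ref_weights) / wt_cai
    }
  }
  out
}

read_codon_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the packaged default feature tables
#'
#' `load_usage_table()` returns E. coli K-12 codon usage (standard public
#' per-mille values). `load_trna_table()` and `load_stall_table()` return
#' synthetic stand-in tables (generated, not measured — see the files'
#' comments); supply your own measured tables for real analyses.
#' `load_sd_params()` returns the nearest-neighbour duplex parameters used
#' by the SD-hybridization module.
#'
#' @return the corresponding table object.
#' @export
load_usage_table <- function() {
  usage_table(read_codon_tsv(system.file("extdata",
    "ecoli_k12_codon_usage.tsv", package = "operonDMS", mustWork = TRUE)),
    source = "E. coli K-12 codon usage (per-mille)")
}

#' @rdname load_usage_table
#' @export
load_trna_table <- function() {
  trna_table(read_codon_tsv(system.file("extdata",
    "trna_abundance_synthetic.tsv", package = "operonDMS", mustWork = TRUE)),
    source = "synthetic stand-in (monotone in codon usage)")
}

#' @rdname load_usage_table
#' @export
load_stall_table <- function() {
  stall_table(read_codon_tsv(system.file("extdata",
    "ribosome_stalling_synthetic.tsv", package = "operonDMS",
    mustWork = TRUE)),
    source = "synthetic stand-in")
}
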