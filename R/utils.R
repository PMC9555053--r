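#' @importFrom stats ppois pnorm quantile rlnorm rmultinom runif median setNames
#' @importFrom utils head combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Standard genetic code lookup
#'
#' Named character vector mapping each of the 64 DNA codons to its
#' one-letter amino acid, with `"*"` for stop codons.
#' @keywords internal
genetic_code <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

translate_codons <- function(codons) {
  unname(genetic_code()[toupper(codons)])
}

#' Split a coding sequence into codons
#' @param seq DNA string, length divisible by 3.
#' @return character vector of 3-base codons.
#' @keywords internal
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("coding sequence length must be divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

gc_fraction <- function(codon) {
  b <- strsplit(toupper(codon), "")[[1]]
  mean(b %in% c("G", "C"))
}

hamming_codon <- function(a, b) {
  sum(strsplit(toupper(a), "")[[1]] != strsplit(toupper(b), "")[[1]])
}

is_dna <- function(x) grepl("^[ACGT]+$", toupper(x))

#' Derive a stage seed from a global seed
#'
#' Fixed-offset fan-out keeps stages reproducible yet independent while
#' staying inside the 32-bit integer range.
#' @keywords internal
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000L * offset) %% .Machine$integer.max)
}
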