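RNA_PAIRS <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE,
               GU = TRUE, UG = TRUE)

is_rna_pair <- function(a, b) isTRUE(RNA_PAIRS[paste0(a, b)])

#' Nearest-neighbour RNA/RNA duplex parameters
#'
#' Transparent duplex energy model used for anti-Shine-Dalgarno scans:
#' Watson-Crick stack free energies (kcal/mol, 37 C, after Xia et al. 1998),
#' a flat simplified value for any stack involving a G.U wobble pair, and a
#' duplex initiation penalty. Mismatches are not paired at all: only
#' contiguous complementary (WC or G.U) runs contribute.
#'
#' @param stack_table data.frame with columns `top` (5'->3' dinucleotide of
#'   strand 1), `bottom` (3'->5' dinucleotide of strand 2) and `dg`
#'   (kcal/mol); default is the packaged table.
#' @param init duplex initiation penalty (kcal/mol).
#' @param gu_stack energy assigned to any complementary stack not listed in
#'   `stack_table` (i.e. involving a G.U pair).
#' @return object of class `nn_params`.
#' @export
nn_params <- function(stack_table = NULL, init = 4.09, gu_stack = -0.5) {
  if (is.null(stack_table))
    stack_table <- read_codon_tsv(system.file("extdata", "sd_nn_params.tsv",
      package = "operonDMS", mustWork = TRUE))
  stopifnot(all(c("top", "bottom", "dg") %in% names(stack_table)),
            all(is.finite(stack_table$dg)))
  structure(list(
    stacks = setNames(stack_table$dg,
                      paste(toupper(stack_table$top),
                            toupper(stack_table$bottom), sep = "/")),
    init = init, gu_stack = gu_stack), class = "nn_params")
}

#' @rdname load_usage_table
#' @export
load_sd_params <- function() nn_params()

min_subarray_sum <- function(x) {
  best <- cur <- x[1]
  for (v in x[-1]) {
    cur <- min(v, cur + v)
    best <- min(best, cur)
  }
  best
}

#' Duplex free energy of an mRNA window against the anti-SD sequence
#'
#' Minimum free energy of the antiparallel duplex between an 8-nt mRNA
#' window and the 16S rRNA anti-Shine-Dalgarno sequence under the
#' nearest-neighbour model, over all registrations. Only contiguous
#' complementary runs pair; the best run (sub-run energies considered) plus
#' the initiation penalty gives the duplex energy. Windows that cannot form
#' a stable duplex (no complementary stretch of 2+, or net positive energy)
#' score 0. More negative means stronger aSD pairing.
#'
#' @param window 8-nt sequence (RNA; DNA is transcribed automatically).
#' @param asd anti-SD sequence, 5'->3' (default `CCUCCUAU`).
#' @param params an [nn_params()].
#' @param energy_fn optional plug-in replacing the packaged model: a
#'   function `(window, asd) -> dG` (e.g. a ViennaRNA duplex wrapper).
#' @return duplex free energy in kcal/mol (<= 0).
#' @export
duplex_dg <- function(window, asd = "CCUCCUAU", params = load_sd_params(),
                      energy_fn = NULL) {
  window <- dna_to_rna(window)
  asd <- dna_to_rna(asd)
  if (nchar(window) != 8L) stop("window must be 8 nt, got ", nchar(window))
  if (!is.null(energy_fn)) return(energy_fn(window, asd))
  w <- strsplit(window, "")[[1]]
  ar <- rev(strsplit(asd, "")[[1]])  # aSD read 3'->5'
  lw <- length(w); la <- length(ar)
  best <- 0
  for (s in seq(-(la - 1L), lw - 1L)) {
    i <- seq_len(lw)
    j <- i - s
    ok <- j >= 1L & j <= la
    i <- i[ok]; j <- j[ok]
    if (length(i) < 2L) next
    paired <- vapply(seq_along(i),
                     function(k) is_rna_pair(w[i[k]], ar[j[k]]), logical(1))
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= 2L)) {
      idx <- seq(starts[ri], ends[ri])
      stacks <- vapply(idx[-length(idx)], function(k) {
        key <- paste0(w[i[k]], w[i[k + 1L]], "/", ar[j[k]], ar[j[k + 1L]])
        val <- params$stacks[key]
        if (is.na(val)) params$gu_stack else unname(val)
      }, numeric(1))
      best <- min(best, min_subarray_sum(stacks) + params$init)
    }
  }
  min(0, best)
}

#' Anti-SD window scan around a mutated codon
#'
#' Evaluates the ten 8-nt windows whose spans overlap the mutated codon
#' (window starts from 7 nt upstream of the codon start to 2 nt into the
#' codon) on both the WT and the mutant transcript, returning per-window
#' duplex energies against the anti-SD sequence and the mean energy
#' difference. A positive mean ddG means the mutation weakened internal
#' aSD-like pairing; negative means it created stronger (pause-prone)
#' pairing.
#'
#' @param transcript mRNA (or DNA) sequence containing the coding sequence.
#' @param codon_position 1-based codon index within the coding sequence.
#' @param wt_codon,mut_codon the reference and mutant codons.
#' @param n_windows number of windows (default 10, fixed by the window/codon
#'   geometry: 10 starts place an 8-nt window over a 3-nt codon).
#' @param cds_offset nucleotides preceding the coding sequence in
#'   `transcript`.
#' @param asd,params,energy_fn see [duplex_dg()].
#' @return list with `windows` (tibble `window_start`, `dg_wt`, `dg_mut`,
#'   `ddg`) and `mean_ddg`.
#' @export
asd_scan <- function(transcript, codon_position, wt_codon, mut_codon,
                     n_windows = 10L, cds_offset = 0L, asd = "CCUCCUAU",
                     params = load_sd_params(), energy_fn = NULL) {
  transcript <- dna_to_rna(transcript)
  wt_codon <- dna_to_rna(wt_codon); mut_codon <- dna_to_rna(mut_codon)
  codon_start <- cds_offset + 3L * (codon_position - 1L) + 1L
  found <- substr(transcript, codon_start, codon_start + 2L)
  if (found != wt_codon)
    stop("transcript has ", found, " at codon ", codon_position,
         ", expected ", wt_codon)
  starts <- seq(codon_start - 7L, codon_start + 2L, length.out = n_windows)
  starts <- as.integer(starts)
  if (starts[1] < 1L || max(starts) + 7L > nchar(transcript))
    stop("insufficient flanking context for codon ", codon_position)
  mut_tx <- paste0(substr(transcript, 1L, codon_start - 1L), mut_codon,
                   substr(transcript, codon_start + 3L, nchar(transcript)))
  dg_wt <- vapply(starts, function(st)
    duplex_dg(substr(transcript, st, st + 7L), asd, params, energy_fn),
    numeric(1))
  dg_mut <- vapply(starts, function(st)
    duplex_dg(substr(mut_tx, st, st + 7L), asd, params, energy_fn),
    numeric(1))
  windows <- tibble::tibble(window_start = starts, dg_wt = dg_wt,
                            dg_mut = dg_mut, ddg = dg_mut - dg_wt)
  list(windows = windows, mean_ddg = mean(windows$ddg))
}

#' Predicted RBS strength of a (mutant) transcript region
#'
#' Free energy of binding to the anti-SD sequence for the best 8-nt window
#' inside the ribosome-binding-site region of the downstream gene (in the
#' studied operon, codons 70-71 of the upstream gene). More negative
#' predicts stronger translation initiation of the downstream gene.
#'
#' @param transcript mRNA (or DNA) sequence.
#' @param rbs_window length-2 integer vector: nucleotide interval (closed,
#'   1-based on `transcript`) holding the RBS; must span >= 8 nt.
#' @param variant optional list `(position, mut_codon)` (codon coordinates
#'   within the coding sequence) applied before scoring; the mutated codon
#'   must intersect `rbs_window`.
#' @param cds_offset nucleotides preceding the coding sequence.
#' @param asd,params,energy_fn see [duplex_dg()].
#' @return dG_bind in kcal/mol.
#' @export
rbs_strength <- function(transcript, rbs_window, variant = NULL,
                         cds_offset = 0L, asd = "CCUCCUAU",
                         params = load_sd_params(), energy_fn = NULL) {
  transcript <- dna_to_rna(transcript)
  stopifnot(length(rbs_window) == 2L, rbs_window[1] <= rbs_window[2])
  if (rbs_window[1] < 1L || rbs_window[2] > nchar(transcript))
    stop("rbs_window outside the transcript")
  if (rbs_window[2] - rbs_window[1] + 1L < 8L)
    stop("rbs_window must span at least 8 nt")
  if (!is.null(variant)) {
    codon_start <- cds_offset + 3L * (variant$position - 1L) + 1L
    if (codon_start + 2L < rbs_window[1] || codon_start > rbs_window[2])
      stop("variant codon lies outside the RBS window")
    transcript <- paste0(substr(transcript, 1L, codon_start - 1L),
                         dna_to_rna(variant$mut_codon),
                         substr(transcript, codon_start + 3L,
                                nchar(transcript)))
  }
  starts <- seq(rbs_window[1], rbs_window[2] - 7L)
  min(vapply(starts, function(st)
    duplex_dg(substr(transcript, st, st + 7L), asd, params, energy_fn),
    numeric(1)))
}
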