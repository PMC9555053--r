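#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = character()))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(id = names(x),
                 sequence = as.character(x),
                 quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Demultiplex reads by 6-base MID tag
#'
#' A read is assigned to the condition whose tag exactly matches its first
#' six bases; the tag (and its quality) is stripped. Anything else lands in
#' the `unassigned` bin and is retained for accounting, never silently
#' dropped.
#'
#' @param reads tibble from [read_fastq()].
#' @param mid_map named character vector condition -> 6-base tag.
#' @return the input tibble with a `condition` column (`"unassigned"` for
#'   unmatched reads) and tags stripped from assigned reads.
#' @export
demultiplex <- function(reads, mid_map) {
  stopifnot(all(nchar(mid_map) == 6L), !is.null(names(mid_map)))
  if (anyDuplicated(mid_map)) stop("duplicate MID tag in map")
  tag <- substr(reads$sequence, 1L, 6L)
  cond <- names(mid_map)[match(tag, mid_map)]
  hit <- !is.na(cond)
  reads$condition <- ifelse(hit, cond, "unassigned")
  reads$sequence[hit] <- substr(reads$sequence[hit], 7L,
                                nchar(reads$sequence[hit]))
  reads$quality[hit] <- substr(reads$quality[hit], 7L,
                               nchar(reads$quality[hit]))
  reads
}

mean_phred <- function(quality) {
  uq <- unique(quality)
  m <- vapply(uq, function(q) {
    if (!nchar(q)) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1))
  unname(m[match(quality, uq)])
}

#' Quality/length filter for reads
#'
#' Drops reads shorter than `min_length` or with mean Phred quality below
#' `q_cutoff` (set `per_base = TRUE` to require every base to clear the
#' cutoff instead of the mean).
#'
#' @param reads tibble with `sequence` and `quality` columns.
#' @param q_cutoff Phred cutoff (default 20).
#' @param min_length minimum read length (default 75).
#' @param per_base if TRUE, apply the cutoff per base rather than to the
#'   mean quality.
#' @return tibble with logical `keep` and character `filter_reason`
#'   (`NA`, `"length"` or `"quality"`) columns added.
#' @export
quality_filter <- function(reads, q_cutoff = 20, min_length = 75,
                           per_base = FALSE) {
  len_ok <- nchar(reads$sequence) >= min_length & nchar(reads$sequence) > 0
  if (per_base) {
    uq <- unique(reads$quality)
    minq <- vapply(uq, function(q)
      if (nchar(q)) min(utf8ToInt(q) - 33L) else 0, numeric(1))
    q_ok <- unname(minq[match(reads$quality, uq)]) >= q_cutoff
  } else {
    q_ok <- mean_phred(reads$quality) >= q_cutoff
  }
  reads$keep <- len_ok & q_ok
  reads$filter_reason <- ifelse(!len_ok, "length",
                         ifelse(!q_ok, "quality", NA_character_))
  reads
}

#' Merge a forward/reverse read pair requiring an identical overlap
#'
#' The reverse read is reverse-complemented, then the maximal exact
#' suffix(forward)/prefix(reverse-complement) overlap of at least
#' `min_overlap` bases is sought. Merging succeeds only when the overlap is
#' base-identical; a near-overlap (best candidate identity >= 0.75) is
#' rejected as `mismatch`, anything else as `no_overlap`.
#'
#' @param fwd,rev forward and reverse read sequences (single strings).
#' @param min_overlap minimum overlap length (default 10).
#' @return list with `merged` (string or NA) and `reason`
#'   (NA, `"mismatch"` or `"no_overlap"`).
#' @export
merge_pair <- function(fwd, rev, min_overlap = 10L) {
  rc <- revcomp(rev)
  nf <- nchar(fwd); nr <- nchar(rc)
  best_frac <- 0
  for (o in seq(min(nf, nr), min_overlap)) {
    a <- substr(fwd, nf - o + 1L, nf)
    b <- substr(rc, 1L, o)
    if (a == b) {
      merged <- paste0(fwd, substr(rc, o + 1L, nr))
      return(list(merged = merged, reason = NA_character_))
    }
    frac <- sum(charToRaw(a) == charToRaw(b)) / o
    if (frac > best_frac) best_frac <- frac
  }
  if (min(nf, nr) < min_overlap)
    return(list(merged = NA_character_, reason = "no_overlap"))
  list(merged = NA_character_,
       reason = if (best_frac >= 0.75) "mismatch" else "no_overlap")
}

merge_pairs_vec <- function(fwd, rev, min_overlap = 10L) {
  merged <- rep(NA_character_, length(fwd))
  reason <- rep(NA_character_, length(fwd))
  rc <- if (length(rev)) revcomp(rev) else character()
  full <- nchar(fwd) == nchar(rc) & fwd == rc & nchar(fwd) >= min_overlap
  merged[full] <- fwd[full]
  todo <- which(!full)
  for (i in todo) {
    m <- merge_pair(fwd[i], rev[i], min_overlap)
    merged[i] <- m$merged
    reason[i] <- m$reason
  }
  list(merged = merged, reason = reason)
}

#' Smith-Waterman local alignment of a read against the reference
#'
#' EDNAFULL-equivalent scoring (match +5, mismatch -4) with affine gaps
#' (opening 20, extension 0.5 per gapped base), mirroring an EMBOSS
#' water run with the gap-opening penalty raised to 20.
#'
#' @param read read sequence (string).
#' @param reference reference coding sequence (string).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return list with `score`, `read_range`, `ref_range` (start/end),
#'   `n_indel` (number of gap openings), `aligned_read`, `aligned_ref`
#'   (gapped strings).
#' @export
align_read <- function(read, reference, gap_open = 20, gap_extend = 0.5) {
  if (!nchar(read) || !nchar(reference)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(reference),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  ni <- Biostrings::nindel(al)
  list(score = Biostrings::score(al),
       read_range = c(Biostrings::start(pat), Biostrings::end(pat)),
       ref_range = c(Biostrings::start(sub), Biostrings::end(sub)),
       n_indel = sum(Biostrings::insertion(ni)[, "Length"] > 0) +
                 sum(Biostrings::deletion(ni)[, "Length"] > 0),
       aligned_read = as.character(Biostrings::alignedPattern(al)),
       aligned_ref = as.character(Biostrings::alignedSubject(al)))
}

codon_diffs <- function(seq, reference) {
  a <- charToRaw(seq); b <- charToRaw(reference)
  mism <- which(a != b)
  if (!length(mism)) return(integer())
  sort(unique((mism - 1L) %/% 3L + 1L))
}

#' Call a single-codon variant from a full-coverage read
#'
#' Implements the acceptance rules for amplicon reads: reads must span the
#' entire reference; any indel, more than one differing codon, or an
#' ambiguous base inside a differing codon leads to rejection. Reads equal
#' in length to the reference are compared directly (the gap-free optimal
#' alignment under the scoring scheme — a local alignment would clip a
#' terminal-codon mutation and mis-classify the read as partial coverage);
#' other reads go through [align_read()].
#'
#' @param seq merged read sequence (string).
#' @param reference reference coding sequence (string).
#' @param gap_open,gap_extend passed to [align_read()] when needed.
#' @return list with `status` in `wt`/`variant`/`reject`; for variants,
#'   `position`, `wt_codon`, `mut_codon`; for rejects, `reason` in
#'   `indel`/`multi_codon`/`partial_coverage`/`ambiguous_base`.
#' @export
call_variant <- function(seq, reference, gap_open = 20, gap_extend = 0.5) {
  ref_len <- nchar(reference)
  if (nchar(seq) == ref_len) {
    read_part <- seq
  } else if (nchar(seq) < ref_len) {
    return(list(status = "reject", reason = "partial_coverage"))
  } else {
    al <- align_read(seq, reference, gap_open, gap_extend)
    if (al$n_indel > 0)
      return(list(status = "reject", reason = "indel"))
    if (al$ref_range[1] != 1L || al$ref_range[2] != ref_len)
      return(list(status = "reject", reason = "partial_coverage"))
    read_part <- al$aligned_read
  }
  diffs <- codon_diffs(read_part, reference)
  if (!length(diffs)) return(list(status = "wt"))
  if (length(diffs) > 1L)
    return(list(status = "reject", reason = "multi_codon"))
  pos <- diffs
  mut <- substr(read_part, 3L * (pos - 1L) + 1L, 3L * pos)
  if (grepl("[^ACGT]", mut))
    return(list(status = "reject", reason = "ambiguous_base"))
  list(status = "variant", position = pos,
       wt_codon = substr(reference, 3L * (pos - 1L) + 1L, 3L * pos),
       mut_codon = mut)
}

call_variants_unique <- function(seqs, reference, gap_open = 20,
                                 gap_extend = 0.5) {
  out <- tibble::tibble(sequence = seqs, status = NA_character_,
                        reason = NA_character_, position = NA_integer_,
                        wt_codon = NA_character_, mut_codon = NA_character_)
  for (i in seq_along(seqs)) {
    cv <- call_variant(seqs[i], reference, gap_open, gap_extend)
    out$status[i] <- cv$status
    if (cv$status == "reject") out$reason[i] <- cv$reason
    if (cv$status == "variant") {
      out$position[i] <- cv$position
      out$wt_codon[i] <- cv$wt_codon
      out$mut_codon[i] <- cv$mut_codon
    }
  }
  out
}

#' Tally variant calls into a count-table column
#'
#' Rejected reads are excluded from both the counts and the column total
#' (the total-read denominator of the survival score covers single mutants
#' and WT reads only).
#'
#' @param calls tibble with columns `status`, `position`, `wt_codon`,
#'   `mut_codon` (one row per retained read).
#' @param condition,replicate labels attached to the column.
#' @return tibble in count-table format (`variant_id`, `position`,
#'   `wt_codon`, `mut_codon`, `condition`, `replicate`, `count`), including
#'   a WT row.
#' @export
tally_counts <- function(calls, condition, replicate) {
  kept <- calls[calls$status %in% c("wt", "variant"), , drop = FALSE]
  wt_n <- sum(kept$status == "wt")
  v <- kept[kept$status == "variant", , drop = FALSE]
  if (nrow(v)) {
    key <- sprintf("p%03d_%s", v$position, v$mut_codon)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    meta <- v[match(agg$key, key), c("position", "wt_codon", "mut_codon")]
    vt <- tibble::tibble(variant_id = agg$key,
                         position = meta$position,
                         wt_codon = meta$wt_codon,
                         mut_codon = meta$mut_codon,
                         condition = condition, replicate = replicate,
                         count = as.integer(agg$Freq))
  } else {
    vt <- tibble::tibble(variant_id = character(), position = integer(),
                         wt_codon = character(), mut_codon = character(),
                         condition = character(), replicate = integer(),
                         count = integer())
  }
  rbind(tibble::tibble(variant_id = "WT", position = NA_integer_,
                       wt_codon = NA_character_, mut_codon = NA_character_,
                       condition = condition, replicate = replicate,
                       count = as.integer(wt_n)),
        vt)
}

#' Phred sequencing-error probabilities
#'
#' Per-base error `10^(-q/10)` and the probability of a specific base
#' substitution at a position. The default split assumes all four bases are
#' equally likely to be assigned in error (per-base error / 4, so Q35 gives
#' 1/3,162 and 1/12,649); `convention = "third"` divides by the three
#' non-reference bases instead.
#'
#' @param q Phred quality (>= 0).
#' @param convention `"quarter"` (default) or `"third"`.
#' @return list with `per_base` and `per_substitution`.
#' @export
phred_error_prob <- function(q, convention = c("quarter", "third")) {
  convention <- match.arg(convention)
  if (any(q < 0)) stop("Phred score must be nonnegative")
  per_base <- 10^(-q / 10)
  list(per_base = per_base,
       per_substitution = per_base / switch(convention, quarter = 4, third = 3))
}

#' Minimum read count unexplainable by sequencing error
#'
#' Under a Poisson approximation to the binomial error model, the expected
#' number of reads of a specific single-base-substitution artifact is
#' `lambda = total_reads * per-substitution error`. The threshold is the
#' smallest count k whose upper tail probability falls below `alpha`; the
#' three conventions differ in the tail: `poisson_gt` uses P(X > k) (default;
#' 100,000 reads at Q35 give 13), `poisson_ge` uses P(X >= k) (gives 14),
#' and `normal` uses a normal-approximation P(X >= k) without continuity
#' correction (gives 13).
#'
#' @param total_reads total usable reads in the sample (> 0).
#' @param q Phred quality assumed for the error model.
#' @param alpha tail probability (0 < alpha < 1).
#' @param convention one of `"poisson_gt"`, `"poisson_ge"`, `"normal"`.
#' @param error_split passed to [phred_error_prob()].
#' @return integer threshold.
#' @export
min_reads_threshold <- function(total_reads, q = 35, alpha = 0.05,
                                convention = c("poisson_gt", "poisson_ge",
                                               "normal"),
                                error_split = "quarter") {
  convention <- match.arg(convention)
  stopifnot(total_reads > 0, alpha > 0, alpha < 1)
  lambda <- total_reads * phred_error_prob(q, error_split)$per_substitution
  tail_prob <- switch(convention,
    poisson_gt = function(k) 1 - ppois(k, lambda),
    poisson_ge = function(k) 1 - ppois(k - 1, lambda),
    normal = function(k) 1 - pnorm((k - lambda) / sqrt(lambda)))
  k <- 0L
  while (tail_prob(k) >= alpha) k <- k + 1L
  k
}

#' Process paired FASTQ files into a variant count table
#'
#' Full pipeline stage: demultiplex both mates by MID tag, quality/length
#' filter (a pair is dropped if either mate fails), merge pairs requiring an
#' identical overlap, call single-codon variants against the reference, and
#' tally counts per condition and replicate. Every input read pair is
#' accounted for in exactly one bin of the rejection summary or the counts.
#'
#' @param files tibble with columns `replicate`, `r1`, `r2` (paths), e.g.
#'   the manifest returned by [emit_fastq()] (its `condition` column, if
#'   present, is ignored: condition is taken from the MID tag).
#' @param reference reference coding sequence (string).
#' @param mid_map named character vector condition -> 6-base tag.
#' @param q_cutoff,min_length,per_base see [quality_filter()].
#' @param min_overlap see [merge_pair()].
#' @param gap_open,gap_extend see [align_read()].
#' @return list with `counts` (count-table tibble over all conditions and
#'   replicates) and `rejections` (tibble `replicate`, `condition`,
#'   `reason`, `n`).
#' @export
process_fastq <- function(files, reference, mid_map,
                          q_cutoff = 20, min_length = 75, per_base = FALSE,
                          min_overlap = 10L, gap_open = 20,
                          gap_extend = 0.5) {
  reference <- toupper(reference)
  counts <- list(); rejections <- list()
  note <- function(rep, cond, reason, n) {
    if (n > 0)
      rejections[[length(rejections) + 1L]] <<-
        tibble::tibble(replicate = rep, condition = cond,
                       reason = reason, n = n)
  }
  for (i in seq_len(nrow(files))) {
    rep_i <- files$replicate[i]
    r1 <- demultiplex(read_fastq(files$r1[i]), mid_map)
    r2 <- demultiplex(read_fastq(files$r2[i]), mid_map)
    stopifnot(nrow(r1) == nrow(r2))
    if (!nrow(r1)) next
    # pair condition: both mates must agree on an assigned condition
    cond <- ifelse(r1$condition == r2$condition & r1$condition != "unassigned",
                   r1$condition, "unassigned")
    note(rep_i, "unassigned", "unassigned_tag", sum(cond == "unassigned"))
    for (cd in names(mid_map)) {
      sel <- which(cond == cd)
      if (!length(sel)) next
      f1 <- quality_filter(r1[sel, ], q_cutoff, min_length, per_base)
      f2 <- quality_filter(r2[sel, ], q_cutoff, min_length, per_base)
      pair_keep <- f1$keep & f2$keep
      why <- ifelse(!f1$keep, f1$filter_reason, f2$filter_reason)
      for (rs in c("length", "quality"))
        note(rep_i, cd, paste0("filtered_", rs),
             sum(!pair_keep & why == rs, na.rm = TRUE))
      if (!any(pair_keep)) next
      m <- merge_pairs_vec(f1$sequence[pair_keep], f2$sequence[pair_keep],
                           min_overlap)
      ok <- !is.na(m$merged)
      for (rs in c("mismatch", "no_overlap"))
        note(rep_i, cd, paste0("merge_", rs), sum(!ok & m$reason == rs,
                                                  na.rm = TRUE))
      merged <- m$merged[ok]
      if (!length(merged)) next
      useq <- unique(merged)
      calls_u <- call_variants_unique(useq, reference, gap_open, gap_extend)
      calls <- calls_u[match(merged, useq), , drop = FALSE]
      for (rs in unique(calls$reason[!is.na(calls$reason)]))
        note(rep_i, cd, rs, sum(calls$reason == rs, na.rm = TRUE))
      counts[[length(counts) + 1L]] <- tally_counts(calls, cd, rep_i)
    }
  }
  list(counts = if (length(counts)) do.call(rbind, counts) else NULL,
       rejections = if (length(rejections)) do.call(rbind, rejections)
                    else tibble::tibble(replicate = integer(),
                                        condition = character(),
                                        reason = character(), n = integer()))
}
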