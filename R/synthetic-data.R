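#' Describe an operonic gene targeted by single-codon saturation mutagenesis
#'
#' Bundles the reference coding sequence with the codon positions subjected
#' to NNK mutagenesis and (optionally) the codon interval that doubles as the
#' ribosome-binding site (RBS) of the downstream gene of the operon.
#'
#' @param gene_id character scalar naming the gene.
#' @param coding_sequence DNA string; length divisible by 3, starting with a
#'   start codon (ATG/GTG/TTG).
#' @param mutagenized_positions integer vector of 1-based codon indices to
#'   saturate (codon 1 is the start codon).
#' @param rbs_region optional length-2 integer vector, closed codon interval
#'   holding the downstream gene's RBS (e.g. codons 70-71).
#' @param amplicon_flanks character vector of length 2: upstream and
#'   downstream DNA context included in sequenced amplicons (may be empty).
#' @return An object of class `operon_spec`.
#' @export
operon_spec <- function(gene_id, coding_sequence,
                        mutagenized_positions,
                        rbs_region = NULL,
                        amplicon_flanks = c("", "")) {
  coding_sequence <- toupper(coding_sequence)
  if (!is_dna(coding_sequence)) stop("coding_sequence must be A/C/G/T only")
  if (nchar(coding_sequence) %% 3L != 0L)
    stop("coding_sequence length must be divisible by 3")
  if (!substr(coding_sequence, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    stop("coding_sequence must begin with a start codon")
  n_codons <- nchar(coding_sequence) / 3L
  mutagenized_positions <- as.integer(mutagenized_positions)
  bad <- mutagenized_positions[mutagenized_positions < 1L |
                               mutagenized_positions > n_codons]
  if (length(bad))
    stop("mutagenized position(s) out of range: ", paste(bad, collapse = ", "))
  if (!is.null(rbs_region)) {
    rbs_region <- as.integer(rbs_region)
    stopifnot(length(rbs_region) == 2L, rbs_region[1] <= rbs_region[2])
    if (rbs_region[1] < 1L || rbs_region[2] > n_codons)
      stop("rbs_region outside the gene")
  }
  structure(list(gene_id = gene_id,
                 coding_sequence = coding_sequence,
                 n_codons = n_codons,
                 mutagenized_positions = sort(unique(mutagenized_positions)),
                 rbs_region = rbs_region,
                 amplicon_flanks = toupper(amplicon_flanks)),
            class = "operon_spec")
}

#' @export
print.operon_spec <- function(x, ...) {
  cat("<operon_spec>", x$gene_id, "-", x$n_codons, "codons,",
      length(x$mutagenized_positions), "mutagenized positions\n")
  invisible(x)
}

#' All 32 NNK codons
#'
#' N = A/C/G/T at positions 1-2, K = G/T at position 3. The set encodes all
#' 20 amino acids and exactly one stop codon (TAG).
#' @return character vector of 32 codons.
#' @export
nnk_codons <- function() {
  n <- c("A", "C", "G", "T")
  as.vector(outer(outer(n, n, paste0), c("G", "T"), paste0))
}

#' Enumerate the NNK single-codon variants of a library
#'
#' One row per (mutagenized position, NNK codon), classified relative to the
#' reference codon as synonymous, nonsynonymous, nonsense, or wt_identical
#' (the NNK codon equals the reference codon, so the construct is
#' indistinguishable from wild type).
#'
#' @param spec an [operon_spec()].
#' @return tibble with columns `variant_id`, `position`, `wt_codon`,
#'   `mut_codon`, `wt_aa`, `mut_aa`, `class`.
#' @export
enumerate_nnk_variants <- function(spec) {
  stopifnot(inherits(spec, "operon_spec"))
  codons <- split_codons(spec$coding_sequence)
  nnk <- nnk_codons()
  pos <- rep(spec$mutagenized_positions, each = length(nnk))
  mut <- rep(nnk, times = length(spec$mutagenized_positions))
  wt <- codons[pos]
  wt_aa <- translate_codons(wt)
  mut_aa <- translate_codons(mut)
  cls <- ifelse(mut == wt, "wt_identical",
         ifelse(mut_aa == "*", "nonsense",
         ifelse(mut_aa == wt_aa, "synonymous", "nonsynonymous")))
  tibble::tibble(
    variant_id = sprintf("p%03d_%s", pos, mut),
    position = pos, wt_codon = wt, mut_codon = mut,
    wt_aa = wt_aa, mut_aa = mut_aa, class = cls)
}

#' Expected wild-type fraction of an NNK library
#'
#' Assembled NNK pools regenerate the wild-type codon whenever the reference
#' codon itself is an NNK codon (K-ending); template plasmid carryover adds a
#' further fixed fraction. With equimolar positions and codons:
#' `carryover + (1 - carryover) * n_K / (n_pos * 32)` where `n_K` counts
#' positions whose reference codon ends in G or T.
#'
#' @param spec an [operon_spec()].
#' @param template_carryover fraction of constructs that are untouched
#'   template (0 <= x < 1).
#' @return expected WT read fraction.
#' @export
expected_wt_fraction <- function(spec, template_carryover = 0) {
  stopifnot(inherits(spec, "operon_spec"),
            template_carryover >= 0, template_carryover < 1)
  codons <- split_codons(spec$coding_sequence)[spec$mutagenized_positions]
  n_k <- sum(substr(codons, 3L, 3L) %in% c("G", "T"))
  template_carryover +
    (1 - template_carryover) * n_k / (length(codons) * 32)
}

#' Generative model for true per-variant survival effects
#'
#' Log-linear effect model used to endow simulated variants with known ground
#' truth: `survival = baseline * RCU^rcu_coefficient * exp(region_offset) *
#' lognormal(0, noise_sd)`. It encodes the association the screen is designed
#' to detect — rarer mutant codons (lower relative codon usage) surviving
#' selection less often — plus optional region-level offsets (e.g. an
#' RBS-overlapping segment) and per-variant biological noise.
#'
#' @param baseline_survival survival of the wild type (positive).
#' @param rcu_coefficient log-survival change per unit log-RCU.
#' @param region_effects data.frame with columns `from`, `to` (codon
#'   interval, closed) and `offset` (additive on log survival); or NULL.
#' @param noise_sd sd of lognormal per-variant noise (0 = none).
#' @param seed integer seed making effect assignment reproducible.
#' @return object of class `effect_model`.
#' @export
effect_model <- function(baseline_survival = 1, rcu_coefficient = 0,
                         region_effects = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(baseline_survival > 0, noise_sd >= 0)
  if (!is.null(region_effects))
    stopifnot(all(c("from", "to", "offset") %in% names(region_effects)))
  structure(list(baseline_survival = baseline_survival,
                 rcu_coefficient = rcu_coefficient,
                 region_effects = region_effects,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "effect_model")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Assign ground-truth survival effects to an enumerated NNK library
#'
#' Applies an [effect_model()] to the variant table, producing a simulated
#' library with per-variant `true_survival` and unselected pool proportions.
#' NNK codons identical to the reference (`wt_identical`) are folded into the
#' wild-type pool mass: their reads are sequence-identical to WT so no
#' downstream analysis can distinguish them. Nonsense variants have no
#' defined RCU; the model treats their RCU as 1 so that the
#' `rcu_coefficient = 0` neutral model is exactly neutral for every variant.
#'
#' @param variants tibble from [enumerate_nnk_variants()].
#' @param model an [effect_model()].
#' @param usage_table a [usage_table()] covering all non-stop codons.
#' @param wt_fraction total WT fraction of the pool (NNK-borne plus template
#'   carryover); remaining mass is split equally across variants.
#' @return object of class `simulated_library`: list with `variants`
#'   (tibble incl. `true_survival`), `wt_fraction`, `wt_survival`,
#'   `unselected_proportions` (named, sums to 1, includes `"WT"`).
#' @export
assign_true_effects <- function(variants, model, usage_table,
                                wt_fraction = 0.10) {
  stopifnot(inherits(model, "effect_model"),
            wt_fraction >= 0, wt_fraction < 1)
  v <- variants[variants$class != "wt_identical", , drop = FALSE]
  rcu_vals <- vapply(seq_len(nrow(v)), function(i) {
    if (v$class[i] == "nonsense") return(1)
    rcu(v$wt_codon[i], v$mut_codon[i], usage_table)
  }, numeric(1))
  offset <- numeric(nrow(v))
  if (!is.null(model$region_effects)) {
    re <- model$region_effects
    for (k in seq_len(nrow(re))) {
      hit <- v$position >= re$from[k] & v$position <= re$to[k]
      offset[hit] <- offset[hit] + re$offset[k]
    }
  }
  noise <- if (model$noise_sd > 0)
    with_seed(model$seed, rlnorm(nrow(v), 0, model$noise_sd))
  else rep(1, nrow(v))
  v$rcu <- rcu_vals
  v$true_survival <- model$baseline_survival *
    rcu_vals^model$rcu_coefficient * exp(offset) * noise
  props <- c(WT = wt_fraction,
             setNames(rep((1 - wt_fraction) / nrow(v), nrow(v)),
                      v$variant_id))
  structure(list(variants = v,
                 wt_fraction = wt_fraction,
                 wt_survival = model$baseline_survival,
                 unselected_proportions = props),
            class = "simulated_library")
}

#' Sequencing-run configuration for library simulation
#'
#' @param depth_per_replicate integer vector of usable read depths, one per
#'   replicate (recycled); defaults mirror a three-replicate NovaSeq run
#'   with usable depths of 201938, 478296 and 100205 reads.
#' @param n_replicates number of biological replicates.
#' @param q_score_profile single Phred value or per-cycle vector.
#' @param sequencing_error_rate per-base substitution error rate in emitted
#'   reads.
#' @param mid_tags named character vector of distinct 6-base multiplex
#'   identifier (MID) tags, one per condition.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(depth_per_replicate = c(201938L, 478296L, 100205L),
                       n_replicates = 3L,
                       q_score_profile = 35L,
                       sequencing_error_rate = 0,
                       mid_tags = c(unselected = "ACGTAC",
                                    selected = "TGCATG"),
                       seed = 1L) {
  stopifnot(all(depth_per_replicate > 0), n_replicates >= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1,
            all(nchar(mid_tags) == 6L), all(is_dna(mid_tags)),
            !is.null(names(mid_tags)))
  if (anyDuplicated(mid_tags)) stop("MID tags must be pairwise distinct")
  structure(list(
    depth_per_replicate = rep_len(as.integer(depth_per_replicate),
                                  n_replicates),
    n_replicates = as.integer(n_replicates),
    q_score_profile = as.integer(q_score_profile),
    sequencing_error_rate = sequencing_error_rate,
    mid_tags = mid_tags,
    seed = as.integer(seed)), class = "sim_config")
}

#' Draw variant count tables under selection
#'
#' Unselected counts are multinomial draws from the pool proportions;
#' selected counts are multinomial draws from proportions reweighted by each
#' variant's true survival (WT at the model baseline). Replicates are
#' independent, each at its configured depth.
#'
#' @param library a [assign_true_effects()] result.
#' @param config a [sim_config()].
#' @return tibble with columns `variant_id`, `position`, `wt_codon`,
#'   `mut_codon`, `condition` (unselected/selected), `replicate`, `count`,
#'   including one WT row per condition and replicate.
#' @export
simulate_counts <- function(library, config) {
  stopifnot(inherits(library, "simulated_library"),
            inherits(config, "sim_config"))
  p_un <- library$unselected_proportions
  surv <- c(library$wt_survival,
            library$variants$true_survival[
              match(names(p_un)[-1], library$variants$variant_id)])
  p_sel <- p_un * surv
  p_sel <- p_sel / sum(p_sel)
  v <- library$variants
  meta_idx <- match(names(p_un), c("WT", v$variant_id))
  out <- vector("list", 2L * config$n_replicates)
  k <- 0L
  for (r in seq_len(config$n_replicates)) {
    depth <- config$depth_per_replicate[r]
    if (depth <= 0) stop("replicate depth must be positive")
    draws <- with_seed(stage_seed(config$seed, r), list(
      unselected = as.vector(rmultinom(1L, depth, p_un)),
      selected = as.vector(rmultinom(1L, depth, p_sel))))
    for (cond in c("unselected", "selected")) {
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        variant_id = names(p_un),
        position = c(NA_integer_, v$position)[meta_idx],
        wt_codon = c(NA_character_, v$wt_codon)[meta_idx],
        mut_codon = c(NA_character_, v$mut_codon)[meta_idx],
        condition = cond, replicate = r,
        count = draws[[cond]])
    }
  }
  do.call(rbind, out)
}

phred_to_chars <- function(q, len) {
  q <- rep_len(q, len)
  rawToChar(as.raw(33L + q))
}

mutate_codon_in_gene <- function(gene, position, mut_codon) {
  start <- 3L * (position - 1L) + 1L
  paste0(substr(gene, 1L, start - 1L), mut_codon,
         substr(gene, start + 3L, nchar(gene)))
}

#' Emit paired FASTQ files for simulated counts
#'
#' For every counted molecule a forward and a reverse read spanning the full
#' amplicon (flanks + gene) is written, each prefixed with the condition's
#' 6-base MID tag. Qualities follow the configured Phred profile;
#' substitution errors are injected uniformly at the configured rate
#' (anywhere in the read, tag included). Read order is shuffled within each
#' file; everything is reproducible from the config seed.
#'
#' @param library a [assign_true_effects()] result.
#' @param spec the [operon_spec()] the library was enumerated from.
#' @param counts tibble from [simulate_counts()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if missing).
#' @return tibble manifest: condition, replicate, n_reads, r1, r2 paths.
#' @export
emit_fastq <- function(library, spec, counts, config, dir) {
  stopifnot(inherits(spec, "operon_spec"), inherits(config, "sim_config"))
  if (anyDuplicated(config$mid_tags)) stop("MID tag collision")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gene <- spec$coding_sequence
  amplicon <- function(g) paste0(spec$amplicon_flanks[1], g,
                                 spec$amplicon_flanks[2])
  templates <- c(WT = amplicon(gene),
                 setNames(amplicon(vapply(seq_len(nrow(library$variants)),
                   function(i) mutate_codon_in_gene(
                     gene, library$variants$position[i],
                     library$variants$mut_codon[i]), character(1))),
                   library$variants$variant_id))
  manifest <- list()
  for (r in sort(unique(counts$replicate))) {
    for (cond in names(config$mid_tags)) {
      cc <- counts[counts$replicate == r & counts$condition == cond, ]
      tmpl <- templates[cc$variant_id]
      if (anyNA(tmpl)) stop("counts reference unknown variant ids")
      fseq <- rep(paste0(config$mid_tags[[cond]], tmpl), cc$count)
      rseq <- rep(paste0(config$mid_tags[[cond]], revcomp(tmpl)), cc$count)
      n <- length(fseq)
      sub_seed <- stage_seed(config$seed,
                             100L * r + match(cond, names(config$mid_tags)))
      ord <- with_seed(sub_seed, sample.int(n))
      fseq <- fseq[ord]; rseq <- rseq[ord]
      if (config$sequencing_error_rate > 0) {
        fseq <- with_seed(sub_seed + 1L,
                          inject_substitutions(fseq, config$sequencing_error_rate))
        rseq <- with_seed(sub_seed + 2L,
                          inject_substitutions(rseq, config$sequencing_error_rate))
      }
      read_len <- if (n) nchar(fseq[1]) else 0L
      qual <- phred_to_chars(config$q_score_profile, read_len)
      ids <- sprintf("%s_rep%d_%06d", cond, r, seq_len(n))
      r1 <- file.path(dir, sprintf("%s_rep%d_R1.fastq", cond, r))
      r2 <- file.path(dir, sprintf("%s_rep%d_R2.fastq", cond, r))
      write_fastq(ids, fseq, qual, r1, mate = 1L)
      write_fastq(ids, rseq, qual, r2, mate = 2L)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        condition = cond, replicate = r, n_reads = n, r1 = r1, r2 = r2)
    }
  }
  do.call(rbind, manifest)
}

inject_substitutions <- function(seqs, rate) {
  if (!length(seqs)) return(seqs)
  len <- nchar(seqs[1])
  n_err <- stats::rbinom(1L, length(seqs) * len, rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE)
  pos <- sample.int(len, n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    cur <- substr(seqs[idx[k]], pos[k], pos[k])
    new <- sample(setdiff(bases, cur), 1L)
    substr(seqs[idx[k]], pos[k], pos[k]) <- new
  }
  seqs
}

write_fastq <- function(ids, seqs, qual_string, path, mate) {
  if (!length(ids)) { file.create(path); return(invisible(path)) }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s/%d", ids, mate)
  q <- Biostrings::PhredQuality(rep(qual_string, length(seqs)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Write a ground-truth JSON file for a simulated library
#' @param library a [assign_true_effects()] result.
#' @param path output path.
#' @export
write_ground_truth <- function(library, path) {
  jsonlite::write_json(list(
    wt_fraction = library$wt_fraction,
    wt_survival = library$wt_survival,
    variants = library$variants[, c("variant_id", "position", "wt_codon",
                                    "mut_codon", "class", "true_survival")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
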