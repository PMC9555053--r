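#' Write a TSV with a metadata preamble
#'
#' All tabular pipeline outputs share this format: `#`-prefixed metadata
#' lines (tool version, parameters) followed by a header line and
#' tab-separated values.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list of metadata values.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("operonDMS ",
                               as.character(utils::packageVersion("operonDMS")))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#' @param path input path.
#' @return tibble (metadata lines are skipped).
#' @export
read_tsv_meta <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Configuration for an end-to-end pipeline run
#'
#' @param spec an [operon_spec()].
#' @param outdir output directory.
#' @param stages character vector of enabled stages, a subset of
#'   `simulate`, `process`, `score`, `features`, `sd_scan`, `associate`
#'   (order fixed).
#' @param model an [effect_model()].
#' @param sim a [sim_config()].
#' @param wt_fraction WT fraction of the simulated pool.
#' @param q_cutoff,min_length,min_overlap,gap_open read-processing knobs.
#' @param min_unselected_reads,n_generations scoring knobs.
#' @param activity_threshold ES cutoff for the association split.
#' @param usage,trna,stall feature tables (defaults: packaged tables).
#' @param seed global seed; fanned out to stages by fixed offsets.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec, outdir,
                            stages = c("simulate", "process", "score",
                                       "features", "sd_scan", "associate"),
                            model = effect_model(),
                            sim = sim_config(),
                            wt_fraction = 0.10,
                            q_cutoff = 20, min_length = 75,
                            min_overlap = 10L, gap_open = 20,
                            min_unselected_reads = 20,
                            n_generations = generations(),
                            activity_threshold = 0.1,
                            usage = NULL, trna = NULL, stall = NULL,
                            seed = 1L) {
  all_stages <- c("simulate", "process", "score", "features", "sd_scan",
                  "associate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(spec = spec, outdir = outdir,
                 stages = all_stages[all_stages %in% stages],
                 model = model, sim = sim, wt_fraction = wt_fraction,
                 q_cutoff = q_cutoff, min_length = min_length,
                 min_overlap = min_overlap, gap_open = gap_open,
                 min_unselected_reads = min_unselected_reads,
                 n_generations = n_generations,
                 activity_threshold = activity_threshold,
                 usage = usage, trna = trna, stall = stall,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the simulate -> process -> score -> features -> sd_scan -> associate
#' pipeline
#'
#' Executes the enabled stages in order, writing every intermediate table
#' under the configured output directory and returning (and writing) a run
#' manifest with versions, parameters, the seed, per-stage record counts
#' and output checksums. Stage dependencies are enforced: `process` needs
#' `simulate`'s FASTQ, `score` needs counts, `associate` needs both scores
#' and features.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  usage <- config$usage %||% load_usage_table()
  trna <- config$trna %||% load_trna_table()
  stall <- config$stall %||% load_stall_table()
  on <- function(stage) stage %in% config$stages
  path <- function(f) file.path(config$outdir, f)
  manifest <- list(
    package = "operonDMS",
    version = as.character(utils::packageVersion("operonDMS")),
    seed = config$seed,
    parameters = list(q_cutoff = config$q_cutoff,
                      min_length = config$min_length,
                      min_unselected_reads = config$min_unselected_reads,
                      n_generations = config$n_generations,
                      activity_threshold = config$activity_threshold,
                      wt_fraction = config$wt_fraction,
                      rcu_coefficient = config$model$rcu_coefficient,
                      noise_sd = config$model$noise_sd,
                      depth_per_replicate = config$sim$depth_per_replicate),
    stages = list())
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg,
                                    call. = FALSE)
  variants <- enumerate_nnk_variants(config$spec)
  lib <- counts <- scores <- feats <- NULL

  if (on("simulate")) {
    lib <- assign_true_effects(variants, config$model, usage,
                               config$wt_fraction)
    counts <- simulate_counts(lib, config$sim)
    write_ground_truth(lib, path("ground_truth.json"))
    write_tsv_meta(counts, path("counts_simulated.tsv"),
                   list(stage = "simulate", seed = config$sim$seed))
    fq <- emit_fastq(lib, config$spec, counts, config$sim, path("fastq"))
    manifest$stages$simulate <- list(n_variants = nrow(lib$variants),
                                     n_reads = sum(fq$n_reads))
  }

  if (on("process")) {
    if (is.null(lib)) fail("process", "requires the simulate stage")
    fq_files <- list.files(path("fastq"), "_R1\\.fastq$", full.names = TRUE)
    files <- tibble::tibble(
      r1 = fq_files,
      r2 = sub("_R1\\.fastq$", "_R2.fastq", fq_files),
      replicate = as.integer(sub(".*_rep(\\d+)_R1\\.fastq$", "\\1",
                                 fq_files)))
    proc <- process_fastq(files, config$spec$coding_sequence,
                          config$sim$mid_tags,
                          q_cutoff = config$q_cutoff,
                          min_length = config$min_length,
                          min_overlap = config$min_overlap,
                          gap_open = config$gap_open)
    counts <- proc$counts
    write_tsv_meta(counts, path("counts_recovered.tsv"),
                   list(stage = "process"))
    write_tsv_meta(proc$rejections, path("rejection_summary.tsv"),
                   list(stage = "process"))
    manifest$stages$process <- list(n_rows = nrow(counts),
                                    n_rejected = sum(proc$rejections$n))
  }

  if (on("score")) {
    if (is.null(counts)) fail("score", "requires counts from simulate or process")
    scores <- score_library(counts, config$min_unselected_reads,
                            config$n_generations)
    write_tsv_meta(scores, path("scores.tsv"), list(stage = "score"))
    write_tsv_meta(position_class_fractions(scores),
                   path("position_summary.tsv"), list(stage = "score"))
    write_tsv_meta(avg_pairwise_codon_delta(scores),
                   path("codon_delta.tsv"), list(stage = "score"))
    manifest$stages$score <- list(n_scored = sum(!is.na(scores$es_mean)))
  }

  if (on("features")) {
    feats <- variant_features(variants, config$spec, usage, trna, stall)
    write_tsv_meta(feats, path("features.tsv"), list(stage = "features"))
    manifest$stages$features <- list(n_rows = nrow(feats))
  }

  if (on("sd_scan") && !is.null(config$spec$rbs_region)) {
    rbs <- config$spec$rbs_region
    # scan all 8-nt windows overlapping the RBS codons: pad the codon
    # interval by 5 nt each side (clipped to the gene)
    rbs_nt <- c(max(1L, 3L * (rbs[1] - 1L) + 1L - 5L),
                min(nchar(config$spec$coding_sequence), 3L * rbs[2] + 5L))
    at_rbs <- variants[variants$position >= rbs[1] &
                       variants$position <= rbs[2] &
                       variants$class != "wt_identical", , drop = FALSE]
    dg <- vapply(seq_len(nrow(at_rbs)), function(i)
      rbs_strength(config$spec$coding_sequence, rbs_nt,
                   list(position = at_rbs$position[i],
                        mut_codon = at_rbs$mut_codon[i])), numeric(1))
    sdtab <- tibble::tibble(variant_id = at_rbs$variant_id,
                            dg_bind = round(dg, 1))
    write_tsv_meta(sdtab, path("rbs_strength.tsv"), list(stage = "sd_scan"))
    if (!is.null(feats))
      feats <- merge(feats, sdtab, by = "variant_id", all.x = TRUE)
    manifest$stages$sd_scan <- list(n_rows = nrow(sdtab))
  }

  if (on("associate")) {
    if (is.null(scores)) fail("associate", "requires the score stage")
    if (is.null(feats)) fail("associate", "requires the features stage")
    joined <- merge(scores[, c("variant_id", "es_mean")], feats,
                    by = "variant_id")
    report <- feature_association_report(joined,
                                         threshold = config$activity_threshold)
    write_tsv_meta(report, path("association_report.tsv"),
                   list(stage = "associate"))
    split <- split_by_activity(joined, config$activity_threshold)
    bs <- lapply(c(active = "active", inactive = "inactive"), function(g) {
      vals <- split[[g]]$rcu
      if (!sum(!is.na(vals))) return(NULL)
      s <- box_stats(vals)
      tibble::tibble(group = g, feature = "rcu", median = s$median,
                     q1 = s$q1, q3 = s$q3, iqr = s$iqr,
                     whisker_low = s$whisker_low,
                     whisker_high = s$whisker_high,
                     n_outliers = length(s$outliers), n = s$n)
    })
    bs <- do.call(rbind, bs[!vapply(bs, is.null, logical(1))])
    if (!is.null(bs))
      write_tsv_meta(bs, path("box_stats.tsv"), list(stage = "associate"))
    manifest$stages$associate <- list(n_features = nrow(report))
  }

  outputs <- list.files(config$outdir, "\\.(tsv|json)$", full.names = TRUE)
  outputs <- setdiff(outputs, path("manifest.json"))
  manifest$outputs <- lapply(setNames(basename(outputs), basename(outputs)),
                             function(f) unname(tools::md5sum(path(f))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads the scalar parameters (seeds, cutoffs, depths, sequences) from
#' YAML and assembles a [pipeline_config()]; fields not present fall back
#' to the defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- operon_spec(y$gene_id %||% "gene",
                      y$coding_sequence,
                      y$mutagenized_positions,
                      rbs_region = y$rbs_region,
                      amplicon_flanks = y$amplicon_flanks %||% c("", ""))
  model <- effect_model(y$baseline_survival %||% 1,
                        y$rcu_coefficient %||% 0,
                        noise_sd = y$noise_sd %||% 0,
                        seed = y$seed %||% 1L)
  sim <- sim_config(
    depth_per_replicate = y$depth_per_replicate %||%
      c(201938L, 478296L, 100205L),
    n_replicates = y$n_replicates %||% 3L,
    q_score_profile = y$q_score_profile %||% 35L,
    sequencing_error_rate = y$sequencing_error_rate %||% 0,
    seed = y$seed %||% 1L)
  args <- list(spec = spec, outdir = y$outdir %||% "pipeline_out",
               model = model, sim = sim, seed = y$seed %||% 1L)
  for (k in c("stages", "wt_fraction", "q_cutoff", "min_length",
              "min_unselected_reads", "n_generations",
              "activity_threshold"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}
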