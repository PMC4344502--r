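# End-to-end orchestration: simulate (or load) -> quantify -> kinetics ->
# sequence features, with TSV outputs and a summary report.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to simulate input data, or `NULL` when real
#'   inputs are supplied.
#' @param hairpin_fasta,annotation_tsv,reads,samples_tsv input paths used
#'   when `sim` is `NULL`: a hairpin FASTA, its mature-arm annotation, a
#'   named list of per-sample read FASTA paths or a count-table TSV, and a
#'   sample sheet.
#' @param thresholds a [threshold_config()].
#' @param nta enable the 3' non-templated-addition remapping pass.
#' @param feature_positions positions tested in the feature stage.
#' @param perm_iterations permutation iterations for the feature stage.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            hairpin_fasta = NULL, annotation_tsv = NULL,
                            reads = NULL, samples_tsv = NULL,
                            thresholds = threshold_config(),
                            nta = FALSE,
                            feature_positions = c(1, "last"),
                            perm_iterations = thresholds$perm_iterations,
                            seed = if (!is.null(sim)) sim$seed else 1L) {
  cfg <- list(sim = sim, hairpin_fasta = hairpin_fasta,
              annotation_tsv = annotation_tsv, reads = reads,
              samples_tsv = samples_tsv, thresholds = thresholds,
              nta = nta, feature_positions = feature_positions,
              perm_iterations = as.integer(perm_iterations),
              seed = as.integer(seed))
  if (is.null(sim)) {
    assert_that(!is.null(hairpin_fasta) && !is.null(annotation_tsv) &&
                  !is.null(reads) && !is.null(samples_tsv),
                "without a simulate block, reference/reads/samples paths are required")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim` and
#' `thresholds` are nested maps passed to [sim_config()] and
#' [threshold_config()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  assert_that(requireNamespace("yaml", quietly = TRUE),
              "the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  th <- if (!is.null(y$thresholds)) do.call(threshold_config, y$thresholds)
        else threshold_config()
  pipeline_config(
    sim = sim,
    hairpin_fasta = y$hairpin_fasta, annotation_tsv = y$annotation_tsv,
    reads = y$reads, samples_tsv = y$samples_tsv,
    thresholds = th, nta = isTRUE(y$nta),
    feature_positions = y$feature_positions %||% c(1, "last"),
    perm_iterations = y$perm_iterations %||% th$perm_iterations,
    seed = y$seed %||% (if (!is.null(sim)) sim$seed else 1L))
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full turnover pipeline
#'
#' Stages: (1) simulate a truth-labelled dataset (or load the configured
#' reference and reads), (2) quantify isoforms and normalize to
#' frequencies, (3) annotate star strands, (4) classify turnover and fit
#' decay models at the mature and isoform level, (5) compare positional
#' sequence features between fast and slow isoform sets. All stage tables
#' are written as TSV under `out_dir` together with a run log and a
#' `summary.json` with detectable/fast/slow counts split by strand role,
#' kinetic-shape tallies, and the feature table. Deterministic given the
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage result and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  th <- config$thresholds
  pipeline_log(log_con, "pipeline start; seed=", config$seed)

  stage <- "simulate/load"
  res <- tryCatch({
    if (!is.null(config$sim)) {
      sim_ref <- generate_reference(config$sim)
      sim <- simulate_timecourse(sim_ref, config$sim)
      reference <- sim_ref$reference
      counts_in <- sim$counts
      samples <- sim$samples
      pipeline_log(log_con, "simulated ", nrow(reference$hairpins),
                   " hairpins, ", nrow(sim$counts), " unique sequences, ",
                   nrow(samples), " samples")
    } else {
      sim_ref <- NULL; sim <- NULL
      reference <- load_reference(config$hairpin_fasta,
                                  config$annotation_tsv)
      samples <- readr::read_tsv(config$samples_tsv,
                                 show_col_types = FALSE, progress = FALSE)
      counts_in <- if (is.character(config$reads) &&
                       length(config$reads) == 1 &&
                       grepl("\\.tsv$", config$reads)) {
        readr::read_tsv(config$reads, show_col_types = FALSE,
                        progress = FALSE)
      } else {
        lapply(config$reads, function(p)
          as.character(Biostrings::readBStringSet(p)))
      }
    }

    stage <- "quantify"
    counts <- quantify_reads(counts_in, reference, th, nta = config$nta)
    freqs <- compute_frequencies(counts, samples, th)
    readr::write_tsv(freqs$isoform, file.path(out_dir, "isoform_freq.tsv"),
                     progress = FALSE)
    readr::write_tsv(freqs$mature, file.path(out_dir, "mature_freq.tsv"),
                     progress = FALSE)
    pipeline_log(log_con, "quantified ", nrow(freqs$isoform),
                 " isoforms / ", nrow(freqs$mature), " mature groups; ",
                 sum(freqs$isoform$detected), " / ",
                 sum(freqs$mature$detected), " detected")

    stage <- "star annotation"
    star <- annotate_star(freqs, reference)
    readr::write_tsv(star, file.path(out_dir, "strand_roles.tsv"),
                     progress = FALSE)

    stage <- "kinetics"
    calls_mature <- turnover_calls(freqs, thresholds = th, level = "mature")
    calls_iso <- turnover_calls(freqs, thresholds = th, level = "isoform")
    readr::write_tsv(calls_mature, file.path(out_dir, "calls_mature.tsv"),
                     progress = FALSE)
    readr::write_tsv(calls_iso, file.path(out_dir, "calls_isoform.tsv"),
                     progress = FALSE)
    pipeline_log(log_con, "classified ", nrow(calls_mature),
                 " mature entities, ", nrow(calls_iso), " isoforms")

    stage <- "features"
    sets <- grouped_isoform_sets(calls_iso)
    features <- NULL
    motif <- NULL
    lengths <- NULL
    if (length(sets$fast) > 0 && length(sets$slow) > 0) {
      features <- position_enrichment_test(
        sets, positions = config$feature_positions,
        iterations = config$perm_iterations, seed = config$seed)
      motif <- a_rich_motif_stat(sets, min_a = th$min_a,
                                 iterations = config$perm_iterations,
                                 seed = config$seed)
      lengths <- length_distribution(sets)
      readr::write_tsv(features, file.path(out_dir, "feature_stats.tsv"),
                       progress = FALSE)
      readr::write_tsv(motif$motif, file.path(out_dir, "a_motif.tsv"),
                       progress = FALSE)
      readr::write_tsv(lengths$histogram,
                       file.path(out_dir, "length_hist.tsv"),
                       progress = FALSE)
    } else {
      pipeline_log(log_con,
                   "feature stage skipped: empty fast or slow isoform set")
    }

    stage <- "summary"
    summary <- pipeline_summary(freqs, star, calls_mature, calls_iso,
                                sim_ref)
    jsonlite::write_json(unclass(summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pipeline_log(log_con, "done")

    list(reference = reference, sim = sim, sim_ref = sim_ref,
         counts = counts, freqs = freqs, star = star,
         calls_mature = calls_mature, calls_isoform = calls_iso,
         sets = sets, features = features, motif = motif,
         lengths = lengths, summary = summary)
  }, error = function(e) {
    pipeline_log(log_con, "FAILED at stage '", stage, "': ",
                 conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

# headline counts: detectable entities, fast/slow split by strand role,
# shape tallies, and (for simulated data) the truth confusion matrix
pipeline_summary <- function(freqs, star, calls_mature, calls_iso,
                             sim_ref = NULL) {
  star_by_mature <- star |>
    select("mature_id", "strand_role")
  cm <- calls_mature |>
    tidyr::separate_rows("entity_id", sep = ";") |>
    left_join(star_by_mature, by = c(entity_id = "mature_id"))
  class_counts <- function(df) as.list(table(df$turnover_class))
  out <- list(
    n_detectable_mature = sum(freqs$mature$detected),
    n_detectable_isoform = sum(freqs$isoform$detected),
    mature_classes = class_counts(calls_mature),
    mature_classes_by_strand = lapply(
      split(cm, cm$strand_role), class_counts),
    isoform_classes = class_counts(calls_iso),
    shape_classes = as.list(table(calls_mature$shape_class))
  )
  class(out) <- "mirturn_summary"
  if (!is.null(sim_ref) && nrow(sim_ref$truth_mature) > 0) {
    truth <- sim_ref$truth_mature |> select("mature_id", truth = "class")
    conf <- calls_mature |>
      filter(.data$detected) |>
      tidyr::separate_rows("entity_id", sep = ";") |>
      left_join(truth, by = c(entity_id = "mature_id")) |>
      filter(!is.na(.data$truth)) |>
      mutate(called_fast = .data$turnover_class %in%
               c("fast_lt25", "fast_lt50")) |>
      count(.data$truth, .data$called_fast)
    out$truth_confusion <- conf
    tp <- sum(conf$n[conf$truth == "fast" & conf$called_fast])
    fn <- sum(conf$n[conf$truth == "fast" & !conf$called_fast])
    fp <- sum(conf$n[conf$truth == "slow" & conf$called_fast])
    tn <- sum(conf$n[conf$truth == "slow" & !conf$called_fast])
    out$fast_sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA
    out$fast_specificity <- if (tn + fp > 0) tn / (tn + fp) else NA
  }
  out
}

#' @export
print.mirturn_summary <- function(x, ...) {
  cat("detectable mature:", x$n_detectable_mature,
      " isoforms:", x$n_detectable_isoform, "\n")
  print(unlist(x$mature_classes))
  print(unlist(x$shape_classes))
  if (!is.null(x$fast_sensitivity)) {
    cat("fast sensitivity:", round(x$fast_sensitivity, 3),
        " specificity:", round(x$fast_specificity, 3), "\n")
  }
  invisible(x)
}
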