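# Bead-array profiling matrices: spike-in normalization (abundance per
# total RNA), total-constant normalization, and total miRNA abundance.

#' Construct a profiling matrix
#'
#' @param intensity numeric matrix, probes x samples, non-negative.
#' @param probe_class character vector (named by probe or in row order) with
#'   values in `mature`, `spikein`, `control`.
#' @param samples sample sheet tibble (`sample_id`, `time_h`, `replicate`);
#'   defaults to parsing nothing and using column names with `time_h = NA`.
#' @return object of class `profiling_matrix`.
#' @export
profiling_matrix <- function(intensity, probe_class, samples = NULL) {
  intensity <- as.matrix(intensity)
  assert_that(!is.null(rownames(intensity)), "intensity needs probe rownames")
  assert_that(all(intensity >= 0), "intensities must be non-negative")
  if (!is.null(names(probe_class))) {
    probe_class <- probe_class[rownames(intensity)]
  }
  assert_that(length(probe_class) == nrow(intensity),
              "probe_class must cover every probe")
  assert_that(all(probe_class %in% c("mature", "spikein", "control")),
              "probe_class values must be mature/spikein/control")
  if (is.null(samples)) {
    samples <- tibble(sample_id = colnames(intensity),
                      time_h = NA_real_, replicate = NA_integer_)
  }
  out <- list(intensity = intensity,
              probe_class = setNames(probe_class, rownames(intensity)),
              samples = as_tibble(samples))
  class(out) <- "profiling_matrix"
  out
}

#' @export
print.profiling_matrix <- function(x, ...) {
  cat("<profiling_matrix> ", nrow(x$intensity), " probes x ",
      ncol(x$intensity), " samples (",
      sum(x$probe_class == "spikein"), " spike-ins)\n", sep = "")
  invisible(x)
}

#' Spike-in normalization (abundance per total RNA)
#'
#' Each sample is scaled by `reference level / geometric mean of its
#' spike-in intensities`, where the reference level is the geometric mean of
#' those per-sample summaries across samples. Because spike-ins are added
#' at a fixed amount per unit of total RNA, the normalized intensities
#' reflect miRNA abundance relative to total RNA; spike-in rows are
#' near-equal across samples afterwards. Because the reference level is
#' estimated from the data, rescaling an input sample changes the output
#' only by a single global factor (the normalization is scale-equivariant
#' up to that factor).
#'
#' @param m a [profiling_matrix()] with at least one spike-in probe.
#' @return the normalized [profiling_matrix()], with the applied per-sample
#'   scale factors in `$scale_factors`.
#' @export
spikein_normalize <- function(m) {
  sp <- m$intensity[m$probe_class == "spikein", , drop = FALSE]
  assert_that(nrow(sp) >= 1, "no spike-in probes in matrix")
  bad <- which(sp <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive spike-in intensity: probe ",
         rownames(sp)[bad[1, 1]], ", sample ", colnames(sp)[bad[1, 2]],
         call. = FALSE)
  }
  per_sample <- apply(sp, 2, geometric_mean)
  ref <- geometric_mean(per_sample)
  scale <- ref / per_sample
  out <- m
  out$intensity <- sweep(m$intensity, 2, scale, `*`)
  out$scale_factors <- scale
  out
}

#' Total-constant normalization
#'
#' Scales each sample so that the sum of its mature-probe intensities equals
#' the across-sample mean of those sums (any positive target constant is
#' equivalent up to a global factor). Valid when total miRNA abundance
#' is approximately constant over the time course; within-sample probe
#' ratios are preserved exactly and rescaling an input sample changes the
#' output only by a global factor.
#'
#' @param m a [profiling_matrix()].
#' @return the normalized [profiling_matrix()] with `$scale_factors`.
#' @export
total_constant_normalize <- function(m) {
  mat <- m$intensity[m$probe_class == "mature", , drop = FALSE]
  sums <- colSums(mat)
  if (any(sums == 0)) {
    stop("all-zero mature probes in sample(s): ",
         paste(colnames(mat)[sums == 0], collapse = ", "), call. = FALSE)
  }
  scale <- mean(sums) / sums
  out <- m
  out$intensity <- sweep(m$intensity, 2, scale, `*`)
  out$scale_factors <- scale
  out
}

#' Total miRNA abundance per sample
#'
#' Sums all mature-probe intensities per sample (spike-in and control rows
#' never contribute) and summarizes the trend over time. Run after
#' [spikein_normalize()] so the totals are on the per-total-RNA scale.
#'
#' @param m a [profiling_matrix()].
#' @return list with `totals` (per-sample tibble), `by_time` (per-timepoint
#'   means) and `trend` (linear slope of total vs time with its 95% CI, or
#'   NULL when times are unavailable).
#' @export
total_mirna_abundance <- function(m) {
  mat <- m$intensity[m$probe_class == "mature", , drop = FALSE]
  totals <- tibble(sample_id = colnames(mat),
                   total = unname(colSums(mat))) |>
    left_join(m$samples, by = "sample_id")
  by_time <- NULL
  trend <- NULL
  if (!all(is.na(totals$time_h))) {
    by_time <- totals |>
      group_by(.data$time_h) |>
      summarise(mean_total = mean(.data$total), n = n(), .groups = "drop")
    if (length(unique(totals$time_h)) >= 2) {
      fit <- lm(total ~ time_h, data = totals)
      ci <- stats::confint(fit)["time_h", ]
      trend <- list(slope = unname(coef(fit)["time_h"]),
                    ci = unname(ci))
    }
  }
  list(totals = totals, by_time = by_time, trend = trend)
}
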