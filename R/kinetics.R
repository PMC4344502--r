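# Turnover kinetics: remaining fractions relative to 0 h, fast/slow
# classification with per-replicate t-tests, single- and two-phase decay
# fits, and kinetic-shape classes.

# long per-replicate frequency table from a wide frequency tibble
freqs_long <- function(freq_tbl, samples, id_col) {
  sn <- samples$sample_id
  freq_tbl |>
    select(entity_id = all_of(id_col), all_of(sn)) |>
    tidyr::pivot_longer(all_of(sn), names_to = "sample_id",
                        values_to = "f") |>
    left_join(samples, by = "sample_id")
}

#' Remaining fractions relative to the 0-h level
#'
#' For every entity, `R(t)` is the mean frequency at time `t` divided by the
#' mean frequency at 0 h (so `R(0) = 1`). Entities with a 0-h mean of zero
#' are marked uncomputable (`R = NA`) rather than erroring.
#'
#' @param freq_tbl wide tibble with an id column and one frequency column
#'   per sample (e.g. `$isoform` or `$mature` of a `frequency_matrix`), or a
#'   `frequency_matrix` itself (then `level` picks the table).
#' @param samples sample sheet (`sample_id`, `time_h`, `replicate`).
#' @param id_col name of the entity id column.
#' @param level `"mature"` or `"isoform"`, used when `freq_tbl` is a
#'   `frequency_matrix`.
#' @return list of class `remaining_fractions`: `$mean` (entity x time tibble
#'   of `R`), `$reps` (per-replicate frequencies and ratios), `$baseline`
#'   (0-h mean per entity).
#' @export
remaining_fractions <- function(freq_tbl, samples = NULL, id_col = NULL,
                                level = c("mature", "isoform")) {
  if (inherits(freq_tbl, "frequency_matrix")) {
    level <- match.arg(level)
    samples <- samples %||% freq_tbl$samples
    id_col <- id_col %||% if (level == "mature") "mature_id" else "sequence"
    freq_tbl <- freq_tbl[[level]]
  }
  assert_that(!is.null(samples) && !is.null(id_col),
              "samples and id_col are required for plain tables")
  samples <- as_tibble(samples)
  assert_that(any(samples$time_h == 0), "need 0-h samples")
  assert_that(length(unique(samples$time_h)) >= 2, "need >= 2 timepoints")

  long <- freqs_long(freq_tbl, samples, id_col)
  baseline <- long |>
    filter(.data$time_h == 0) |>
    group_by(.data$entity_id) |>
    summarise(f0 = mean(.data$f), .groups = "drop")
  reps <- long |>
    left_join(baseline, by = "entity_id") |>
    mutate(ratio = ifelse(.data$f0 > 0, .data$f / .data$f0, NA_real_))
  mean_r <- reps |>
    group_by(.data$entity_id, .data$time_h) |>
    summarise(R = mean(.data$ratio), n_reps = sum(!is.na(.data$ratio)),
              .groups = "drop")
  out <- list(mean = mean_r, reps = reps, baseline = baseline)
  class(out) <- "remaining_fractions"
  out
}

# two-sample equal-variance t-test p-value that tolerates zero variance
safe_t_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(t.test(x, y, var.equal = TRUE)$p.value,
           error = function(e) NA_real_)
}

#' Classify entities into fast/slow turnover groups
#'
#' Applies two-sided equal-variance t-tests on per-replicate frequencies
#' (0 h vs 4 h, 0 h vs 12 h, and 0 h vs the pooled 4+12 h group). An entity
#' is `fast_lt50` when `R(12) < 0.50` and any comparison has `p < alpha`,
#' additionally `fast_lt25` when `R(12) < 0.25`; `slow` when
#' `R(12) >= 0.75` and no comparison is significant; otherwise
#' `intermediate`. Entities without enough replicates (or no computable
#' baseline) are `unclassified`. A Benjamini-Hochberg adjusted column is
#' emitted for information only; the class rules use the nominal p-values.
#'
#' @inheritParams remaining_fractions
#' @param thresholds a [threshold_config()].
#' @return tibble with one row per entity: `R4`, `R12`, `p_0v4`, `p_0v12`,
#'   `p_0v412`, `p_min`, `p_min_bh`, `turnover_class`, `reason`.
#' @export
classify_turnover <- function(freq_tbl, samples = NULL, id_col = NULL,
                              thresholds = threshold_config(),
                              level = c("mature", "isoform")) {
  rf <- if (inherits(freq_tbl, "remaining_fractions")) freq_tbl else
    remaining_fractions(freq_tbl, samples, id_col, level)
  reps <- rf$reps
  alpha <- thresholds$alpha

  per_entity <- reps |>
    group_by(.data$entity_id) |>
    group_map(function(df, key) {
      f0 <- df$f[df$time_h == 0]
      f4 <- df$f[df$time_h == 4]
      f12 <- df$f[df$time_h == 12]
      f0m <- mean(f0)
      r4 <- if (length(f4) && f0m > 0) mean(f4) / f0m else NA_real_
      r12 <- if (length(f12) && f0m > 0) mean(f12) / f0m else NA_real_
      p4 <- if (length(f4)) safe_t_p(f0, f4) else NA_real_
      p12 <- if (length(f12)) safe_t_p(f0, f12) else NA_real_
      p412 <- if (length(c(f4, f12))) safe_t_p(f0, c(f4, f12)) else NA_real_
      tibble(entity_id = key$entity_id, R4 = r4, R12 = r12,
             p_0v4 = p4, p_0v12 = p12, p_0v412 = p412)
    }) |>
    bind_rows()

  per_entity |>
    mutate(
      p_min = pmin(.data$p_0v4, .data$p_0v12, .data$p_0v412, na.rm = TRUE),
      p_min = ifelse(is.finite(.data$p_min), .data$p_min, NA_real_),
      p_min_bh = p.adjust(.data$p_min, method = "BH"),
      any_sig = !is.na(.data$p_min) & .data$p_min < alpha,
      turnover_class = case_when(
        is.na(.data$R12) | is.na(.data$p_min) ~ "unclassified",
        .data$R12 < thresholds$fast25 & .data$any_sig ~ "fast_lt25",
        .data$R12 < thresholds$fast50 & .data$any_sig ~ "fast_lt50",
        .data$R12 >= thresholds$slow75 & !.data$any_sig ~ "slow",
        TRUE ~ "intermediate"),
      reason = case_when(
        is.na(.data$R12) ~ "no 12-h remaining fraction (0-h mean zero?)",
        is.na(.data$p_min) ~ "insufficient replicates for t-tests",
        TRUE ~ "")) |>
    select(-"any_sig")
}

#' Single-exponential decay fit
#'
#' Least-squares fit of `log2(R)` versus time through the origin
#' (`R(0) = 1` by construction). The half-life is `-1/slope`; a
#' non-negative slope yields an infinite half-life. Timepoints with
#' non-positive mean `R` are excluded.
#'
#' @param r_tbl tibble with columns `time_h` and `R` (one entity), e.g. a
#'   subset of `remaining_fractions()$mean`.
#' @return list with `h` (half-life, hours; may be `Inf`), `slope`, `sse`
#'   (sum of squares of `R` residuals on the linear scale), `n_used`.
#' @export
fit_single_exponential <- function(r_tbl) {
  d <- r_tbl |> filter(!is.na(.data$R), .data$R > 0)
  if (nrow(d) < 2) {
    return(list(h = NA_real_, slope = NA_real_, sse = NA_real_, n_used = 0L))
  }
  slope <- sum(d$time_h * log2(d$R)) / sum(d$time_h^2)
  h <- if (slope >= 0) Inf else -1 / slope
  pred <- decay2(r_tbl$time_h, h)
  sse <- sum((r_tbl$R - pred)^2, na.rm = TRUE)
  list(h = h, slope = slope, sse = sse, n_used = nrow(d))
}

two_phase_model <- function(t, f_fast, h_fast, h_slow) {
  f_fast * decay2(t, h_fast) + (1 - f_fast) * decay2(t, h_slow)
}

# closed-form optimal F_fast for fixed half-lives (weighted least squares,
# clipped to [0, 1])
best_f_fast <- function(t, r, w, h_fast, h_slow) {
  df <- decay2(t, h_fast)
  ds <- decay2(t, h_slow)
  denom <- sum(w * (df - ds)^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(w * (df - ds) * (r - ds)) / denom))
}

two_phase_sse <- function(t, r, w, f_fast, h_fast, h_slow) {
  sum(w * (r - two_phase_model(t, f_fast, h_fast, h_slow))^2)
}

#' Two-phase (two-pool) exponential decay fit
#'
#' Fits `R(t) = F_fast * 2^(-t/h_fast) + F_slow * 2^(-t/h_slow)` with
#' `F_fast + F_slow = 1`, `F_fast` in `[0, 1]`, `h_fast` within
#' `thresholds$hfast_bounds` and `h_slow >= h_fast` (including `Inf`, a pure
#' plateau). Minimizes the replicate-count-weighted sum of squares over a
#' coarse grid on the half-lives (with the closed-form optimal `F_fast` at
#' each node), then refines the best candidates with bounded local search.
#' The single-exponential fit is always included as a candidate, so the
#' two-phase SSE never exceeds it. Degenerate flat data (`R = 1`) yields
#' `F_fast = 0` with infinite half-lives.
#'
#' @param r_tbl tibble with `time_h`, `R` and optionally `n_reps` (weights).
#' @param thresholds a [threshold_config()].
#' @return list with `f_fast`, `h_fast`, `f_slow`, `h_slow`, `sse`,
#'   `aic`, `aic_single`, `delta_aic` (positive when the two-phase fit is
#'   preferred) and `single` (the [fit_single_exponential()] result).
#' @export
fit_two_phase <- function(r_tbl, thresholds = threshold_config()) {
  single <- fit_single_exponential(r_tbl)
  d <- r_tbl |> filter(!is.na(.data$R))
  if (!"n_reps" %in% names(d)) d$n_reps <- 1
  if (nrow(d) < 3) {
    return(list(f_fast = NA_real_, h_fast = NA_real_, f_slow = NA_real_,
                h_slow = NA_real_, sse = NA_real_, aic = NA_real_,
                aic_single = NA_real_, delta_aic = NA_real_,
                single = single))
  }
  t <- d$time_h; r <- d$R; w <- d$n_reps
  hb <- thresholds$hfast_bounds

  hf_grid <- logspace(hb[1], hb[2], 30)
  hs_grid <- c(Inf, logspace(0.5, 200, 12))
  cand <- tidyr::expand_grid(hf = hf_grid, hs = hs_grid) |>
    filter(.data$hs >= .data$hf)
  cand$f <- purrr::map2_dbl(cand$hf, cand$hs,
                            ~ best_f_fast(t, r, w, .x, .y))
  cand$sse <- purrr::pmap_dbl(list(cand$f, cand$hf, cand$hs),
                              ~ two_phase_sse(t, r, w, ..1, ..2, ..3))

  # nested single-exponential candidates guarantee SSE(two) <= SSE(single)
  extra <- tibble(hf = numeric(0), hs = numeric(0), f = numeric(0))
  if (is.finite(single$h)) {
    hf_c <- min(max(single$h, hb[1]), hb[2])
    extra <- bind_rows(extra,
                       tibble(hf = hf_c, hs = Inf, f = 1),
                       tibble(hf = hb[1], hs = max(single$h, hb[1]), f = 0))
  } else if (!is.na(single$h)) {
    extra <- bind_rows(extra, tibble(hf = hb[1], hs = Inf, f = 0))
  }
  if (nrow(extra) > 0) {
    extra$sse <- purrr::pmap_dbl(list(extra$f, extra$hf, extra$hs),
                                 ~ two_phase_sse(t, r, w, ..1, ..2, ..3))
    cand <- bind_rows(cand, extra)
  }

  top <- cand |> arrange(.data$sse) |> head(3)
  best <- top[1, ]
  for (i in seq_len(nrow(top))) {
    st <- top[i, ]
    # refine with h_slow = Inf (plateau) ...
    o1 <- tryCatch(optim(
      c(st$f, log(st$hf)),
      function(p) two_phase_sse(t, r, w, p[1], exp(p[2]), Inf),
      method = "L-BFGS-B",
      lower = c(0, log(hb[1])), upper = c(1, log(hb[2])),
      control = list(factr = 1e4)), error = function(e) NULL)
    if (!is.null(o1) && o1$value < best$sse) {
      best <- tibble(hf = exp(o1$par[2]), hs = Inf, f = o1$par[1],
                     sse = o1$value)
    }
    # ... and with finite h_slow
    hs0 <- if (is.finite(st$hs)) st$hs else 100
    o2 <- tryCatch(optim(
      c(st$f, log(st$hf), log(hs0)),
      function(p) {
        hf <- exp(p[2]); hs <- exp(p[3])
        if (hs < hf) return(1e6 + (hf - hs)^2)
        two_phase_sse(t, r, w, p[1], hf, hs)
      },
      method = "L-BFGS-B",
      lower = c(0, log(hb[1]), log(hb[1])),
      upper = c(1, log(hb[2]), log(1e4)),
      control = list(factr = 1e4)), error = function(e) NULL)
    if (!is.null(o2) && o2$value < best$sse) {
      best <- tibble(hf = exp(o2$par[2]), hs = exp(o2$par[3]),
                     f = o2$par[1], sse = o2$value)
    }
  }

  # canonical orientation: the fast pool is the shorter half-life
  f_fast <- best$f; h_fast <- best$hf; h_slow <- best$hs
  if (is.finite(h_slow) && h_slow < h_fast) {
    tmp <- h_fast; h_fast <- h_slow; h_slow <- tmp
    f_fast <- 1 - f_fast
  }
  n <- nrow(d)
  sse_floor <- 1e-12
  aic_two <- n * log(max(best$sse, sse_floor) / n) + 2 * 3
  aic_single <- if (is.na(single$sse)) NA_real_ else
    n * log(max(single$sse, sse_floor) / n) + 2 * 1
  list(f_fast = f_fast, h_fast = h_fast, f_slow = 1 - f_fast,
       h_slow = h_slow, sse = best$sse, aic = aic_two,
       aic_single = aic_single, delta_aic = aic_single - aic_two,
       single = single)
}

#' Classify the kinetic shape of an entity
#'
#' Rules, applied in order: `ultrafast` when `R(1) <= 0.10` (requires a 1-h
#' timepoint); `two_step` when the two-phase fit beats the
#' single-exponential by at least `aic_margin` AIC units with fitted
#' `h_fast <= two_step_hfast_max` and `F_slow >= two_step_fslow_min`;
#' `continuous` for fast-class entities whose single-exponential half-life
#' is >= 4 h or whose single-exponential fit is adequate (no AIC
#' preference for two phases); `stable` for slow-class entities; otherwise
#' `unclassified`.
#'
#' @param r1 remaining fraction at 1 h (NA when no 1-h timepoint exists).
#' @param turnover_class class from [classify_turnover()].
#' @param fit a [fit_two_phase()] result.
#' @param thresholds a [threshold_config()].
#' @return a single string.
#' @export
classify_kinetic_shape <- function(r1, turnover_class, fit,
                                   thresholds = threshold_config()) {
  if (!is.na(r1) && r1 <= thresholds$ultrafast_r1) return("ultrafast")
  # both pools must be substantive, so flat entities whose noise happens to
  # reward the extra parameters are not called two-step
  two_step <- !is.na(fit$delta_aic) &&
    fit$delta_aic >= thresholds$aic_margin &&
    !is.na(fit$h_fast) && fit$h_fast <= thresholds$two_step_hfast_max &&
    !is.na(fit$f_slow) && fit$f_slow >= thresholds$two_step_fslow_min &&
    !is.null(fit$f_fast) && !is.na(fit$f_fast) &&
    fit$f_fast >= thresholds$two_step_fslow_min
  if (two_step) return("two_step")
  fast <- turnover_class %in% c("fast_lt25", "fast_lt50")
  if (fast) {
    h <- fit$single$h
    adequate <- !is.na(fit$delta_aic) &&
      fit$delta_aic < thresholds$aic_margin
    if ((!is.na(h) && h >= 4) || adequate) return("continuous")
  }
  if (turnover_class == "slow") return("stable")
  "unclassified"
}

#' Full turnover-call table for every entity
#'
#' Convenience wrapper combining [remaining_fractions()],
#' [classify_turnover()], [fit_single_exponential()], [fit_two_phase()] and
#' [classify_kinetic_shape()]. Only detected entities are classified and
#' fitted (others are retained as `unclassified` with NA fits) and fits can
#' be restricted to non-slow entities for speed.
#'
#' @inheritParams classify_turnover
#' @param fit_all also fit decay models for slow/undetected entities
#'   (default fits every classified entity).
#' @return tibble with one row per entity: remaining fractions, p-values,
#'   turnover class, both fits' parameters and the kinetic-shape class.
#' @export
turnover_calls <- function(freq_tbl, samples = NULL, id_col = NULL,
                           thresholds = threshold_config(),
                           level = c("mature", "isoform"),
                           fit_all = TRUE) {
  detected_ids <- NULL
  if (inherits(freq_tbl, "frequency_matrix")) {
    level <- match.arg(level)
    samples <- samples %||% freq_tbl$samples
    id_col <- id_col %||% if (level == "mature") "mature_id" else "sequence"
    tbl <- freq_tbl[[level]]
    if ("detected" %in% names(tbl)) {
      detected_ids <- tbl[[id_col]][tbl$detected]
    }
    freq_tbl <- tbl
  }
  rf <- remaining_fractions(freq_tbl, samples, id_col)
  calls <- classify_turnover(rf, thresholds = thresholds)
  if (!is.null(detected_ids)) {
    calls <- calls |>
      mutate(detected = .data$entity_id %in% detected_ids,
             turnover_class = ifelse(.data$detected, .data$turnover_class,
                                     "unclassified"),
             reason = ifelse(.data$detected, .data$reason,
                             "below detection threshold"))
  } else {
    calls$detected <- TRUE
  }

  r_by_entity <- rf$mean |> tidyr::nest(.by = "entity_id", .key = "r_tbl")
  r1_tbl <- rf$mean |>
    filter(.data$time_h == 1) |>
    select("entity_id", R1 = "R")
  calls <- calls |>
    left_join(r1_tbl, by = "entity_id") |>
    left_join(r_by_entity, by = "entity_id")
  if (!"R1" %in% names(calls)) calls$R1 <- NA_real_

  fit_one <- function(r_tbl, do_fit) {
    if (!do_fit) {
      return(tibble(h_single = NA_real_, f_fast = NA_real_,
                    h_fast = NA_real_, f_slow = NA_real_, h_slow = NA_real_,
                    sse_two = NA_real_, delta_aic = NA_real_))
    }
    fit <- fit_two_phase(r_tbl, thresholds)
    tibble(h_single = fit$single$h, f_fast = fit$f_fast,
           h_fast = fit$h_fast, f_slow = fit$f_slow, h_slow = fit$h_slow,
           sse_two = fit$sse, delta_aic = fit$delta_aic)
  }
  do_fit <- calls$detected &
    (fit_all | calls$turnover_class %in% c("fast_lt25", "fast_lt50",
                                           "intermediate"))
  fits <- purrr::map2_dfr(calls$r_tbl, do_fit, fit_one)
  calls <- bind_cols(calls |> select(-"r_tbl"), fits)

  calls$shape_class <- purrr::pmap_chr(
    list(calls$R1, calls$turnover_class, seq_len(nrow(calls))),
    function(r1, tc, i) {
      if (!do_fit[i]) return("unclassified")
      fit <- list(delta_aic = calls$delta_aic[i], h_fast = calls$h_fast[i],
                  f_fast = calls$f_fast[i], f_slow = calls$f_slow[i],
                  single = list(h = calls$h_single[i]))
      classify_kinetic_shape(ifelse(is.na(r1), NA_real_, r1), tc, fit,
                             thresholds)
    })
  calls
}
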