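# Remaining fractions, turnover classification and decay-model fits.

test_that("remaining fractions are ratios to the 0-h mean", {
  samples <- toy_samples(times = c(0, 1, 2), reps = 1)
  # halving every hour
  tbl <- toy_freq_tbl(c(8e-4, 4e-4, 2e-4), samples)
  rf <- remaining_fractions(tbl, samples, id_col = "entity_id")
  expect_equal(rf$mean$R[order(rf$mean$time_h)], c(1, 0.5, 0.25))

  # constant frequencies give R = 1 everywhere
  tbl2 <- toy_freq_tbl(rep(3e-5, 3), samples)
  rf2 <- remaining_fractions(tbl2, samples, id_col = "entity_id")
  expect_equal(rf2$mean$R, rep(1, 3))

  # zero baseline marks the entity uncomputable rather than erroring
  tbl3 <- toy_freq_tbl(c(0, 1e-4, 1e-4), samples)
  rf3 <- remaining_fractions(tbl3, samples, id_col = "entity_id")
  expect_true(all(is.na(rf3$mean$R)))
})

test_that("turnover classes follow the remaining-fraction and t-test gates", {
  samples <- toy_samples(times = c(0, 4, 12), reps = 3)
  run1 <- function(vals) {
    tbl <- toy_freq_tbl(vals, samples)
    classify_turnover(tbl, samples, id_col = "entity_id")
  }
  # R(12) = 0.2 with clearly significant drops -> fast_lt25
  fast <- run1(c(1.00, 1.02, 0.98, 0.50, 0.52, 0.48, 0.20, 0.21, 0.19))
  expect_equal(fast$turnover_class, "fast_lt25")
  expect_lt(fast$p_0v12, 0.05)

  # R(12) = 0.40: fast_lt50 but not fast_lt25
  mid <- run1(c(1.00, 1.02, 0.98, 0.70, 0.72, 0.68, 0.40, 0.41, 0.39))
  expect_equal(mid$turnover_class, "fast_lt50")

  # identical replicate values at all timepoints: R = 1, all p = 1 -> slow
  flat <- run1(rep(0.5, 9))
  expect_equal(flat$turnover_class, "slow")
  expect_equal(flat$p_0v12, 1)

  # R(12) = 0.74 with tiny variance: significant but fails both gates
  inter <- run1(c(1.000, 1.001, 0.999, 0.90, 0.901, 0.899,
                  0.740, 0.741, 0.739))
  expect_lt(inter$p_0v12, 0.05)
  expect_equal(inter$turnover_class, "intermediate")

  # single replicate: t-tests undefined -> unclassified with reason
  s1 <- toy_samples(times = c(0, 4, 12), reps = 1)
  tbl <- toy_freq_tbl(c(1, 0.5, 0.2), s1)
  un <- classify_turnover(tbl, s1, id_col = "entity_id")
  expect_equal(un$turnover_class, "unclassified")
  expect_match(un$reason, "replicates")
})

test_that("classification is monotone in R(12) when tests stay significant", {
  samples <- toy_samples(times = c(0, 4, 12), reps = 3)
  classes <- sapply(c(0.9, 0.7, 0.45, 0.2, 0.05), function(r12) {
    vals <- c(1.00, 1.01, 0.99, 0.6, 0.61, 0.59,
              r12, r12 + 0.01, r12 - 0.01)
    tbl <- toy_freq_tbl(vals, samples)
    classify_turnover(tbl, samples, id_col = "entity_id")$turnover_class
  })
  rank <- c(slow = 0, intermediate = 1, fast_lt50 = 2, fast_lt25 = 3)
  expect_true(all(diff(rank[classes]) >= 0))
  expect_false("slow" %in% classes)  # significant drop blocks the slow call
})

test_that("single-exponential fits recover closed-form half-lives", {
  r <- tibble::tibble(time_h = c(0, 1, 2), R = c(1, 0.5, 0.25))
  fit <- fit_single_exponential(r)
  expect_equal(fit$h, 1.0, tolerance = 1e-12)

  flat <- fit_single_exponential(tibble::tibble(time_h = c(0, 4, 12),
                                                R = c(1, 1, 1)))
  expect_identical(flat$h, Inf)

  # noiseless generator species at h = 18 recovers 18 +- 1e-6
  t <- c(0, 1, 4, 12)
  r18 <- tibble::tibble(time_h = t, R = 2^(-t / 18))
  expect_equal(fit_single_exponential(r18)$h, 18, tolerance = 1e-6)

  # non-positive means are excluded, not fatal
  mix <- fit_single_exponential(tibble::tibble(time_h = c(0, 4, 12),
                                               R = c(1, 0.5, 0)))
  expect_equal(mix$n_used, 2)
})

test_that("two-phase fits recover exact mixtures and nest the single fit", {
  t <- c(0, 1, 4, 12)
  r <- tibble::tibble(time_h = t, R = 0.2 + 0.8 * 2^(-t), n_reps = 3)
  fit <- fit_two_phase(r)
  expect_equal(fit$f_fast, 0.8, tolerance = 1e-6)
  expect_equal(fit$h_fast, 1.0, tolerance = 1e-6)
  expect_equal(fit$f_slow, 0.2, tolerance = 1e-6)
  expect_true(is.infinite(fit$h_slow) || fit$h_slow > 1e3)
  expect_equal(fit$f_fast + fit$f_slow, 1)

  # degenerate flat data: no fast pool, no error
  flat <- fit_two_phase(tibble::tibble(time_h = t, R = rep(1, 4)))
  expect_equal(flat$f_fast, 0, tolerance = 1e-9)

  # nestedness: the two-phase SSE never exceeds the single-exponential SSE
  set.seed(42)
  for (i in 1:20) {
    rr <- tibble::tibble(
      time_h = t,
      R = pmax(0.01, 2^(-t / runif(1, 0.5, 30)) + rnorm(4, 0, 0.05)))
    rr$R[1] <- 1
    f2 <- fit_two_phase(rr)
    expect_lte(f2$sse, f2$single$sse + 1e-9)
  }
})

test_that("two-phase recovery matches a dense brute-force grid oracle", {
  # constructed noisy curves: the packaged fit (coarse grid + refinement)
  # must do at least as well as a dense grid with no local refinement
  set.seed(7)
  t <- c(0, 1, 4, 12)
  hf_dense <- exp(seq(log(0.05), log(50), length.out = 200))
  for (i in 1:10) {
    fs <- runif(1, 0.05, 0.4)
    truth_r <- fs + (1 - fs) * 2^(-t / 1)
    r <- tibble::tibble(time_h = t,
                        R = pmax(0.005, truth_r * (1 + rnorm(4, 0, 0.05))))
    r$R[1] <- 1
    fit <- fit_two_phase(r)
    oracle_sse <- min(vapply(hf_dense, function(hf) {
      d <- 2^(-t / hf)
      f <- min(1, max(0, sum((d - 1) * (r$R - 1)) / sum((d - 1)^2)))
      sum((r$R - (f * d + (1 - f)))^2)
    }, numeric(1)))
    expect_lte(fit$sse, oracle_sse + 1e-9)
    expect_lt(abs(fit$h_fast - 1), 0.5)
  }
})

test_that("kinetic shapes are assigned by the documented rules", {
  th <- threshold_config()
  t <- c(0, 1, 4, 12)

  # near-complete loss at 1 h -> ultrafast (the loop-read pattern)
  r_uf <- tibble::tibble(time_h = t, R = c(1, 0.05, 0.04, 0.03))
  fit_uf <- fit_two_phase(r_uf)
  expect_equal(classify_kinetic_shape(0.05, "fast_lt25", fit_uf, th),
               "ultrafast")

  # plateau at ~0.3 with ~1 h fast phase -> two_step
  r_ts <- tibble::tibble(time_h = t, R = c(1, 0.55, 0.33, 0.30))
  fit_ts <- fit_two_phase(r_ts)
  expect_equal(classify_kinetic_shape(0.55, "fast_lt50", fit_ts, th),
               "two_step")

  # clean single exponential with h = 6 -> continuous fast turnover
  r_c <- tibble::tibble(time_h = t, R = 2^(-t / 6))
  fit_c <- fit_two_phase(r_c)
  expect_equal(classify_kinetic_shape(2^(-1 / 6), "fast_lt50", fit_c, th),
               "continuous")

  # slow entities are stable
  r_s <- tibble::tibble(time_h = t, R = c(1, 1.01, 0.99, 1))
  fit_s <- fit_two_phase(r_s)
  expect_equal(classify_kinetic_shape(1.01, "slow", fit_s, th), "stable")
})

test_that("noiseless generator time courses reproduce the decay law end to end", {
  cfg <- sim_config(n_hairpins = 15, nb_dispersion = 0, depth = 1e6,
                    abundance_sdlog = 0, seed = 41)
  sr <- generate_reference(cfg)
  sim <- simulate_timecourse(sr)
  fr <- compute_frequencies(quantify_reads(sim$counts, sr$reference),
                            sim$samples)
  rf <- remaining_fractions(fr, level = "mature")
  truth <- sr$truth_mature
  j <- dplyr::inner_join(rf$mean, truth,
                         by = c(entity_id = "mature_id"))
  law <- ifelse(j$class == "fast",
                j$f_slow + (1 - j$f_slow) * 2^(-j$time_h / j$h_fast),
                1)
  # normalization against the (slightly decaying) mature total biases R
  # upward by the same per-sample factor for every species
  for (tt in unique(j$time_h)) {
    sel <- j$time_h == tt
    ratio <- j$R[sel] / law[sel]
    expect_lt(diff(range(ratio)), 1e-9)
  }
})
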