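#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults encode the
#' experimental regime the pipeline is designed for: a transcriptional
#' shutoff time course at 0/1/4/12 h with biological triplicate, roughly
#' 8% of mature species turning over fast (mostly star strands) with a
#' fast-pool half-life of 1 h and a residual stable pool, ultrafast
#' loop-derived reads, one dominant isoform per species (~90% of its reads),
#' negative-binomial replicate noise, and three constant spike-ins.
#'
#' @param n_hairpins number of hairpin precursors to simulate (each carries a
#'   5p and a 3p mature arm).
#' @param timepoints_h non-negative hours after shutoff; must include 0.
#' @param n_replicates biological replicates per timepoint.
#' @param depth expected mature-mapped reads per sample.
#' @param frac_fast fraction of mature species assigned fast (two-pool)
#'   turnover.
#' @param frac_fast_star_bias probability that a fast species is the star
#'   strand of its hairpin.
#' @param h_fast fast-pool half-life in hours.
#' @param stable_fraction_range interval from which the residual stable-pool
#'   fraction `F_slow` of a two-pool species is drawn uniformly.
#' @param h_slow half-life (hours) of the stable pool and of slow species;
#'   `Inf` means a pure plateau.
#' @param nb_dispersion negative-binomial dispersion of replicate counts
#'   (variance `mu + d*mu^2`); `0` switches the generator to a deterministic
#'   mode that emits the exact expected counts (useful for oracle tests).
#' @param dominant_isoform_frac fraction of a species' reads carried by its
#'   dominant (annotated) isoform; the remainder is spread over 5'/3'
#'   trimmed minor isoforms with geometrically decaying weights.
#' @param seq_bias named list of planted composition parameters; see
#'   [default_seq_bias()].
#' @param loop_halflife_h half-life of hairpin-loop reads (Dicer byproducts).
#' @param abundance_sdlog log-normal spread (sdlog) of per-hairpin abundance.
#' @param loop_abundance_frac 0-h loop-read abundance relative to the
#'   hairpin's non-star arm.
#' @param spikein_frac expected per-spike-in read count as a fraction of
#'   `depth`.
#' @param seed integer seed; identical configs give byte-identical output.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_hairpins = 200L,
                       timepoints_h = c(0, 1, 4, 12),
                       n_replicates = 3L,
                       depth = 2e6,
                       frac_fast = 0.08,
                       frac_fast_star_bias = 0.8,
                       h_fast = 1.0,
                       stable_fraction_range = c(0.05, 0.4),
                       h_slow = Inf,
                       nb_dispersion = 0.05,
                       dominant_isoform_frac = 0.9,
                       seq_bias = default_seq_bias(),
                       loop_halflife_h = 0.3,
                       abundance_sdlog = 1.0,
                       loop_abundance_frac = 0.05,
                       spikein_frac = 0.005,
                       seed = 1L) {
  cfg <- list(
    n_hairpins = as.integer(n_hairpins),
    timepoints_h = as.numeric(timepoints_h),
    n_replicates = as.integer(n_replicates),
    depth = depth,
    frac_fast = frac_fast,
    frac_fast_star_bias = frac_fast_star_bias,
    h_fast = h_fast,
    stable_fraction_range = stable_fraction_range,
    h_slow = h_slow,
    nb_dispersion = nb_dispersion,
    dominant_isoform_frac = dominant_isoform_frac,
    seq_bias = seq_bias,
    loop_halflife_h = loop_halflife_h,
    abundance_sdlog = abundance_sdlog,
    loop_abundance_frac = loop_abundance_frac,
    spikein_frac = spikein_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted sequence-composition bias
#'
#' Fast-turnover species are drawn with an elevated G/C and depleted U(T)
#' first base, an elevated C / depleted G last base, and an A-depleted
#' window at positions 13-16; slow species follow the background
#' composition with mildly opposite first/last-base skews. All other
#' positions use the uniform `background` distribution.
#'
#' @param a13_16_fast,a13_16_slow probability that each of positions 13-16
#'   is an A in fast resp. slow species.
#' @return named list with elements `background`, `first_fast`, `first_slow`,
#'   `last_fast`, `last_slow`, `a13_16_fast`, `a13_16_slow`.
#' @export
default_seq_bias <- function(a13_16_fast = 0.10, a13_16_slow = 0.35) {
  list(
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    first_fast = c(A = 0.25, C = 0.30, G = 0.30, T = 0.15),
    first_slow = c(A = 0.30, C = 0.15, G = 0.15, T = 0.40),
    last_fast  = c(A = 0.25, C = 0.35, G = 0.10, T = 0.30),
    last_slow  = c(A = 0.25, C = 0.20, G = 0.30, T = 0.25),
    a13_16_fast = a13_16_fast,
    a13_16_slow = a13_16_slow
  )
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_hairpins >= 0L, "n_hairpins must be >= 0")
  assert_that(all(cfg$timepoints_h >= 0), "timepoints must be non-negative")
  assert_that(0 %in% cfg$timepoints_h, "timepoints must include 0 h")
  assert_that(cfg$n_replicates >= 1L, "need at least one replicate")
  assert_that(cfg$depth > 0, "depth must be positive")
  assert_that(cfg$frac_fast > 0 && cfg$frac_fast < 1,
              "frac_fast must lie in (0, 1)")
  assert_that(cfg$frac_fast_star_bias >= 0 && cfg$frac_fast_star_bias <= 1,
              "frac_fast_star_bias must lie in [0, 1]")
  assert_that(cfg$h_fast > 0, "h_fast must be positive")
  assert_that(length(cfg$stable_fraction_range) == 2 &&
                all(cfg$stable_fraction_range >= 0) &&
                all(cfg$stable_fraction_range <= 1) &&
                diff(cfg$stable_fraction_range) >= 0,
              "stable_fraction_range must be an interval inside [0, 1]")
  assert_that(cfg$h_slow > 0, "h_slow must be positive (or Inf)")
  assert_that(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  assert_that(cfg$dominant_isoform_frac > 0 && cfg$dominant_isoform_frac <= 1,
              "dominant_isoform_frac must lie in (0, 1]")
  assert_that(cfg$loop_halflife_h > 0, "loop_halflife_h must be positive")
  for (nm in c("background", "first_fast", "first_slow",
               "last_fast", "last_slow")) {
    p <- cfg$seq_bias[[nm]]
    assert_that(!is.null(p) && length(p) == 4 && all(p >= 0) &&
                  abs(sum(p) - 1) < 1e-8 && all(BASES %in% names(p)),
                paste0("seq_bias$", nm,
                       " must be A/C/G/T probabilities summing to 1"))
  }
  for (nm in c("a13_16_fast", "a13_16_slow")) {
    p <- cfg$seq_bias[[nm]]
    assert_that(is.numeric(p) && p >= 0 && p <= 1,
                paste0("seq_bias$", nm, " must be a probability"))
  }
  invisible(cfg)
}

#' Analysis thresholds
#'
#' Bundles the filtering and classification thresholds used throughout the
#' pipeline. Defaults follow the quantification scheme the package
#' implements: reads of >= 15 nt mapped with zero mismatches, a detection
#' threshold of 5e-6 mean frequency in untreated samples, fast turnover
#' called below 50% (or 25%) remaining at 12 h with a nominal t-test
#' p < 0.05, slow turnover at >= 75% remaining with no significant change,
#' and 10,000 permutation iterations for positional composition tests.
#'
#' @param min_read_len minimum read length (nt) retained for mapping.
#' @param detect_threshold minimum mean 0-h frequency for an entity to count
#'   as reliably quantifiable.
#' @param max_nta maximum number of terminal 3' non-templated bases allowed
#'   in the optional mismatch-remapping pass.
#' @param fast50,fast25 remaining-fraction cutoffs at 12 h for the fast
#'   turnover classes.
#' @param slow75 minimum remaining fraction at 12 h for the slow class.
#' @param alpha nominal significance level of the per-entity t-tests.
#' @param perm_iterations Monte-Carlo iterations of the permutation test.
#' @param mature_window nt by which mature intervals are extended on both
#'   sides when assigning reads to a mature arm.
#' @param mature_overlap minimum fraction of a read that must lie within the
#'   extended mature interval.
#' @param ultrafast_r1 remaining fraction at 1 h at or below which an entity
#'   is called ultrafast.
#' @param aic_margin minimum AIC improvement of the two-phase over the
#'   single-exponential fit required to call two-step kinetics.
#' @param two_step_hfast_max maximum fitted fast-phase half-life (h) for a
#'   two-step call.
#' @param two_step_fslow_min minimum fitted stable-pool fraction for a
#'   two-step call.
#' @param hfast_bounds search bounds (hours) for the fast-phase half-life.
#' @param min_a minimum number of A's in the positions 13-16 window for the
#'   A-rich motif indicator.
#'
#' @return a validated list of class `threshold_config`.
#' @export
threshold_config <- function(min_read_len = 15L,
                             detect_threshold = 5e-6,
                             max_nta = 2L,
                             fast50 = 0.50,
                             fast25 = 0.25,
                             slow75 = 0.75,
                             alpha = 0.05,
                             perm_iterations = 10000L,
                             mature_window = 2L,
                             mature_overlap = 0.75,
                             ultrafast_r1 = 0.10,
                             aic_margin = 2,
                             two_step_hfast_max = 2,
                             two_step_fslow_min = 0.10,
                             hfast_bounds = c(0.05, 50),
                             min_a = 3L) {
  th <- list(
    min_read_len = as.integer(min_read_len),
    detect_threshold = detect_threshold,
    max_nta = as.integer(max_nta),
    fast50 = fast50, fast25 = fast25, slow75 = slow75,
    alpha = alpha,
    perm_iterations = as.integer(perm_iterations),
    mature_window = as.integer(mature_window),
    mature_overlap = mature_overlap,
    ultrafast_r1 = ultrafast_r1,
    aic_margin = aic_margin,
    two_step_hfast_max = two_step_hfast_max,
    two_step_fslow_min = two_step_fslow_min,
    hfast_bounds = hfast_bounds,
    min_a = as.integer(min_a)
  )
  class(th) <- "threshold_config"
  assert_that(th$detect_threshold > 0 && th$detect_threshold < 1,
              "detect_threshold must lie in (0, 1)")
  assert_that(th$fast25 < th$fast50 && th$fast50 < th$slow75,
              "need fast25 < fast50 < slow75")
  assert_that(th$alpha > 0 && th$alpha < 1, "alpha must lie in (0, 1)")
  assert_that(th$min_read_len >= 1L, "min_read_len must be >= 1")
  assert_that(th$max_nta >= 0L, "max_nta must be >= 0")
  assert_that(th$mature_overlap > 0 && th$mature_overlap <= 1,
              "mature_overlap must lie in (0, 1]")
  assert_that(th$perm_iterations > 0L, "perm_iterations must be positive")
  assert_that(length(th$hfast_bounds) == 2 && th$hfast_bounds[1] > 0 &&
                diff(th$hfast_bounds) > 0, "invalid hfast_bounds")
  th
}
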