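# Synthetic-data generator: truth-labelled hairpin references, shutoff
# time-course count tables with negative-binomial replicate noise, and
# bead-array style profiling matrices with spike-in rows.

# draw one mature sequence of length `len` with the planted composition of
# its turnover class ("fast" uses the biased distributions)
generate_mature_seq <- function(len, class, bias) {
  first_p <- if (class == "fast") bias$first_fast else bias$first_slow
  last_p <- if (class == "fast") bias$last_fast else bias$last_slow
  a_p <- if (class == "fast") bias$a13_16_fast else bias$a13_16_slow
  bg <- bias$background
  s <- sample(BASES, len, replace = TRUE, prob = bg[BASES])
  s[1] <- sample(BASES, 1, prob = first_p[BASES])
  s[len] <- sample(BASES, 1, prob = last_p[BASES])
  win <- 13:16
  win <- win[win > 1 & win < len]
  if (length(win) > 0) {
    non_a <- bg[c("C", "G", "T")] / sum(bg[c("C", "G", "T")])
    for (i in win) {
      s[i] <- if (runif(1) < a_p) "A" else
        sample(c("C", "G", "T"), 1, prob = non_a)
    }
  }
  paste(s, collapse = "")
}

#' Generate a truth-labelled synthetic hairpin reference
#'
#' Builds `n_hairpins` precursors (60-90 nt), each with a 5p and a 3p mature
#' arm (20-24 nt, mostly 22) separated by a loop, plus three spike-in
#' sequences that occur nowhere in the hairpins. A fixed number of mature
#' species (`round(frac_fast * 2 * n_hairpins)`) is labelled fast, drawn
#' preferentially from star strands; fast species receive the planted
#' first-base / last-base / central-A composition bias of
#' `config$seq_bias`, slow species the background composition. Star/non-star
#' roles are assigned per hairpin with a non-star:star abundance ratio of at
#' least 4:1.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference` with elements `reference`
#'   (a [mirna_reference()]), `spikeins` (named character vector of 3
#'   sequences), `truth_mature` and `truth_isoform` (truth tables), and
#'   `config`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_hairpins
  bias <- config$seq_bias

  if (n == 0L) {
    ref <- mirna_reference(
      tibble(hairpin_id = character(), sequence = character()),
      tibble(hairpin_id = character(), mature_id = character(),
             arm = character(), start = integer(), end = integer()))
    spike <- setNames(random_dna(3, 22, bias$background),
                      paste0("spikein_", 1:3))
    out <- list(reference = ref, spikeins = spike,
                truth_mature = tibble(), truth_isoform = tibble(),
                config = config)
    class(out) <- "sim_reference"
    return(out)
  }

  # per-species frame: two arms per hairpin
  species <- tibble(
    hairpin_id = rep(sprintf("hp%04d", seq_len(n)), each = 2),
    arm = rep(c("5p", "3p"), n),
    len = sample(20:24, 2 * n, replace = TRUE,
                 prob = c(0.05, 0.15, 0.55, 0.15, 0.10))
  )
  species$mature_id <- paste0("mir", sub("^hp", "", species$hairpin_id),
                              "-", species$arm)

  # strand roles: one non-star arm per hairpin, chosen at random
  nonstar_is_5p <- runif(n) < 0.5
  species$strand_role <- ifelse(
    rep(nonstar_is_5p, each = 2) == (species$arm == "5p"),
    "non_star", "star")

  # turnover classes: fixed count of fast species, biased toward stars
  n_species <- 2L * n
  n_fast <- max(1L, round(config$frac_fast * n_species))
  n_fast_star <- round(config$frac_fast_star_bias * n_fast)
  star_idx <- which(species$strand_role == "star")
  nonstar_idx <- which(species$strand_role == "non_star")
  n_fast_star <- min(n_fast_star, length(star_idx))
  fast_idx <- c(sample(star_idx, n_fast_star),
                sample(nonstar_idx, n_fast - n_fast_star))
  species$class <- "slow"
  species$class[fast_idx] <- "fast"

  # abundances: log-normal per hairpin; star strand down by >= 4-fold
  hairpin_abund <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  star_ratio <- 4 * exp(rexp(n, rate = 1.2))
  species$abundance <- rep(hairpin_abund, each = 2)
  is_star <- species$strand_role == "star"
  species$abundance[is_star] <-
    species$abundance[is_star] / rep(star_ratio, each = 2)[is_star]

  # kinetic truth
  rng <- config$stable_fraction_range
  species$f_slow <- ifelse(species$class == "fast",
                           runif(n_species, rng[1], rng[2]), NA_real_)
  species$h_fast <- ifelse(species$class == "fast", config$h_fast, NA_real_)
  species$h_slow <- config$h_slow

  # mature sequences, unique across the reference
  species$sequence <- vapply(seq_len(n_species), function(i) {
    generate_mature_seq(species$len[i], species$class[i], bias)
  }, character(1))
  for (tries in 1:200) {
    dup <- duplicated(species$sequence)
    if (!any(dup)) break
    species$sequence[dup] <- vapply(which(dup), function(i) {
      generate_mature_seq(species$len[i], species$class[i], bias)
    }, character(1))
  }
  assert_that(!anyDuplicated(species$sequence),
              "could not generate unique mature sequences")

  # hairpin scaffolds: flank5 + 5p + loop + 3p + flank3 (60-90 nt total)
  flank5 <- random_dna(n, sample(4:8, n, replace = TRUE), bias$background)
  flank3 <- random_dna(n, sample(4:8, n, replace = TRUE), bias$background)
  loops <- random_dna(n, sample(15:19, n, replace = TRUE), bias$background)
  m5 <- species$sequence[species$arm == "5p"]
  m3 <- species$sequence[species$arm == "3p"]
  hp_seq <- paste0(flank5, m5, loops, m3, flank3)

  start_5p <- nchar(flank5)
  end_5p <- start_5p + nchar(m5)
  start_3p <- end_5p + nchar(loops)
  end_3p <- start_3p + nchar(m3)

  hairpins <- tibble(hairpin_id = sprintf("hp%04d", seq_len(n)),
                     sequence = hp_seq)
  ann <- bind_rows(
    tibble(hairpin_id = hairpins$hairpin_id,
           mature_id = species$mature_id[species$arm == "5p"],
           arm = "5p", start = start_5p, end = end_5p),
    tibble(hairpin_id = hairpins$hairpin_id,
           mature_id = species$mature_id[species$arm == "3p"],
           arm = "3p", start = start_3p, end = end_3p)) |>
    arrange(.data$hairpin_id, .data$arm != "5p")
  ref <- mirna_reference(hairpins, ann)

  # spike-ins: absent from every hairpin
  spike <- character(0)
  while (length(spike) < 3) {
    cand <- random_dna(1, 22, bias$background)
    if (!any(grepl(cand, hp_seq, fixed = TRUE)) && !(cand %in% spike)) {
      spike <- c(spike, cand)
    }
  }
  spike <- setNames(spike, paste0("spikein_", 1:3))

  # planted-feature flags on the mature sequence
  a_count <- vapply(species$sequence, function(s) {
    if (nchar(s) < 16) return(NA_integer_)
    sum(strsplit(substr(s, 13, 16), "")[[1]] == "A")
  }, integer(1), USE.NAMES = FALSE)
  truth_mature <- species |>
    mutate(first_base = substr(.data$sequence, 1, 1),
           last_base = substr(.data$sequence, nchar(.data$sequence),
                              nchar(.data$sequence)),
           n_a_13_16 = a_count) |>
    select("mature_id", "hairpin_id", "arm", "strand_role", "class",
           "abundance", "f_slow", "h_fast", "h_slow", "sequence",
           "first_base", "last_base", "n_a_13_16")

  truth_isoform <- build_isoform_truth(truth_mature, config)

  out <- list(reference = ref, spikeins = spike,
              truth_mature = truth_mature,
              truth_isoform = truth_isoform,
              config = config)
  class(out) <- "sim_reference"
  out
}

# isoform spectrum: the dominant isoform is the annotated mature sequence;
# minor isoforms are 5'- or 3'-trimmed by 1-3 nt with geometrically decaying
# weights, renormalized to (1 - dominant_isoform_frac)
build_isoform_truth <- function(truth_mature, config) {
  trims <- tibble(
    off5 = c(1L, 2L, 3L, 0L, 0L, 0L),
    off3 = c(0L, 0L, 0L, -1L, -2L, -3L),
    w = 0.5^c(1:3, 1:3)
  )
  minor_total <- 1 - config$dominant_isoform_frac
  purrr::map_dfr(seq_len(nrow(truth_mature)), function(i) {
    sp <- truth_mature[i, ]
    len <- nchar(sp$sequence)
    tr <- trims |>
      mutate(sequence = substr(sp$sequence, 1 + .data$off5,
                               len + .data$off3)) |>
      filter(nchar(.data$sequence) >= 15)
    tr$w <- minor_total * tr$w / sum(tr$w)
    bind_rows(
      tibble(off5 = 0L, off3 = 0L, w = config$dominant_isoform_frac,
             sequence = sp$sequence),
      tr) |>
      mutate(mature_id = sp$mature_id, class = sp$class,
             iso_frac = .data$w, is_dominant = .data$off5 == 0L &
               .data$off3 == 0L) |>
      select("mature_id", "sequence", "off5", "off3", "iso_frac",
             "is_dominant", "class")
  })
}

#' Sample sheet for a simulated time course
#'
#' @param config a [sim_config()].
#' @return tibble with `sample_id`, `time_h`, `replicate`.
#' @export
sim_sample_sheet <- function(config) {
  tidyr::expand_grid(time_h = config$timepoints_h,
                     replicate = seq_len(config$n_replicates)) |>
    mutate(sample_id = sprintf("t%g_r%d", .data$time_h, .data$replicate)) |>
    select("sample_id", "time_h", "replicate")
}

# expected relative abundance (arbitrary units) of every emitted entity at
# every timepoint; the decay laws of the two-pool model live here
expected_abundance <- function(sim_ref, config) {
  truth <- sim_ref$truth_mature
  iso <- sim_ref$truth_isoform |>
    left_join(select(truth, "mature_id", "abundance", "f_slow",
                     "h_fast", "h_slow"),
              by = "mature_id")
  tp <- config$timepoints_h
  decay_m <- vapply(tp, function(t) {
    ifelse(iso$class == "fast",
           iso$f_slow * decay2(t, iso$h_slow) +
             (1 - iso$f_slow) * decay2(t, iso$h_fast),
           decay2(t, iso$h_slow))
  }, numeric(nrow(iso)))
  ab <- iso$abundance * iso$iso_frac
  mature_tbl <- tibble(entity_id = paste0(iso$mature_id, "|",
                                          iso$off5, "|", iso$off3),
                       sequence = iso$sequence,
                       kind = "mature")
  mature_e <- ab * decay_m

  # loop reads: the exact loop interval sequence, ultrafast decay
  loopseq <- sim_ref$reference$loops |>
    left_join(select(sim_ref$reference$hairpins, "hairpin_id", "sequence"),
              by = "hairpin_id") |>
    filter(!is.na(.data$start), .data$end - .data$start >= 15) |>
    mutate(loop_seq = substr(.data$sequence, .data$start + 1, .data$end))
  nonstar_ab <- truth |>
    filter(.data$strand_role == "non_star") |>
    select("hairpin_id", "abundance")
  loopseq <- loopseq |> left_join(nonstar_ab, by = "hairpin_id")
  loop_e <- outer(config$loop_abundance_frac * loopseq$abundance,
                  decay2(tp, config$loop_halflife_h))
  loop_tbl <- tibble(entity_id = paste0("loop|", loopseq$hairpin_id),
                     sequence = loopseq$loop_seq,
                     kind = "loop")

  spike_tbl <- tibble(entity_id = names(sim_ref$spikeins),
                      sequence = unname(sim_ref$spikeins),
                      kind = "spikein")
  spike_e <- matrix(1, nrow = length(sim_ref$spikeins), ncol = length(tp))

  list(entities = bind_rows(mature_tbl, loop_tbl, spike_tbl),
       expected = rbind(mature_e, loop_e, spike_e),
       timepoints = tp)
}

#' Simulate a shutoff time-course read-count table
#'
#' Converts the truth-labelled reference into per-sample counts of unique
#' read sequences. The expected relative abundance of species `i` at time
#' `t` is `A_i * [F_slow * 2^(-t/h_slow) + (1 - F_slow) * 2^(-t/h_fast)]`
#' for two-pool (fast) species, `A_i * 2^(-t/h_slow)` for slow species, and
#' decays with `loop_halflife_h` for loop reads; spike-ins are constant.
#' Counts are scaled so that the expected mature-mapped total of each
#' sample equals `config$depth`, then drawn negative-binomially with
#' dispersion `config$nb_dispersion` (`0` = deterministic expected counts).
#'
#' @param sim_ref output of [generate_reference()].
#' @param config a [sim_config()]; defaults to the one stored in `sim_ref`.
#' @return list of class `sim_timecourse` with `counts` (wide tibble:
#'   `sequence` then one integer column per sample), `expected` (per-entity
#'   expected relative abundance by timepoint, unnormalized), `samples`
#'   (sample sheet) and `truth_isoform`.
#' @export
simulate_timecourse <- function(sim_ref, config = sim_ref$config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  samples <- sim_sample_sheet(config)
  ea <- expected_abundance(sim_ref, config)
  ent <- ea$entities
  is_mature <- ent$kind == "mature"
  is_spike <- ent$kind == "spikein"

  counts <- matrix(0, nrow = nrow(ent), ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    ti <- match(samples$time_h[j], ea$timepoints)
    e <- ea$expected[, ti]
    mature_total <- sum(e[is_mature])
    mu <- config$depth * e / mature_total
    mu[is_spike] <- config$spikein_frac * config$depth
    if (config$nb_dispersion > 0) {
      counts[, j] <- rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion)
    } else {
      counts[, j] <- mu
    }
  }

  # distinct entities can in principle share a read sequence; collapse
  cnt <- as_tibble(counts) |>
    mutate(sequence = ent$sequence) |>
    group_by(.data$sequence) |>
    summarise(across(everything(), sum), .groups = "drop")

  expected_tbl <- as_tibble(ea$expected,
                            .name_repair = ~ paste0("t", ea$timepoints)) |>
    mutate(entity_id = ent$entity_id, sequence = ent$sequence,
           kind = ent$kind) |>
    select("entity_id", "sequence", "kind", everything())

  out <- list(counts = select(cnt, "sequence", everything()),
              expected = expected_tbl,
              samples = samples,
              truth_isoform = sim_ref$truth_isoform,
              config = config)
  class(out) <- "sim_timecourse"
  out
}

#' Expand a simulated count table into per-sample read FASTA files
#'
#' Writes one FASTA per sample with one record per read occurrence, i.e.
#' a sequence observed `k` times yields `k` records. Intended for small
#' simulated depths (fixture generation); counts are rounded to integers.
#'
#' @param sim a `sim_timecourse`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of file paths.
#' @export
write_reads_fasta <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(
    file.path(dir, paste0(sim$samples$sample_id, ".fasta")),
    sim$samples$sample_id)
  for (s in sim$samples$sample_id) {
    k <- round(sim$counts[[s]])
    seqs <- rep(sim$counts$sequence, k)
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- sprintf("%s_read%07d", s, seq_along(ss))
    Biostrings::writeXStringSet(ss, paths[[s]])
  }
  invisible(paths)
}

#' Simulate a bead-array profiling intensity matrix with spike-in rows
#'
#' Each sample's intensities are `scale_s * expected abundance * lognormal
#' noise`; three spike-in rows are `scale_s * constant`. The per-sample
#' scale factors emulate varying RNA input and are recorded in the truth so
#' that [spikein_normalize()] can be validated by round trip.
#'
#' @param config a [sim_config()]; profiling uses its own timepoint grid.
#' @param timepoints_h profiling timepoints (hours).
#' @param noise_sd sdlog of the multiplicative log-normal noise (0 = none).
#' @param scale_sdlog sdlog of the per-sample scale factors (0 = all 1).
#' @return a [profiling_matrix()] whose `truth` element records the scale
#'   factors and the generating reference.
#' @export
simulate_profiling_matrix <- function(config,
                                      timepoints_h = c(0, 2, 4, 6, 12, 24),
                                      noise_sd = 0.1,
                                      scale_sdlog = 0.3) {
  validate_sim_config(config)
  sim_ref <- generate_reference(config)
  set.seed(config$seed + 2L)
  truth <- sim_ref$truth_mature
  samples <- tidyr::expand_grid(time_h = timepoints_h,
                                replicate = seq_len(config$n_replicates)) |>
    mutate(sample_id = sprintf("t%g_r%d", .data$time_h, .data$replicate)) |>
    select("sample_id", "time_h", "replicate")
  n_s <- nrow(samples)
  scale_s <- if (scale_sdlog > 0) rlnorm(n_s, 0, scale_sdlog) else rep(1, n_s)

  decay_m <- vapply(samples$time_h, function(t) {
    ifelse(truth$class == "fast",
           truth$f_slow * decay2(t, truth$h_slow) +
             (1 - truth$f_slow) * decay2(t, truth$h_fast),
           decay2(t, truth$h_slow))
  }, numeric(nrow(truth)))
  base <- truth$abundance * decay_m
  spike_base <- matrix(1, nrow = 3, ncol = n_s)
  m <- rbind(base, spike_base)
  m <- sweep(m, 2, scale_s, `*`)
  if (noise_sd > 0) {
    m <- m * matrix(rlnorm(length(m), 0, noise_sd), nrow = nrow(m))
  }
  rownames(m) <- c(truth$mature_id, names(sim_ref$spikeins))
  colnames(m) <- samples$sample_id
  probe_class <- setNames(c(rep("mature", nrow(truth)), rep("spikein", 3)),
                          rownames(m))
  pm <- profiling_matrix(m, probe_class, samples)
  pm$truth <- list(scale_factors = setNames(scale_s, samples$sample_id),
                   sim_ref = sim_ref)
  pm
}
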