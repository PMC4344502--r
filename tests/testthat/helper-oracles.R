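# Independent oracles used by the test suite. These deliberately share no
# code with the package internals they check.

# Brute-force read assignment: scan every read against every position of
# every hairpin and apply the region rules directly.
oracle_assign_reads <- function(read_seqs, hairpins, matures, loops,
                                min_len = 15, window = 2, overlap = 0.75) {
  rows <- list()
  for (rs in read_seqs) {
    L <- nchar(rs)
    if (L < min_len) next
    for (h in seq_len(nrow(hairpins))) {
      hseq <- hairpins$sequence[h]
      hid <- hairpins$hairpin_id[h]
      if (nchar(hseq) < L) next
      for (s in 0:(nchar(hseq) - L)) {
        if (substr(hseq, s + 1, s + L) != rs) next
        e <- s + L
        # region by the overlap rule
        marms <- matures[matures$hairpin_id == hid, ]
        best_frac <- -1; best <- NULL
        for (k in seq_len(nrow(marms))) {
          lo <- marms$start[k] - window; hi <- marms$end[k] + window
          ov <- max(0, min(e, hi) - max(s, lo))
          frac <- ov / L
          if (frac >= overlap &&
              (frac > best_frac ||
               (frac == best_frac && marms$arm[k] == "5p" &&
                !is.null(best) && best$arm != "5p"))) {
            best_frac <- frac; best <- marms[k, ]
          }
        }
        if (!is.null(best)) {
          rows[[length(rows) + 1]] <- data.frame(
            sequence = rs, hairpin_id = hid, region = paste0("mature",
                                                             best$arm),
            mature_id = best$mature_id, stringsAsFactors = FALSE)
        } else {
          lp <- loops[loops$hairpin_id == hid, ]
          in_loop <- nrow(lp) == 1 && !is.na(lp$start) &&
            s >= lp$start && e <= lp$end
          rows[[length(rows) + 1]] <- data.frame(
            sequence = rs, hairpin_id = hid,
            region = if (in_loop) "loop" else "other",
            mature_id = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(0), hairpin_id = character(0),
                      region = character(0), mature_id = character(0)))
  }
  unique(do.call(rbind, rows))
}

# Two-sided Fisher exact p by direct enumeration with log-choose
# probabilities (no dhyper).
oracle_fisher_p <- function(a, b, c_, d_) {
  m <- a + c_; n <- b + d_; k <- a + b
  if (m == 0 || n == 0 || k == 0 || (c_ + d_) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Exact permutation p by enumerating every subset of the pool.
oracle_perm_p_exact <- function(feature, n_fast, observed) {
  idx <- utils::combn(length(feature), n_fast)
  counts <- apply(idx, 2, function(i) sum(feature[i]))
  expected <- n_fast * mean(feature)
  if (observed > expected) mean(counts >= observed)
  else if (observed < expected) mean(counts <= observed)
  else 1
}

# Tiny deterministic reference shared by quantification tests: two
# hairpins, hand-placed arms, one duplicated mature sequence pair.
toy_reference <- function() {
  m5a <- "ACGTACGTACGTACGTACGTAC"          # 22 nt
  m3a <- "TTGCAGGCAGTTGCAGGCAGTT"          # 22 nt
  loopa <- "CCCCCGGGGGCCCCCGG"             # 17 nt
  m5b <- "GGATCCGGATCCGGATCCGGAT"          # 22 nt
  m3b <- "CAACTGCAACTGCAACTGCAAC"          # 22 nt
  loopb <- "AAAAATTTTTAAAAATT"
  hp <- tibble::tibble(
    hairpin_id = c("hpA", "hpB"),
    sequence = c(paste0("GGGGG", m5a, loopa, m3a, "GGGGG"),
                 paste0("TTTTT", m5b, loopb, m3b, "TTTTT")))
  ann <- tibble::tibble(
    hairpin_id = c("hpA", "hpA", "hpB", "hpB"),
    mature_id = c("mirA-5p", "mirA-3p", "mirB-5p", "mirB-3p"),
    arm = c("5p", "3p", "5p", "3p"),
    start = c(5L, 5L + 22L + 17L, 5L, 5L + 22L + 17L),
    end = c(27L, 5L + 22L + 17L + 22L, 27L, 5L + 22L + 17L + 22L))
  mirna_reference(hp, ann)
}

# sample sheet for hand-built frequency fixtures
toy_samples <- function(times = c(0, 4, 12), reps = 3) {
  tidyr::expand_grid(time_h = times, replicate = seq_len(reps)) |>
    dplyr::mutate(sample_id = sprintf("t%g_r%d", time_h, replicate)) |>
    dplyr::select(sample_id, time_h, replicate)
}

# wide one-entity frequency table from per-timepoint replicate values
toy_freq_tbl <- function(values, samples, id = "x") {
  stopifnot(length(values) == nrow(samples))
  out <- tibble::tibble(entity_id = id)
  for (i in seq_len(nrow(samples))) out[[samples$sample_id[i]]] <- values[i]
  out
}
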