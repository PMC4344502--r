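# Positional nucleotide composition of fast vs slow turnover isoforms:
# Fisher's exact test, permutation null, A-rich central window, lengths.

#' Build the fast/slow isoform sets from turnover calls
#'
#' @param calls isoform-level output of [classify_turnover()] or
#'   [turnover_calls()] where `entity_id` is the isoform sequence.
#' @return list of class `grouped_isoform_sets` with character vectors
#'   `$fast` (classes `fast_lt25`/`fast_lt50`) and `$slow` (class `slow`);
#'   intermediate and unclassified isoforms are excluded.
#' @export
grouped_isoform_sets <- function(calls) {
  fast <- calls$entity_id[calls$turnover_class %in%
                            c("fast_lt25", "fast_lt50")]
  slow <- calls$entity_id[calls$turnover_class == "slow"]
  out <- list(fast = unique(fast), slow = unique(slow))
  class(out) <- "grouped_isoform_sets"
  out
}

# nucleotide at 1-based position `pos` of each sequence, or its last base
# when pos == "last"; NA for sequences shorter than pos
base_at <- function(seqs, pos) {
  if (identical(pos, "last")) {
    return(substr(seqs, nchar(seqs), nchar(seqs)))
  }
  pos <- as.integer(pos)
  out <- substr(seqs, pos, pos)
  out[out == ""] <- NA_character_
  out
}

#' Positional nucleotide composition of two isoform sets
#'
#' Counts each nucleotide at each requested position (1-based from the 5'
#' end; `"last"` denotes the final base of each sequence) in the fast and
#' slow sets. Sequences shorter than a position are excluded from that
#' position's tally. `position = "total"` aggregates over all positions of
#' all sequences.
#'
#' @param sets a [grouped_isoform_sets()] (or list with `$fast`, `$slow`).
#' @param positions integer positions and/or `"last"`, `"total"`.
#' @return tibble with `position`, `nucleotide`, `count_fast`, `count_slow`,
#'   `n_fast`, `n_slow` (set sizes at that position), `freq_fast`,
#'   `freq_slow`, `freq_ratio` (fast/slow).
#' @export
positional_composition <- function(sets, positions = c(1:22, "last")) {
  assert_that(length(sets$fast) > 0 && length(sets$slow) > 0,
              "both isoform sets must be non-empty")
  count_set <- function(seqs, pos) {
    if (identical(pos, "total")) {
      b <- unlist(strsplit(seqs, ""))
    } else {
      b <- base_at(seqs, pos)
      b <- b[!is.na(b)]
    }
    n <- length(b)
    cnt <- table(factor(b, levels = BASES))
    tibble(nucleotide = BASES, count = as.integer(cnt), n = n)
  }
  purrr::map_dfr(positions, function(p) {
    f <- count_set(sets$fast, p)
    s <- count_set(sets$slow, p)
    tibble(position = as.character(p), nucleotide = f$nucleotide,
           count_fast = f$count, count_slow = s$count,
           n_fast = f$n, n_slow = s$n)
  }) |>
    mutate(freq_fast = .data$count_fast / .data$n_fast,
           freq_slow = .data$count_slow / .data$n_slow,
           freq_ratio = .data$freq_fast / .data$freq_slow)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric enumeration: with margins fixed, the p-value is the
#' sum of the probabilities of all tables whose probability does not exceed
#' that of the observed table (up to a 1e-7 relative tolerance for
#' floating-point ties). Zero-margin tables return 1.
#'
#' @param a,b,c_,d_ cell counts: `a` = feature present in fast set, `b` =
#'   absent in fast, `c_` = present in slow, `d_` = absent in slow.
#' @return the two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c_, d_) {
  assert_that(all(c(a, b, c_, d_) >= 0), "cell counts must be >= 0")
  m <- a + c_        # feature-present margin
  n <- b + d_        # feature-absent margin
  k <- a + b         # fast-set size
  if (m == 0 || n == 0 || k == 0 || (c_ + d_) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo permutation p-value: draw `n_fast`-sized subsets of the pool
# (without replacement) and count how often the feature count is as or more
# extreme than observed, one-sided in the observed direction. Returns the
# p-value, the direction, and the permutation counts.
permutation_p <- function(feature, n_fast, observed, iterations) {
  assert_that(iterations > 0, "iterations must be positive")
  pool_n <- length(feature)
  expected <- n_fast * mean(feature)
  direction <- if (observed > expected) "enriched"
               else if (observed < expected) "depleted" else "none"
  counts <- vapply(seq_len(iterations), function(i) {
    sum(feature[sample.int(pool_n, n_fast)])
  }, numeric(1))
  hits <- switch(direction,
                 enriched = sum(counts >= observed),
                 depleted = sum(counts <= observed),
                 none = iterations)
  list(p = hits / iterations, direction = direction,
       perm_mean = mean(counts), perm_sd = sd(counts))
}

#' Fisher and permutation tests of positional nucleotide enrichment
#'
#' For every nucleotide at a position, builds the 2x2 table (nucleotide
#' yes/no x fast/slow), computes the two-sided Fisher exact p-value by
#' hypergeometric enumeration, and estimates a permutation p-value by
#' repeatedly drawing `|fast|` isoforms from the pooled fast+slow set and
#' counting iterations with a nucleotide frequency as or more extreme than
#' observed (one-sided in the observed direction, no pseudocount; a zero
#' count therefore reports p = 0 with a 1/M resolution floor noted in the
#' `p_perm_floor` column).
#'
#' @param sets a [grouped_isoform_sets()].
#' @param positions positions to test (integers and/or `"last"`).
#' @param iterations Monte-Carlo iterations `M`.
#' @param seed integer seed for the permutation RNG.
#' @return tibble of per-(position, nucleotide) statistics: counts,
#'   frequencies, `fisher_p`, `perm_p`, `p_perm_floor` (= 1/M), `direction`.
#' @export
position_enrichment_test <- function(sets, positions = c(1, "last"),
                                     iterations = 10000L, seed = 1L) {
  comp <- positional_composition(sets, positions)
  set.seed(seed)
  out <- purrr::map_dfr(unique(comp$position), function(p) {
    rows <- comp |> filter(.data$position == p)
    fast_b <- base_at(sets$fast, if (p == "last") "last" else p)
    slow_b <- base_at(sets$slow, if (p == "last") "last" else p)
    fast_b <- fast_b[!is.na(fast_b)]
    slow_b <- slow_b[!is.na(slow_b)]
    pool <- c(fast_b, slow_b)
    purrr::map_dfr(BASES, function(nt) {
      r <- rows |> filter(.data$nucleotide == nt)
      fisher <- fisher_exact_p(r$count_fast, r$n_fast - r$count_fast,
                               r$count_slow, r$n_slow - r$count_slow)
      perm <- permutation_p(pool == nt, length(fast_b), r$count_fast,
                            iterations)
      r |> mutate(fisher_p = fisher, perm_p = perm$p,
                  p_perm_floor = 1 / iterations,
                  direction = perm$direction)
    })
  })
  out
}

#' A-rich motif statistic for a central window
#'
#' Computes per-position A frequencies for the window (default positions
#' 13-16) in each set, plus a motif-level indicator (at least `min_a` A's in
#' the window) tested with Fisher's exact test and the permutation null.
#' Sequences shorter than the window's end are excluded from the window
#' statistic and reported in the exclusion tally.
#'
#' @param sets a [grouped_isoform_sets()].
#' @param window integer vector `c(first, last)` of 1-based positions.
#' @param min_a minimum number of A's for the motif indicator.
#' @param iterations,seed permutation settings.
#' @return list with `motif` (one-row tibble of motif-level counts and
#'   p-values), `per_position` (per-position A statistics from
#'   [position_enrichment_test()], A rows only), `excluded` (sequences too
#'   short, per set).
#' @export
a_rich_motif_stat <- function(sets, window = c(13, 16), min_a = 3L,
                              iterations = 10000L, seed = 1L) {
  wpos <- seq(window[1], window[2])
  count_a <- function(seqs) {
    keep <- nchar(seqs) >= window[2]
    sub <- substr(seqs[keep], window[1], window[2])
    n_a <- nchar(sub) - nchar(gsub("A", "", sub, fixed = TRUE))
    list(n_a = n_a, n_excluded = sum(!keep))
  }
  f <- count_a(sets$fast)
  s <- count_a(sets$slow)
  assert_that(length(f$n_a) > 0 && length(s$n_a) > 0,
              "window lies beyond every sequence in a set")
  a <- sum(f$n_a >= min_a); b <- length(f$n_a) - a
  c_ <- sum(s$n_a >= min_a); d_ <- length(s$n_a) - c_
  fisher <- fisher_exact_p(a, b, c_, d_)
  set.seed(seed)
  perm <- permutation_p(c(f$n_a, s$n_a) >= min_a, length(f$n_a), a,
                        iterations)
  motif <- tibble(
    window = paste(window, collapse = "-"), min_a = min_a,
    count_fast = a, n_fast = length(f$n_a),
    count_slow = c_, n_slow = length(s$n_a),
    freq_fast = a / length(f$n_a), freq_slow = c_ / length(s$n_a),
    fisher_p = fisher, perm_p = perm$p, p_perm_floor = 1 / iterations,
    direction = perm$direction)
  per_position <- position_enrichment_test(sets, positions = wpos,
                                           iterations = iterations,
                                           seed = seed + 1L) |>
    filter(.data$nucleotide == "A")
  list(motif = motif, per_position = per_position,
       excluded = c(fast = f$n_excluded, slow = s$n_excluded))
}

#' Length distributions of the fast and slow isoform sets
#'
#' @param sets a [grouped_isoform_sets()].
#' @return list with `histogram` (tibble `set`, `length`, `n`) and `modes`
#'   (named vector of modal lengths).
#' @export
length_distribution <- function(sets) {
  hist_tbl <- bind_rows(
    tibble(set = "fast", length = nchar(sets$fast)),
    tibble(set = "slow", length = nchar(sets$slow))) |>
    count(.data$set, .data$length, name = "n")
  modes <- hist_tbl |>
    group_by(.data$set) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup()
  list(histogram = hist_tbl,
       modes = setNames(modes$length, modes$set))
}
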