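# Read-to-hairpin assignment by exact substring matching, isoform counting,
# frequency normalization, detection filtering and star-strand annotation.

# Enumerate all substrings of the hairpins whose lengths occur in `lens`;
# returns a tibble (sequence, hairpin_id, start) used as a hash join target.
# This trades memory (~ n_hairpins * n_lengths * hairpin_length rows) for a
# single vectorized join instead of a per-read scan.
hairpin_substring_index <- function(reference, lens) {
  hp <- reference$hairpins
  lens <- sort(unique(lens))
  parts <- lapply(lens, function(L) {
    ok <- hp$length >= L
    if (!any(ok)) return(NULL)
    n_starts <- hp$length[ok] - L + 1L
    seqs <- rep.int(hp$sequence[ok], n_starts)
    start <- sequence(n_starts) - 1L
    list(sequence = substring(seqs, start + 1L, start + L),
         hairpin_id = rep.int(hp$hairpin_id[ok], n_starts),
         start = start)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(tibble(sequence = character(0), hairpin_id = character(0),
                  start = integer(0)))
  }
  tibble(
    sequence = unlist(lapply(parts, `[[`, "sequence"), use.names = FALSE),
    hairpin_id = unlist(lapply(parts, `[[`, "hairpin_id"),
                        use.names = FALSE),
    start = unlist(lapply(parts, `[[`, "start"), use.names = FALSE))
}

# classify one match (start, len) on a hairpin into mature5p/mature3p/loop/
# other following the overlap rule: >= `overlap` of the read inside the
# mature interval extended by `window` nt on each side wins (larger overlap
# breaks ties, then 5p); loops must contain the read entirely.
classify_matches <- function(matches, reference, window, overlap) {
  if (nrow(matches) == 0) {
    return(mutate(matches, region = character(0), mature_id = character(0),
                  group_id = integer(0), off5 = integer(0),
                  off3 = integer(0)))
  }
  mat <- reference$matures
  loops <- reference$loops
  m <- matches |>
    mutate(.row = seq_len(n()), end = .data$start + .data$len) |>
    left_join(mat |>
                select("hairpin_id", "mature_id", "arm", "group_id",
                       m_start = "start", m_end = "end"),
              by = "hairpin_id", relationship = "many-to-many") |>
    mutate(
      ov = pmax(0, pmin(.data$end, .data$m_end + window) -
                  pmax(.data$start, .data$m_start - window)),
      frac = .data$ov / .data$len)
  best <- m |>
    filter(.data$frac >= overlap) |>
    group_by(.data$.row) |>
    arrange(desc(.data$frac), .data$arm != "5p", .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    transmute(.row = .data$.row,
              region = paste0("mature", .data$arm),
              mature_id = .data$mature_id,
              group_id = .data$group_id,
              off5 = as.integer(.data$start - .data$m_start),
              off3 = as.integer(.data$end - .data$m_end))
  out <- matches |>
    mutate(.row = seq_len(n()), end = .data$start + .data$len) |>
    left_join(best, by = ".row") |>
    left_join(loops |> rename(l_start = "start", l_end = "end"),
              by = "hairpin_id")
  out |>
    mutate(
      in_loop = !is.na(.data$l_start) & .data$start >= .data$l_start &
        .data$end <= .data$l_end,
      region = case_when(
        !is.na(.data$region) ~ .data$region,
        .data$in_loop ~ "loop",
        TRUE ~ "other")) |>
    select(-".row", -"l_start", -"l_end", -"in_loop", -"end")
}

# normalize the `reads` argument (per-sample character vectors / DNAStringSet
# / a wide count table) to a wide unique-sequence count table
as_count_table <- function(reads) {
  if (is.data.frame(reads)) {
    assert_that("sequence" %in% names(reads),
                "count table needs a 'sequence' column")
    return(as_tibble(reads))
  }
  assert_that(is.list(reads) && !is.null(names(reads)),
              "reads must be a named list of per-sample sequences or a count table")
  tabs <- purrr::imap(reads, function(x, nm) {
    x <- as.character(x)
    tb <- table(x)
    tibble(sequence = names(tb), n = as.integer(tb)) |>
      mutate(sample_id = nm)
  })
  bind_rows(tabs) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
}

#' Assign reads to hairpins and count sequence isoforms
#'
#' Pass 1 keeps reads of length >= `thresholds$min_read_len` that occur as
#' exact substrings of a hairpin; each match is classified as `mature5p`,
#' `mature3p` (>= 75% of the read within the mature interval extended by
#' 2 nt), `loop` (entirely inside the loop interval) or `other`. A read
#' matching several hairpins is counted once per distinct mature sequence
#' group and flagged `multimapped`; per-sample totals count each read once.
#' With `nta = TRUE` a second pass matches remaining reads exactly except
#' for up to `max_nta` terminal 3' bases, recorded as a non-templated
#' addition (NTA) suffix.
#'
#' @param reads a named list of per-sample read sequence vectors (or
#'   `DNAStringSet`s), or a pre-made wide count table with a `sequence`
#'   column and one count column per sample.
#' @param reference a [mirna_reference()].
#' @param thresholds a [threshold_config()].
#' @param nta enable the 3' mismatch remapping pass (off by default).
#' @return an `isoform_counts` object: a tibble with one row per (sequence,
#'   mature group) assignment — columns `sequence`, `hairpin_id`, `region`,
#'   `mature_id`, `group_id`, `off5`, `off3`, `nta`, `multimapped`, then one
#'   count column per sample. Attributes: `samples` (sample names),
#'   `discarded` (reads shorter than the minimum, per sample),
#'   `unassigned` (eligible but unmatched reads, per sample).
#' @export
quantify_reads <- function(reads, reference, thresholds = threshold_config(),
                           nta = FALSE) {
  assert_that(nrow(reference$hairpins) > 0, "empty reference")
  counts <- as_count_table(reads)
  counts$sequence <- canonical_dna(counts$sequence, "read sequence")
  counts <- counts |>
    group_by(.data$sequence) |>
    summarise(across(where(is.numeric), sum), .groups = "drop")
  sample_names <- setdiff(names(counts), "sequence")
  assert_that(length(sample_names) > 0, "no sample count columns found")

  len <- nchar(counts$sequence)
  short <- counts[len < thresholds$min_read_len, ]
  eligible <- counts[len >= thresholds$min_read_len, ]

  idx <- hairpin_substring_index(reference,
                                 unique(nchar(eligible$sequence)))
  matches <- eligible |>
    select("sequence") |>
    mutate(len = nchar(.data$sequence)) |>
    inner_join(idx, by = "sequence", relationship = "many-to-many")
  assigned <- classify_matches(matches, reference,
                               thresholds$mature_window,
                               thresholds$mature_overlap) |>
    mutate(nta = "")

  unmatched <- eligible |>
    filter(!.data$sequence %in% assigned$sequence)

  if (nta && nrow(unmatched) > 0 && thresholds$max_nta > 0) {
    nta_rows <- nta_remap(unmatched$sequence, reference, thresholds, idx)
    assigned <- bind_rows(assigned, nta_rows)
    unmatched <- unmatched |>
      filter(!.data$sequence %in% nta_rows$sequence)
  }

  # one row per distinct mature sequence group; loop/other: one row total
  dedup <- assigned |>
    mutate(key = ifelse(grepl("^mature", .data$region),
                        paste0("g", .data$group_id), .data$region),
           rank = ifelse(grepl("^mature", .data$region), 1L,
                         ifelse(.data$region == "loop", 2L, 3L))) |>
    group_by(.data$sequence) |>
    mutate(n_group = n_distinct(.data$key[grepl("^mature", .data$region)])) |>
    # mature assignments take precedence over loop, loop over other
    filter(.data$rank == min(.data$rank)) |>
    arrange(.data$region, .data$hairpin_id, .by_group = TRUE) |>
    distinct(.data$key, .keep_all = TRUE) |>
    mutate(multimapped = .data$n_group > 1) |>
    ungroup() |>
    select(-"key", -"rank", -"n_group", -"len")

  out <- dedup |>
    left_join(eligible, by = "sequence") |>
    arrange(.data$hairpin_id, .data$mature_id, .data$off5, .data$off3)
  attr(out, "samples") <- sample_names
  attr(out, "discarded") <- colSums(short[sample_names])
  attr(out, "unassigned") <- colSums(unmatched[sample_names])
  class(out) <- c("isoform_counts", class(out))
  out
}

# pass 2: exact prefix match with k = 1..max_nta trailing bases that either
# mismatch the hairpin or run past its 3' end; the suffix is the NTA
nta_remap <- function(seqs, reference, thresholds, idx = NULL) {
  hp <- setNames(reference$hairpins$sequence, reference$hairpins$hairpin_id)
  rows <- list()
  for (k in seq_len(thresholds$max_nta)) {
    if (length(seqs) == 0) break
    plen <- nchar(seqs) - k
    ok <- plen >= thresholds$min_read_len
    if (!any(ok)) next
    pref <- substr(seqs[ok], 1, plen[ok])
    have <- if (is.null(idx) || nrow(idx) == 0) integer(0) else
      unique(nchar(idx$sequence))
    if (all(unique(nchar(pref)) %in% have)) {
      idx_k <- idx
    } else {
      idx_k <- hairpin_substring_index(reference, unique(nchar(pref)))
    }
    m <- tibble(sequence = seqs[ok], prefix = pref,
                len = nchar(pref) + k) |>
      inner_join(idx_k |> rename(prefix = "sequence"),
                 by = "prefix", relationship = "many-to-many")
    if (nrow(m) == 0) next
    # templated continuation of the hairpin after the matched prefix
    hp_len <- nchar(hp[m$hairpin_id])
    cont <- substr(hp[m$hairpin_id], m$start + nchar(m$prefix) + 1,
                   pmin(m$start + nchar(m$prefix) + k, hp_len))
    suffix <- substr(m$sequence, nchar(m$prefix) + 1, nchar(m$sequence))
    keep <- cont != suffix  # identical continuation would be a pass-1 match
    m <- m[keep, ]
    if (nrow(m) == 0) next
    # classify on the matched prefix footprint; keep the full read as key
    cls <- classify_matches(
      m |> transmute(sequence = .data$sequence,
                     len = nchar(.data$prefix),
                     hairpin_id = .data$hairpin_id,
                     start = .data$start),
      reference, thresholds$mature_window, thresholds$mature_overlap)
    cls$nta <- substr(m$sequence, nchar(m$prefix) + 1, nchar(m$sequence))
    rows[[k]] <- cls
    seqs <- setdiff(seqs, cls$sequence)
  }
  if (length(rows) == 0) {
    return(tibble(sequence = character(0), len = integer(0),
                  hairpin_id = character(0), start = integer(0),
                  region = character(0), mature_id = character(0),
                  group_id = integer(0), off5 = integer(0),
                  off3 = integer(0), nta = character(0)))
  }
  bind_rows(rows)
}

#' Normalize isoform counts to frequencies and apply the detection filter
#'
#' Frequencies are reads divided by the total mature-mapped reads of the
#' sample (loop and `other` reads are excluded from the denominator; every
#' mature-mapped read counts exactly once, so isoform frequencies sum to 1
#' per sample). Mature-level frequencies are the sum over a mature group's
#' isoforms. An entity is flagged `detected` when its mean frequency over
#' the 0-h samples is at least `thresholds$detect_threshold`.
#'
#' @param counts an `isoform_counts` from [quantify_reads()].
#' @param samples sample sheet tibble (`sample_id`, `time_h`, `replicate`).
#' @param thresholds a [threshold_config()].
#' @return list of class `frequency_matrix` with wide tibbles `$isoform`
#'   (key `sequence`; one frequency column per sample; `detected` flag) and
#'   `$mature` (key `group_id`/`mature_id`), plus `$totals` (mature-mapped
#'   reads per sample) and `$samples`.
#' @export
compute_frequencies <- function(counts, samples,
                                thresholds = threshold_config()) {
  sn <- attr(counts, "samples") %||% setdiff(names(counts),
    c("sequence", "hairpin_id", "region", "mature_id", "group_id",
      "off5", "off3", "nta", "multimapped", "start", "len"))
  samples <- as_tibble(samples)
  assert_that(all(samples$sample_id %in% sn),
              "sample sheet names samples missing from the count table")
  sn <- samples$sample_id
  zero_h <- samples$sample_id[samples$time_h == 0]
  assert_that(length(zero_h) > 0, "need at least one 0-h sample")

  mature <- counts |> filter(grepl("^mature", .data$region))
  # denominator: each mature-mapped read once, regardless of multimapping
  uniq <- mature |> distinct(.data$sequence, .keep_all = TRUE)
  totals <- colSums(uniq[sn])
  if (any(totals == 0)) {
    stop("no mature-mapped reads in sample(s): ",
         paste(sn[totals == 0], collapse = ", "), call. = FALSE)
  }

  iso <- uniq
  iso[sn] <- lapply(sn, function(s) iso[[s]] / totals[[s]])
  iso <- iso |>
    mutate(detected =
             rowMeans(as.matrix(iso[zero_h])) >= thresholds$detect_threshold)

  mat <- mature
  mat[sn] <- lapply(sn, function(s) mat[[s]] / totals[[s]])
  mat <- mat |>
    group_by(.data$group_id) |>
    summarise(mature_id = paste(sort(unique(.data$mature_id)),
                                collapse = ";"),
              hairpin_id = paste(sort(unique(.data$hairpin_id)),
                                 collapse = ";"),
              across(all_of(sn), sum), .groups = "drop")
  mat <- mat |>
    mutate(detected =
             rowMeans(as.matrix(mat[zero_h])) >= thresholds$detect_threshold)

  out <- list(isoform = iso, mature = mat,
              totals = totals, samples = samples,
              thresholds = thresholds)
  class(out) <- "frequency_matrix"
  out
}

#' Annotate star and non-star strands from untreated samples
#'
#' For each hairpin with two annotated mature arms, the arm with the larger
#' mean 0-h frequency is annotated `non_star` and the other `star`; hairpins
#' with a single annotated mature are `non_star`. Exactly equal means are
#' tie-broken 5p = non-star and flagged `ambiguous`.
#'
#' @param freqs a `frequency_matrix` from [compute_frequencies()].
#' @param reference the [mirna_reference()] used for quantification.
#' @return tibble with `hairpin_id`, `mature_id`, `arm`, `mean_f0`,
#'   `strand_role`, `ambiguous`.
#' @export
annotate_star <- function(freqs, reference) {
  zero_h <- freqs$samples$sample_id[freqs$samples$time_h == 0]
  mat_f <- freqs$mature |>
    select("group_id", all_of(zero_h)) |>
    mutate(mean_f0 = rowMeans(as.matrix(pick(all_of(zero_h))))) |>
    select("group_id", "mean_f0")
  ann <- reference$matures |>
    left_join(mat_f, by = "group_id") |>
    mutate(mean_f0 = tidyr::replace_na(.data$mean_f0, 0))
  ann |>
    group_by(.data$hairpin_id) |>
    mutate(
      n_arms = n(),
      top = max(.data$mean_f0),
      tie = .data$n_arms == 2 & sum(.data$mean_f0 == .data$top) == 2,
      strand_role = case_when(
        n_arms == 1 ~ "non_star",
        tie & arm == "5p" ~ "non_star",
        tie ~ "star",
        mean_f0 == top ~ "non_star",
        TRUE ~ "star"),
      ambiguous = .data$tie) |>
    ungroup() |>
    select("hairpin_id", "mature_id", "arm", "mean_f0", "strand_role",
           "ambiguous")
}
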