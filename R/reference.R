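#' Hairpin reference with located mature arms
#'
#' A `mirna_reference` holds precursor (hairpin) sequences together with the
#' intervals of their annotated mature products. Coordinates are 0-based
#' half-open on the hairpin; the loop interval is derived as the region
#' between the 5p arm's end and the 3p arm's start. Identical mature
#' sequences arising from different hairpins (paralogue precursors) are
#' collected into cross-reference groups so that a read matching several of
#' them is counted once per distinct mature sequence.
#'
#' @param hairpins tibble with columns `hairpin_id`, `sequence`.
#' @param matures tibble with columns `hairpin_id`, `mature_id`,
#'   `arm` (`"5p"`/`"3p"`), `start`, `end`.
#' @return an object of class `mirna_reference`: a list with tibbles
#'   `$hairpins` (id, sequence, length), `$matures` (annotation plus the
#'   mature `sequence` and `group_id`) and `$loops` (derived loop interval
#'   per hairpin).
#' @export
mirna_reference <- function(hairpins, matures) {
  hairpins <- as_tibble(hairpins)
  matures <- as_tibble(matures)
  assert_that(all(c("hairpin_id", "sequence") %in% names(hairpins)),
              "hairpins needs columns hairpin_id, sequence")
  assert_that(all(c("hairpin_id", "mature_id", "arm", "start", "end") %in%
                    names(matures)),
              "matures needs hairpin_id, mature_id, arm, start, end")
  assert_that(!anyDuplicated(hairpins$hairpin_id),
              "duplicated hairpin_id in reference")
  hairpins$sequence <- canonical_dna(hairpins$sequence, "hairpin sequence")
  hairpins$length <- nchar(hairpins$sequence)

  unknown <- setdiff(matures$hairpin_id, hairpins$hairpin_id)
  if (length(unknown) > 0) {
    stop("annotation references unknown hairpin(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  assert_that(all(matures$arm %in% c("5p", "3p")),
              "arm must be '5p' or '3p'")
  matures <- matures |>
    left_join(select(hairpins, "hairpin_id", hp_len = "length",
                     hp_seq = "sequence"),
              by = "hairpin_id")
  bad <- matures$start < 0 | matures$end > matures$hp_len |
    matures$start >= matures$end
  if (any(bad)) {
    stop("out-of-bounds mature interval for: ",
         paste(head(matures$mature_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  matures$sequence <- substr(matures$hp_seq, matures$start + 1, matures$end)
  matures$group_id <- match(matures$sequence, unique(matures$sequence))

  # 5p must precede 3p on each two-arm hairpin; derive the loop interval
  loops <- matures |>
    select("hairpin_id", "arm", "start", "end") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("start", "end")) |>
    left_join(select(hairpins, "hairpin_id", "length"), by = "hairpin_id")
  if (!"start_5p" %in% names(loops)) loops$start_5p <- NA_real_
  if (!"start_3p" %in% names(loops)) loops$start_3p <- NA_real_
  if (!"end_5p" %in% names(loops)) loops$end_5p <- NA_real_
  if (!"end_3p" %in% names(loops)) loops$end_3p <- NA_real_
  both <- !is.na(loops$end_5p) & !is.na(loops$start_3p)
  if (any(both & loops$end_5p > loops$start_3p)) {
    stop("5p arm must precede (or abut) the 3p arm on each hairpin",
         call. = FALSE)
  }
  loops <- loops |>
    mutate(start = ifelse(both, .data$end_5p, NA_real_),
           end = ifelse(both, .data$start_3p, NA_real_)) |>
    select("hairpin_id", "start", "end")

  out <- list(
    hairpins = select(hairpins, "hairpin_id", "sequence", "length"),
    matures = select(matures, "hairpin_id", "mature_id", "arm",
                     "start", "end", "sequence", "group_id"),
    loops = loops
  )
  class(out) <- "mirna_reference"
  out
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("<mirna_reference> ", nrow(x$hairpins), " hairpins, ",
      nrow(x$matures), " mature arms (",
      length(unique(x$matures$group_id)), " distinct sequences)\n", sep = "")
  invisible(x)
}

#' Load a hairpin reference from FASTA + annotation TSV
#'
#' The annotation table must have columns `hairpin_id`, `mature_id`, `arm`
#' (`5p`/`3p`), `start`, `end`, with 0-based half-open coordinates on the
#' hairpin. `U` characters in the FASTA are canonicalized to `T`; any other
#' non-ACGTU character is an error naming the record.
#'
#' @param hairpin_fasta path to the precursor FASTA.
#' @param annotation_tsv path to the mature-arm annotation TSV.
#' @return a [mirna_reference()] object.
#' @export
load_reference <- function(hairpin_fasta, annotation_tsv) {
  seqs <- Biostrings::readBStringSet(hairpin_fasta)
  hairpins <- tibble(
    hairpin_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
  ann <- readr::read_tsv(annotation_tsv, show_col_types = FALSE,
                         progress = FALSE)
  mirna_reference(hairpins, ann)
}

#' Write a hairpin reference to FASTA + annotation TSV
#'
#' @param reference a [mirna_reference()].
#' @param hairpin_fasta,annotation_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, hairpin_fasta, annotation_tsv) {
  ss <- Biostrings::DNAStringSet(
    setNames(reference$hairpins$sequence, reference$hairpins$hairpin_id))
  Biostrings::writeXStringSet(ss, hairpin_fasta)
  readr::write_tsv(
    select(reference$matures, "hairpin_id", "mature_id", "arm",
           "start", "end"),
    annotation_tsv, progress = FALSE)
  invisible(c(hairpin_fasta, annotation_tsv))
}
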