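# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

geometric_mean <- function(x) exp(mean(log(x)))

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Draw `n` random sequences of lengths `len` (recycled) from base
# probabilities `probs` (named A/C/G/T vector). Returns a character vector.
random_dna <- function(n, len, probs) {
  len <- rep_len(len, n)
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len[i], replace = TRUE, prob = probs[BASES]),
          collapse = "")
  }, character(1))
}

# canonicalize an RNA/DNA string: uppercase, U -> T; error on other letters
canonical_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGTU characters in ", what, ": ",
         paste(head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  x
}

# half-life decay factor 2^(-t/h) that tolerates h = Inf (no decay)
decay2 <- function(t, h) {
  out <- 2^(-t / h)
  out[is.infinite(h)] <- 1
  # t = 0 with h = 0 would be NaN; define as 1 (nothing has decayed at t = 0)
  out[t == 0] <- 1
  out
}

sample_cols <- function(tbl, samples) {
  intersect(samples$sample_id, names(tbl))
}
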