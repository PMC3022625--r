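#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rgeom rmultinom runif rnorm setNames lm coef
#'   residuals qnorm sd
#' @importFrom utils write.table read.delim head
NULL

# Alphabet guard used across all sequence-facing entry points.
assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (!is.character(x) || anyNA(x))
    stop(what, " must be a character vector without NA", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(what, " contains characters outside ",
         if (allow_n) "ACGTN" else "ACGT",
         " (first offender: ", x[which(bad)[1]], ")", call. = FALSE)
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement (A<->T, C<->G), vectorised.
#' `N` is its own complement.
#'
#' @param x character vector of DNA strings over ACGT(N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  assert_dna(x, allow_n = TRUE)
  vapply(chartr("ACGTN", "TGCAN", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

# Fixed-width string field access without Biostrings round trips.
substr_v <- function(x, start, stop) substring(x, start, stop)

gc_fraction <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)
  vapply(v, function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

# All 0-based start positions of a fixed pattern in a string (exact).
find_all <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}
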