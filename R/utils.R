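# Small shared helpers.

#' Round half away from zero
#'
#' Display rounding used for expected counts in report tables: .5 always
#' rounds up, unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves up.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Percentage or proportion of a count
#'
#' @param count,total non-negative counts, `total > 0`.
#' @param percent if `TRUE` (default) return `100 * count / total`.
#' @return numeric scalar/vector.
#' @examples
#' proportion_of(2129, 17544)        # multistep share of het loci, in percent
#' proportion_of(1497, 6062268, percent = FALSE)
#' @export
proportion_of <- function(count, total, percent = TRUE) {
  stopifnot(all(count >= 0), all(total > 0))
  p <- count / total
  if (percent) 100 * p else p
}

#' Reverse complement of a nucleotide string
#' @param s character vector of ACGT strings.
#' @return character vector.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' All rotations of a string
#' @param s single string.
#' @return character vector of `nchar(s)` rotations (may contain duplicates).
#' @export
rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n) - 1L,
         function(k) paste0(substr(s, k + 1L, n), substr(s, 1L, k)),
         character(1))
}

# Validate a nucleotide string; returns the uppercased string.
.check_dna <- function(s, allow_n = FALSE, what = "sequence") {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  s <- toupper(s)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), s))
    stop(sprintf("%s contains characters outside {%s}", what,
                 paste(strsplit(alphabet, "")[[1]], collapse = ",")),
         call. = FALSE)
  s
}

.msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
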