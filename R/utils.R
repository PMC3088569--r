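#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed report values use the
#' conventional half-up rule (e.g. 10.25 -> 10.3 at 1 decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of DNA/RNA sequences
#'
#' @param x character vector of sequences (A/C/G/T/U/N, case-insensitive).
#' @return character vector of reverse complements, uppercase DNA alphabet.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    chartr("uU", "tT", x)
  )))
}

# stopifnot-style check with a formatted message
abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  abort_if(any(bad), "%s contains characters outside {A,C,G,T%s} at entry %d",
           what, if (allow_n) ",N" else "", which(bad)[1])
  invisible(x)
}
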