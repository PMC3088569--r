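#' Fold a sequence into its minimum-free-energy structure
#'
#' Computes the minimum-free-energy nested secondary structure under the
#' package's nearest-neighbour model (see [energy_params()]): stacking
#' energies for adjacent pairs, size-dependent penalties for hairpin loops,
#' bulges and internal loops, and an affine multiloop cost. Watson-Crick and
#' G.U pairs are allowed; hairpin loops are at least 3 nt. DNA input (T) is
#' transcribed to U before folding. Among co-optimal structures a fixed
#' deterministic traceback preference (pair as early and as left as
#' possible) selects one.
#'
#' @param sequence a single RNA/DNA sequence (A/C/G/U/T), length >= 5.
#' @return an object of class `rna_fold`: list with `sequence` (as given,
#'   uppercased), `pairs` (two-column matrix of 1-based pair indices),
#'   `energy` (kcal/mol; 0 for an unpaired structure), `dotbracket`.
#' @examples
#' fold_min_energy("GGGAAAACCC")
#' @export
fold_min_energy <- function(sequence) {
  abort_if(length(sequence) != 1, "fold_min_energy() folds one sequence")
  sequence <- toupper(sequence)
  abort_if(nchar(sequence) < 5, "sequence shorter than 5 nt")
  code <- encode_rna(sequence)
  res <- .fold_mfe_cpp(code, energy_params())
  partner <- res$partner
  idx <- which(partner > seq_along(partner))
  pairs <- cbind(i = idx, j = partner[idx])
  structure(list(sequence = sequence,
                 pairs = pairs,
                 energy = res$energy / 100,
                 dotbracket = pairs_to_dotbracket(pairs, nchar(sequence))),
            class = "rna_fold")
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(sprintf("<rna_fold> %d nt, %d pairs, %.2f kcal/mol\n",
              nchar(x$sequence), nrow(x$pairs), x$energy))
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  invisible(x)
}

#' Score every precursor-length subwindow of a folding window
#'
#' Internal workhorse of [scan_precursors()]: fills the folding tables once
#' for the whole window and reads off the MFE of every subwindow in the scan
#' length range that fully contains the mature region.
#'
#' @param window window sequence.
#' @param mature_start,mature_stop 1-based bounds of the mature region in
#'   the window.
#' @param len_min,len_max subwindow length range.
#' @return tibble with `start`, `len`, `energy` (kcal/mol).
#' @keywords internal
subwindow_energies <- function(window, mature_start, mature_stop,
                               len_min, len_max) {
  code <- encode_rna(window)
  m <- .scan_mfe_cpp(code, energy_params(), as.integer(len_min),
                     as.integer(len_max), as.integer(mature_start),
                     as.integer(mature_stop))
  tibble::tibble(start = m[, 1], len = m[, 2], energy = m[, 3] / 100)
}
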