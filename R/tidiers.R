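#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into a per-tag tibble
#'
#' One row per unique tag, joining the adaptor classification with the
#' annotation category (NA for unmatched tags).
#'
#' @param x an `srna_run`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.srna_run <- function(x, ...) {
  ann <- dplyr::rename(x$records, annotation = "category")
  x$classified |>
    dplyr::left_join(ann, by = "tag_id") |>
    tibble::as_tibble()
}

#' One-row summary of a pipeline run
#'
#' @param x an `srna_run`.
#' @param ... unused.
#' @return a one-row tibble with the headline accounting figures.
#' @export
glance.srna_run <- function(x, ...) {
  cats <- x$screen$categories
  pick <- function(cat) cats$n_reads[cats$category == cat]
  tibble::tibble(
    n_reads = sum(x$tags$count),
    n_unique_tags = nrow(x$tags),
    pct_legitimate = percentage(pick("legitimate"), sum(x$tags$count)),
    pct_matched = x$alignment$pct_reads_matched,
    n_mirna_features = nrow(x$expression),
    n_candidates = nrow(x$candidates),
    n_passing_precursors = sum(x$candidates$verdict, na.rm = TRUE))
}

#' Tidy a folded structure into a per-position tibble
#'
#' @param x an `rna_fold`.
#' @param ... unused.
#' @return tibble with `position`, `base`, `partner` (0 = unpaired), `symbol`.
#' @export
tidy.rna_fold <- function(x, ...) {
  n <- nchar(x$sequence)
  tibble::tibble(
    position = seq_len(n),
    base = strsplit(x$sequence, "")[[1]],
    partner = pairs_to_partner(x$pairs, n),
    symbol = strsplit(x$dotbracket, "")[[1]])
}

#' @export
glance.rna_fold <- function(x, ...) {
  tibble::tibble(length = nchar(x$sequence), n_pairs = nrow(x$pairs),
                 energy = x$energy)
}

#' Tidy a hairpin candidate into a one-row tibble
#'
#' @param x a `hairpin_candidate`.
#' @param ... unused.
#' @return one-row tibble with locus, energy, flags and verdict.
#' @export
tidy.hairpin_candidate <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(precursor = x$precursor, chrom = x$chrom, start = x$start,
                   stop = x$stop, strand = x$strand, energy = x$energy,
                   mature_offset = x$mature_offset,
                   mature_length = x$mature_length, mature_arm = x$mature_arm,
                   n_mature_pairs = x$n_mature_pairs,
                   dotbracket = x$structure$dotbracket),
    tibble::as_tibble(as.list(x$flags)),
    tibble::tibble(verdict = x$verdict))
}
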