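#' Counts per million
#'
#' CPM uses the library's total sequence reads (not mapped reads) as the
#' denominator. The exact ratio is returned; reporting rounds to 2 decimals
#' half-up.
#'
#' @param count read count(s) attributed to a feature.
#' @param total_reads total sequence reads in the library.
#' @param digits decimal places for reporting (`NULL` for the exact ratio).
#' @return numeric vector of CPM values.
#' @examples
#' compute_cpm(487654, 3763491)
#' @export
compute_cpm <- function(count, total_reads, digits = 2) {
  abort_if(total_reads <= 0, "total_reads must be positive")
  abort_if(any(count < 0 | count > total_reads),
           "count outside [0, total_reads]")
  cpm <- count / total_reads * 1e6
  if (!is.null(digits)) cpm <- round_half_up(cpm, digits)
  cpm
}

#' Per-miRNA expression table
#'
#' Pools the read counts of all tags annotated to the same miRNA feature
#' (summation over tags) and reports CPM against the library total.
#'
#' @param records tibble from [annotate_tags()].
#' @param tags collapsed tag table.
#' @param total_reads library total sequence reads (defaults to the tag
#'   table's sum, which equals it when no reads were rejected).
#' @param mirna_meta optional tibble with `feature_id` plus metadata columns
#'   (`accession`, `mirna_id`, `chrom`, `start`, `stop`, `strand`) joined
#'   onto the result.
#' @return tibble with one row per expressed miRNA feature: `mirna_id`,
#'   `count`, `cpm` (2 decimals), plus any metadata, sorted by decreasing
#'   CPM.
#' @export
expression_table <- function(records, tags, total_reads = sum(tags$count),
                             mirna_meta = NULL) {
  out <- records |>
    dplyr::filter(.data$category == "mirna") |>
    dplyr::left_join(tags[, c("tag_id", "count")], by = "tag_id") |>
    dplyr::group_by(feature_id = .data$feature_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(cpm = compute_cpm(.data$count, total_reads))
  if (!is.null(mirna_meta)) {
    out <- dplyr::left_join(out, mirna_meta, by = "feature_id")
    if ("mirna_id" %in% names(out)) {
      out$mirna_id <- dplyr::coalesce(out$mirna_id, out$feature_id)
    }
  }
  if (!"mirna_id" %in% names(out)) out$mirna_id <- out$feature_id
  out |>
    dplyr::relocate("mirna_id") |>
    dplyr::arrange(dplyr::desc(.data$cpm), .data$mirna_id)
}

#' Combined CPM of a miRNA family
#'
#' Sums member CPM values; the conventional report rounds the aggregate to
#' the nearest integer.
#'
#' @param records expression tibble with `mirna_id` and `cpm`.
#' @param member_ids character vector of family member ids.
#' @param digits decimal places for the aggregate (default 0).
#' @return numeric scalar.
#' @examples
#' tab <- tibble::tibble(mirna_id = c("a", "b"), cpm = c(1.2, 2.3))
#' aggregate_family(tab, c("a", "b"))
#' @export
aggregate_family <- function(records, member_ids, digits = 0) {
  missing <- setdiff(member_ids, records$mirna_id)
  abort_if(length(missing) > 0, "unknown family member id: %s", missing[1])
  round_half_up(sum(records$cpm[records$mirna_id %in% member_ids]), digits)
}

#' Top expressed fraction of a ranked table
#'
#' Returns the top `ceiling(fraction * n)` records by decreasing CPM, ties
#' broken by `mirna_id`.
#'
#' @param records expression tibble with `mirna_id` and `cpm`.
#' @param fraction fraction in (0, 1].
#' @return tibble slice of `records`.
#' @export
top_expressed <- function(records, fraction = 0.10) {
  abort_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  n_top <- ceiling(fraction * nrow(records))
  records |>
    dplyr::arrange(dplyr::desc(.data$cpm), .data$mirna_id) |>
    dplyr::slice_head(n = n_top)
}
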