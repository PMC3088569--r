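#' Collapse raw reads into abundance-ranked unique tags
#'
#' Identical reads are collapsed into unique tags carrying their read count.
#' Tags are ranked by decreasing count with ties broken lexicographically by
#' sequence, so identical input multisets always yield identical output
#' regardless of read order. Tag identifiers are `<prefix>_<rank>`.
#'
#' Reads whose length differs from `read_length` are rejected and counted; the
#' number rejected is attached as attribute `n_rejected` and raised as a
#' warning, matching the run-log accounting.
#'
#' @param reads character vector of read sequences.
#' @param id_prefix prefix for tag identifiers.
#' @param read_length expected read length in nt (default 36).
#' @return a tibble with columns `tag_id`, `sequence`, `count`, `rank`,
#'   ordered by rank; attribute `n_rejected` counts length-rejected reads.
#' @examples
#' collapse_reads(c("AA", "AA", "CC"), read_length = 2)
#' @export
collapse_reads <- function(reads, id_prefix = "tag", read_length = 36L) {
  bad <- nchar(reads) != read_length
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(sprintf("%d read(s) rejected: length != %d nt", n_rejected, read_length),
            call. = FALSE)
    reads <- reads[!bad]
  }
  if (length(reads) == 0) {
    out <- tibble::tibble(tag_id = character(), sequence = character(),
                          count = integer(), rank = integer())
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  counts <- table(reads)
  out <- tibble::tibble(sequence = names(counts), count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  tag_id = paste0(id_prefix, "_", .data$rank)) |>
    dplyr::select("tag_id", "sequence", "count", "rank")
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Summarise a collapsed tag table
#'
#' Asserts read-count conservation: the sum of tag counts must equal the
#' number of reads that entered collapsing.
#'
#' @param tags tibble from [collapse_reads()].
#' @return one-row tibble with `n_unique` and `n_reads`.
#' @export
tag_accounting <- function(tags) {
  tibble::tibble(n_unique = nrow(tags),
                 n_reads = sum(tags$count))
}
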