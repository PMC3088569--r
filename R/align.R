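#' Build a both-strand k-mer index of a genome
#'
#' Every genomic k-mer is recorded with its plus-strand start coordinate;
#' minus-strand entries store the reverse complement of the genome substring,
#' i.e. the sequence a query read off the minus strand would have. k-mers
#' containing N are excluded (they can never be exact-matched).
#'
#' @param g an [genome()] object.
#' @param k k-mer / query length in nt (default 22).
#' @return an object of class `srna_index`: list with `k` and `lookup`, a
#'   tibble of (`kmer`, `chrom`, `start`, `strand`).
#' @export
build_index <- function(g, k = 22L) {
  abort_if(k < 1, "k must be >= 1")
  per_chrom <- purrr::map(names(g), function(chrom) {
    s <- g[[chrom]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    if (!any(keep)) return(NULL)
    tibble::tibble(
      kmer = c(kmers[keep], revcomp(kmers[keep])),
      chrom = chrom,
      start = rep(starts[keep], 2L),
      strand = rep(c("+", "-"), each = sum(keep)))
  })
  lookup <- dplyr::bind_rows(per_chrom)
  if (nrow(lookup) == 0) {
    lookup <- tibble::tibble(kmer = character(), chrom = character(),
                             start = integer(), strand = character())
  }
  structure(list(k = as.integer(k), lookup = lookup), class = "srna_index")
}

#' @export
print.srna_index <- function(x, ...) {
  cat(sprintf("<srna_index> k=%d, %d postings\n", x$k, nrow(x$lookup)))
  invisible(x)
}

# implied start of the full-length tag footprint on the plus strand
footprint_start <- function(start, end_used, strand, strip_length) {
  ifelse((end_used == "end3") == (strand == "+"), start, start - strip_length)
}

empty_hits <- function() {
  tibble::tibble(tag_id = character(), end_used = character(),
                 chrom = character(), start = integer(), stop = integer(),
                 strand = character(), end_uniqueness = character(),
                 end_n_loci = integer(), redundant = logical(),
                 n_loci = integer(), uniqueness = character())
}

#' Align tags to the genome by dual 22-nt end queries
#'
#' Each tag is queried twice: `end3` uses the 5'-most `k` nt of the raw tag
#' (14 bases stripped from the 3' end) and `end5` the 3'-most `k` nt
#' (14 stripped from the 5' end). Only perfect matches are reported. Per
#' pass, a tag is `unique` (1 locus) or `multi` (several; listed loci capped
#' at `multi_locus_report_cap`, the true count kept in `end_n_loci`); queries
#' with no locus, including any containing N, produce no rows. When the two
#' passes of one tag land on the same implied 36-nt footprint the `end5` hit
#' is flagged `redundant`; the combined non-redundant hit set is
#' `redundant == FALSE`, over which the tag-level `n_loci` and `uniqueness`
#' are computed. A tag is genome-matched if either pass matched.
#'
#' @param tags tibble with `tag_id`, `sequence`, `count`.
#' @param index an [build_index()] object.
#' @param config an [run_config()] object.
#' @return tibble of hits: `tag_id`, `end_used`, `chrom`, `start`, `stop`,
#'   `strand`, `end_uniqueness`, `end_n_loci`, `redundant`, `n_loci`,
#'   `uniqueness`.
#' @export
align_tags <- function(tags, index, config = run_config()) {
  k <- index$k
  rl <- config$read_length
  queries <- dplyr::bind_rows(
    tibble::tibble(tag_id = tags$tag_id, end_used = "end3",
                   query = substr(tags$sequence, 1L, k)),
    tibble::tibble(tag_id = tags$tag_id, end_used = "end5",
                   query = substr(tags$sequence, rl - k + 1L, rl)))
  queries <- dplyr::filter(queries, !grepl("N", .data$query, fixed = TRUE))
  hits <- dplyr::inner_join(queries, index$lookup,
                            by = c("query" = "kmer"),
                            relationship = "many-to-many")
  if (nrow(hits) == 0) return(empty_hits())
  hits <- hits |>
    dplyr::mutate(stop = .data$start + k - 1L) |>
    dplyr::group_by(.data$tag_id, .data$end_used) |>
    dplyr::mutate(end_n_loci = dplyr::n(),
                  end_uniqueness = ifelse(.data$end_n_loci == 1L, "unique", "multi")) |>
    dplyr::ungroup() |>
    dplyr::mutate(fp = footprint_start(.data$start, .data$end_used,
                                       .data$strand, config$strip_length)) |>
    # end3 sorts before end5, so duplicated() flags the end5 copy
    dplyr::arrange(.data$tag_id, .data$chrom, .data$strand, .data$fp,
                   .data$end_used) |>
    dplyr::mutate(redundant = duplicated(
      paste(.data$tag_id, .data$chrom, .data$strand, .data$fp)))
  hits <- hits |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(n_loci = sum(!.data$redundant),
                  uniqueness = ifelse(.data$n_loci == 1L, "unique", "multi")) |>
    dplyr::group_by(.data$tag_id, .data$end_used) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand, .by_group = TRUE) |>
    dplyr::slice_head(n = config$multi_locus_report_cap) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$tag_id, .data$end_used, .data$chrom, .data$start) |>
    dplyr::select("tag_id", "end_used", "chrom", "start", "stop", "strand",
                  "end_uniqueness", "end_n_loci", "redundant", "n_loci",
                  "uniqueness")
  hits
}

#' Alignment accounting (matched / unmatched tags and reads)
#'
#' @param hits tibble from [align_tags()].
#' @param tags the collapsed tag table that was aligned.
#' @return one-row tibble: per-end matched tag counts, combined non-redundant
#'   matched tag count, matched/unmatched tag and read counts, and
#'   percentages of total reads.
#' @export
alignment_accounting <- function(hits, tags) {
  total_reads <- sum(tags$count)
  matched_ids <- unique(hits$tag_id)
  matched_reads <- sum(tags$count[tags$tag_id %in% matched_ids])
  tibble::tibble(
    n_tags_total = nrow(tags),
    n_reads_total = total_reads,
    n_tags_end3 = dplyr::n_distinct(hits$tag_id[hits$end_used == "end3"]),
    n_tags_end5 = dplyr::n_distinct(hits$tag_id[hits$end_used == "end5"]),
    n_tags_matched = length(matched_ids),
    n_reads_matched = matched_reads,
    n_tags_unmatched = nrow(tags) - length(matched_ids),
    n_reads_unmatched = total_reads - matched_reads,
    pct_reads_matched = percentage(matched_reads, total_reads),
    pct_reads_unmatched = percentage(total_reads - matched_reads, total_reads))
}
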