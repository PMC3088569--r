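longest_3p_overlap <- function(seqs, adaptor, read_length, min_overlap) {
  # longest prefix of the 3' adaptor exactly matching a suffix of the tag
  out <- integer(length(seqs))
  for (L in seq(min(nchar(adaptor), read_length), min_overlap)) {
    todo <- out == 0L
    if (!any(todo)) break
    hit <- substr(seqs[todo], read_length - L + 1L, read_length) ==
      substr(adaptor, 1L, L)
    out[todo][hit] <- L
  }
  out
}

longest_5p_overlap <- function(seqs, adaptor, read_length, min_overlap) {
  # longest suffix of the 5' adaptor exactly matching a prefix of the tag
  out <- integer(length(seqs))
  alen <- nchar(adaptor)
  for (L in seq(min(alen, read_length), min_overlap)) {
    todo <- out == 0L
    if (!any(todo)) break
    hit <- substr(seqs[todo], 1L, L) == substr(adaptor, alen - L + 1L, alen)
    out[todo][hit] <- L
  }
  out
}

#' Classify tags by adaptor content
#'
#' Detects exact adaptor remnants at the tag ends: `overlap_3p` is the longest
#' prefix of the 3' adaptor matching a suffix of the tag and `overlap_5p` the
#' longest suffix of the 5' adaptor matching the tag's prefix, each only
#' counted when at least `min_adaptor_overlap` nt long. Categories follow the
#' library-construction logic: a tag with no adaptor at either end is
#' contamination from longer transcripts (`no_adaptor`); a tag that is all
#' adaptor is a cloning artefact (`adaptor_only`); anything with a non-empty
#' insert and at least one adaptor end is a `legitimate` library insert.
#'
#' In the rare case that the two detected overlaps together exceed the read
#' length (self-overlapping adaptor remnants) the insert is taken as empty and
#' the tag classified `adaptor_only`.
#'
#' @param tags tibble with at least `sequence` (from [collapse_reads()]), or a
#'   character vector of tag sequences.
#' @param config an [run_config()] object.
#' @return the input tibble with columns `overlap_5p`, `overlap_3p`,
#'   `category`, `insert`, `insert_length`, `size_class` appended.
#' @export
classify_adaptors <- function(tags, config = run_config()) {
  if (is.character(tags)) tags <- tibble::tibble(sequence = tags)
  seqs <- tags$sequence
  assert_dna(seqs, what = "tag")
  abort_if(any(nchar(seqs) != config$read_length),
           "tag length != read_length (%d) at entry %d", config$read_length,
           which(nchar(seqs) != config$read_length)[1])
  o3 <- longest_3p_overlap(seqs, config$adaptor_3p, config$read_length,
                           config$min_adaptor_overlap)
  o5 <- longest_5p_overlap(seqs, config$adaptor_5p, config$read_length,
                           config$min_adaptor_overlap)
  ins_len <- pmax(0L, config$read_length - o5 - o3)
  insert <- substring(seqs, o5 + 1L, config$read_length - o3)
  insert[ins_len == 0L] <- ""
  category <- dplyr::case_when(
    o5 == 0L & o3 == 0L ~ "no_adaptor",
    ins_len == 0L ~ "adaptor_only",
    TRUE ~ "legitimate"
  )
  dplyr::mutate(tags,
    overlap_5p = o5, overlap_3p = o3,
    category = factor(category, levels = c("no_adaptor", "adaptor_only", "legitimate")),
    insert = insert, insert_length = ins_len,
    size_class = classify_size(ins_len))
}

#' @rdname classify_adaptors
#' @param tag_sequence a single tag sequence.
#' @return `classify_adaptor()` returns a one-row tibble.
#' @export
classify_adaptor <- function(tag_sequence, config = run_config()) {
  classify_adaptors(tibble::tibble(sequence = tag_sequence), config)
}

#' Assign insert lengths to size classes
#'
#' Bins are disjoint: `lt16` (<= 15 nt), `16_19`, `20_25`, `26_29`, `ge30`.
#'
#' @param insert_length integer vector of insert lengths (nt).
#' @return factor with the five size-class levels.
#' @export
classify_size <- function(insert_length) {
  abort_if(any(insert_length < 0), "negative insert length")
  cut(insert_length, breaks = c(-1, 15, 19, 25, 29, Inf),
      labels = c("lt16", "16_19", "20_25", "26_29", "ge30"))
}

#' Adaptor-screen summary
#'
#' Per-category unique-tag and read counts with percentages of total reads,
#' plus the size-class distribution of legitimate tags (also as percentages
#' of total reads, the convention used for the printed distributions).
#'
#' @param classified tibble from [classify_adaptors()] including `count`.
#' @return list with tibbles `categories` and `size_classes`.
#' @export
screen_report <- function(classified) {
  total_reads <- sum(classified$count)
  categories <- classified |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(n_tags = dplyr::n(), n_reads = sum(.data$count),
                     .groups = "drop") |>
    dplyr::mutate(pct_reads = percentage(.data$n_reads, total_reads))
  size_classes <- classified |>
    dplyr::filter(.data$category == "legitimate") |>
    dplyr::group_by(size_class = .data$size_class, .drop = FALSE) |>
    dplyr::summarise(n_tags = dplyr::n(), n_reads = sum(.data$count),
                     .groups = "drop") |>
    dplyr::mutate(pct_reads = percentage(.data$n_reads, total_reads))
  list(categories = categories, size_classes = size_classes)
}
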