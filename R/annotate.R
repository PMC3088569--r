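ANNOTATION_PRECEDENCE <- c("repeat", "ncrna", "mirna", "refseq", "est")
ANNOTATION_CATEGORIES <- c(ANNOTATION_PRECEDENCE,
                           "unique_no_annotation", "multi_no_annotation")

track_list <- function(tracks) {
  # accept a named list of interval tibbles or srna_track objects
  nms <- purrr::map_chr(seq_along(tracks), function(i) {
    nm <- attr(tracks[[i]], "track_name")
    if (is.null(nm)) nm <- names(tracks)[i]
    abort_if(is.null(nm) || !nm %in% TRACK_NAMES,
             "track %d has no recognised name", i)
    nm
  })
  stats::setNames(tracks, nms)
}

#' Annotate genome-matched tags by fixed track precedence
#'
#' Each tag's non-redundant hits are intersected with the annotation tracks
#' in fixed precedence order (`repeat` > `ncrna` > `mirna` > `refseq` >
#' `est`); the first track overlapping any of the tag's reported loci by at
#' least 1 nt determines its single category. Unannotated tags fall into
#' `unique_no_annotation` or `multi_no_annotation` according to their
#' combined-locus uniqueness. Overlap is strand-agnostic unless a track name
#' is listed in `strand_aware_tracks`.
#'
#' @param hits tibble from [align_tags()].
#' @param tracks named list of annotation tracks (see [annotation_track()]).
#' @param g optional genome; if supplied, a hit on a chromosome absent from
#'   it is an error.
#' @param strand_aware_tracks character vector of track names for which the
#'   feature strand must equal the hit strand.
#' @return tibble with one row per genome-matched tag: `tag_id`, `category`
#'   (factor over the seven categories), `feature_id` (`NA` when
#'   unannotated).
#' @export
annotate_tags <- function(hits, tracks, g = NULL,
                          strand_aware_tracks = character(0)) {
  tracks <- track_list(tracks)
  if (!is.null(g)) {
    bad <- setdiff(unique(hits$chrom), names(g))
    abort_if(length(bad) > 0, "hit chromosome '%s' absent from genome", bad[1])
  }
  loci <- dplyr::filter(hits, !.data$redundant)
  if (nrow(loci) == 0) {
    return(tibble::tibble(tag_id = character(),
                          category = factor(character(),
                                            levels = ANNOTATION_CATEGORIES),
                          feature_id = character()))
  }
  per_tag <- dplyr::distinct(loci, .data$tag_id, .data$uniqueness)
  assigned <- tibble::tibble(tag_id = character(), category = character(),
                             feature_id = character())
  remaining <- loci
  for (nm in intersect(ANNOTATION_PRECEDENCE, names(tracks))) {
    if (nrow(remaining) == 0) break
    tr <- tibble::as_tibble(unclass(tracks[[nm]]))
    if (nrow(tr) == 0) next
    ov <- dplyr::inner_join(remaining, tr, by = "chrom", suffix = c("", ".f"),
                            relationship = "many-to-many") |>
      dplyr::filter(.data$start <= .data$stop.f, .data$stop >= .data$start.f)
    if (nm %in% strand_aware_tracks) {
      ov <- dplyr::filter(ov, .data$strand.f == "*" |
                            .data$strand == .data$strand.f)
    }
    if (nrow(ov) == 0) next
    found <- ov |>
      dplyr::arrange(.data$tag_id, .data$chrom, .data$start.f, .data$feature_id) |>
      dplyr::distinct(.data$tag_id, .keep_all = TRUE) |>
      dplyr::transmute(.data$tag_id, category = nm, .data$feature_id)
    assigned <- dplyr::bind_rows(assigned, found)
    remaining <- dplyr::filter(remaining, !.data$tag_id %in% found$tag_id)
  }
  out <- per_tag |>
    dplyr::left_join(assigned, by = "tag_id") |>
    dplyr::mutate(category = dplyr::coalesce(
      .data$category,
      dplyr::if_else(.data$uniqueness == "unique",
                     "unique_no_annotation", "multi_no_annotation"))) |>
    dplyr::transmute(
      .data$tag_id,
      category = factor(.data$category, levels = ANNOTATION_CATEGORIES),
      feature_id = .data$feature_id)
  dplyr::arrange(out, .data$tag_id)
}

#' @rdname annotate_tags
#' @return `annotate_tag()` is the single-hit convenience form and returns a
#'   one-row tibble.
#' @export
annotate_tag <- function(hits, tracks, g = NULL,
                         strand_aware_tracks = character(0)) {
  annotate_tags(hits, tracks, g, strand_aware_tracks)
}

#' Annotation summary table
#'
#' Per-category accounting of matched unique tags: tags matched via the
#' `end3` pass, via the `end5` pass, the combined non-redundant tag count,
#' and the total read count, with a `total` row of column sums.
#'
#' @param records tibble from [annotate_tags()].
#' @param hits tibble from [align_tags()].
#' @param tags collapsed tag table.
#' @return tibble with columns `category`, `n_tags_end3`, `n_tags_end5`,
#'   `n_tags_combined`, `n_reads`; last row is `total`.
#' @export
annotation_table <- function(records, hits, tags) {
  end3 <- unique(hits$tag_id[hits$end_used == "end3"])
  end5 <- unique(hits$tag_id[hits$end_used == "end5"])
  counts <- tags[, c("tag_id", "count")]
  body <- records |>
    dplyr::left_join(counts, by = "tag_id") |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n_tags_end3 = sum(.data$tag_id %in% end3),
      n_tags_end5 = sum(.data$tag_id %in% end5),
      n_tags_combined = dplyr::n(),
      n_reads = sum(.data$count, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(category = as.character(.data$category))
  total <- body |>
    dplyr::summarise(category = "total",
                     dplyr::across(dplyr::where(is.numeric), sum))
  dplyr::bind_rows(body, total)
}
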