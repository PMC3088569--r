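#' Percentage of total reads
#'
#' @param part_reads,total_reads read counts; `total_reads` must be > 0 and
#'   `part_reads` within `[0, total_reads]`.
#' @param digits decimal places (default 1, the reporting convention).
#' @return numeric, rounded half-up.
#' @examples
#' percentage(3089973, 3763491)
#' @export
percentage <- function(part_reads, total_reads, digits = 1) {
  abort_if(any(total_reads <= 0), "total_reads must be positive")
  abort_if(any(part_reads < 0 | part_reads > total_reads),
           "part_reads outside [0, total_reads]")
  round_half_up(part_reads / total_reads * 100, digits)
}

REPORT_STAGES <- c("tags", "screen", "alignment", "annotation",
                   "expression", "candidates")

#' Assemble the run report
#'
#' Bundles the per-stage summaries into one object whose blocks satisfy the
#' conservation cascade: adaptor-category reads sum to the total, matched
#' plus unmatched reads equal the total, and annotation-category reads sum
#' to the matched total. These identities are asserted at construction.
#'
#' @param stages named list with elements `tags` (from [tag_accounting()]),
#'   `screen` (from [screen_report()]), `alignment` (from
#'   [alignment_accounting()]), `annotation` (from [annotation_table()]),
#'   `expression` (from [expression_table()]) and `candidates` (candidate
#'   tibble; may have zero rows).
#' @return an object of class `srna_report`.
#' @export
build_report <- function(stages) {
  missing <- setdiff(REPORT_STAGES, names(stages))
  abort_if(length(missing) > 0, "missing stage: %s", missing[1])
  totals <- stages$tags
  cat_reads <- sum(stages$screen$categories$n_reads)
  abort_if(cat_reads != totals$n_reads,
           "adaptor-category reads (%d) do not sum to total reads (%d)",
           cat_reads, totals$n_reads)
  aln <- stages$alignment
  abort_if(aln$n_reads_matched + aln$n_reads_unmatched != totals$n_reads,
           "matched + unmatched reads do not equal total reads")
  ann_total <- stages$annotation[stages$annotation$category == "total", ]
  abort_if(nrow(ann_total) == 1 && ann_total$n_reads != aln$n_reads_matched,
           "annotation-category reads do not sum to matched reads")
  structure(list(
    totals = totals,
    adaptor_categories = stages$screen$categories,
    size_classes = stages$screen$size_classes,
    alignment = aln,
    annotation = stages$annotation,
    expression = stages$expression,
    candidates = stages$candidates), class = "srna_report")
}

#' @export
format.srna_report <- function(x, ...) {
  fmt_tbl <- function(tbl) {
    paste(utils::capture.output(print(as.data.frame(tbl), row.names = FALSE)),
          collapse = "\n")
  }
  n_pass <- if (nrow(x$candidates)) sum(x$candidates$verdict, na.rm = TRUE) else 0L
  paste0(
    "== small RNA run report ==\n",
    sprintf("reads: %d   unique tags: %d\n\n", x$totals$n_reads, x$totals$n_unique),
    "-- adaptor screen (percent of total reads) --\n",
    fmt_tbl(x$adaptor_categories), "\n\n",
    "-- size classes of legitimate tags --\n",
    fmt_tbl(x$size_classes), "\n\n",
    "-- genome alignment --\n",
    fmt_tbl(x$alignment), "\n\n",
    "-- annotation --\n",
    fmt_tbl(x$annotation), "\n\n",
    sprintf("-- expression: %d miRNA features --\n", nrow(x$expression)),
    fmt_tbl(utils::head(x$expression, 10)), "\n\n",
    sprintf("-- novel precursor candidates: %d scanned, %d passing --\n",
            nrow(x$candidates), n_pass))
}

#' @export
print.srna_report <- function(x, ...) {
  cat(format(x))
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits one TSV per block plus `summary.txt`, the plain-text run log.
#'
#' @param report an `srna_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- c("totals", "adaptor_categories", "size_classes", "alignment",
              "annotation", "expression", "candidates")
  for (b in blocks) {
    tbl <- report[[b]]
    if (is.data.frame(tbl)) {
      readr::write_tsv(tbl, file.path(dir, paste0(b, ".tsv")))
    }
  }
  writeLines(format(report), file.path(dir, "summary.txt"))
  invisible(dir)
}
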