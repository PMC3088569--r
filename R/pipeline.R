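#' Run the full small RNA annotation and discovery pipeline
#'
#' Chains the stages: read collapsing, adaptor screening, dual-end exact
#' alignment, precedence annotation, CPM expression, candidate selection and
#' hairpin-precursor discovery, and assembles the run report.
#'
#' @param reads character vector of fixed-length reads (e.g. from
#'   [read_fastq()]).
#' @param g an [genome()] object.
#' @param tracks named list of annotation tracks (see [annotation_track()]).
#' @param config an [run_config()] object.
#' @param mirna_meta optional miRNA metadata for the expression table.
#' @param discover run the hairpin-discovery stage (the slowest one).
#' @return an object of class `srna_run`: list with the per-stage tibbles
#'   (`tags`, `classified`, `hits`, `records`, `expression`, `candidates`),
#'   the passing `hairpins` (list of `hairpin_candidate`), and `report`.
#' @export
run_small_rna_pipeline <- function(reads, g, tracks, config = run_config(),
                                   mirna_meta = NULL, discover = TRUE) {
  tags <- collapse_reads(reads, config$tag_id_prefix, config$read_length)
  classified <- classify_adaptors(tags, config)
  screen <- screen_report(classified)
  index <- build_index(g, config$end_query_length)
  hits <- align_tags(tags, index, config)
  alignment <- alignment_accounting(hits, tags)
  records <- annotate_tags(hits, tracks, g)
  expression <- expression_table(records, tags, sum(tags$count), mirna_meta)
  selected <- select_candidates(records, hits, classified)
  disc <- if (discover) discover_precursors(selected, g, config) else
    list(table = dplyr::mutate(selected, scan_status = character(nrow(selected)),
                               precursor = NA_character_, precursor_start = NA_integer_,
                               precursor_stop = NA_integer_, energy = NA_real_,
                               dotbracket = NA_character_, verdict = NA),
         hairpins = list())
  report <- build_report(list(tags = tag_accounting(tags), screen = screen,
                              alignment = alignment,
                              annotation = annotation_table(records, hits, tags),
                              expression = expression,
                              candidates = disc$table))
  structure(list(config = config, tags = tags, classified = classified,
                 hits = hits, records = records, screen = screen,
                 alignment = alignment, expression = expression,
                 candidates = disc$table, hairpins = disc$hairpins,
                 report = report), class = "srna_run")
}

#' Hairpin discovery over a candidate table
#'
#' Scans the flanking window of each candidate mature locus for a passing
#' precursor. Candidates whose mature span falls outside the chromosome
#' (insert projected past a contig end) are reported with
#' `scan_status = "locus_truncated"` and not scanned.
#'
#' @param selected tibble from [select_candidates()].
#' @param g an [genome()] object.
#' @param config an [run_config()] object.
#' @return list with `table` (candidate tibble plus scan columns) and
#'   `hairpins` (named list of passing `hairpin_candidate` objects).
#' @export
discover_precursors <- function(selected, g, config = run_config()) {
  hairpins <- list()
  n <- nrow(selected)
  scan_status <- character(n)
  precursor <- rep(NA_character_, n)
  pre_start <- rep(NA_integer_, n)
  pre_stop <- rep(NA_integer_, n)
  energy <- rep(NA_real_, n)
  dotbracket <- rep(NA_character_, n)
  verdict <- rep(FALSE, n)
  for (r in seq_len(n)) {
    chrom <- selected$chrom[r]
    if (selected$mature_start[r] < 1 ||
        selected$mature_stop[r] > nchar(g[[chrom]])) {
      scan_status[r] <- "locus_truncated"
      next
    }
    w <- extract_window(g, chrom, selected$mature_start[r],
                        selected$mature_stop[r], selected$strand[r],
                        config = config)
    hp <- scan_precursors(w, config = config)
    if (is.null(hp)) {
      scan_status[r] <- "no_passing_precursor"
    } else {
      scan_status[r] <- "pass"
      precursor[r] <- hp$precursor
      pre_start[r] <- hp$start
      pre_stop[r] <- hp$stop
      energy[r] <- hp$energy
      dotbracket[r] <- hp$structure$dotbracket
      verdict[r] <- TRUE
      hairpins[[selected$tag_id[r]]] <- hp
    }
  }
  table <- dplyr::mutate(selected, scan_status = scan_status,
                         precursor = precursor, precursor_start = pre_start,
                         precursor_stop = pre_stop, energy = energy,
                         dotbracket = dotbracket, verdict = verdict)
  list(table = table, hairpins = hairpins)
}

#' Export passing precursors as FASTA
#'
#' @param run an `srna_run` (or the `hairpins` list itself).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_precursors <- function(run, path) {
  hairpins <- if (inherits(run, "srna_run")) run$hairpins else run
  seqs <- purrr::map_chr(hairpins, "precursor")
  ss <- Biostrings::DNAStringSet(chartr("Uu", "Tt", seqs))
  names(ss) <- names(hairpins)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.srna_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}
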