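#' Read a FASTQ file of fixed-length reads
#'
#' Parses plain (uncompressed) 4-line-per-record FASTQ. Quality strings are
#' read and discarded: tag ranking downstream uses raw abundance with no
#' quality filtering, so qualities carry no information for this pipeline.
#' The parser is line-based so that malformed records can be reported with
#' their line number.
#'
#' @param path path to a FASTQ file.
#' @return character vector of read sequences, uppercased.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' write_fastq(c("ACGT", "GGCC"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readr::read_lines(path, progress = FALSE)
  n <- length(lines)
  if (n == 0) return(character(0))
  abort_if(n %% 4 != 0,
           "malformed FASTQ: %d lines is not a multiple of 4 (truncated record near line %d)",
           n, n)
  hdr <- seq(1, n, by = 4)
  sep <- seq(3, n, by = 4)
  bad_hdr <- !startsWith(lines[hdr], "@")
  abort_if(any(bad_hdr), "malformed FASTQ: expected '@' header at line %d",
           hdr[which(bad_hdr)[1]])
  bad_sep <- !startsWith(lines[sep], "+")
  abort_if(any(bad_sep), "malformed FASTQ: expected '+' separator at line %d",
           sep[which(bad_sep)[1]])
  seqs <- toupper(lines[seq(2, n, by = 4)])
  quals <- lines[seq(4, n, by = 4)]
  bad_len <- nchar(seqs) != nchar(quals)
  abort_if(any(bad_len),
           "malformed FASTQ: sequence/quality length mismatch at line %d",
           hdr[which(bad_len)[1]] + 1)
  assert_dna(seqs, what = "FASTQ read")
  seqs
}

#' @rdname read_fastq
#' @param reads character vector of read sequences.
#' @param ids optional read identifiers (defaults to `read_1`, `read_2`, ...).
#' @return `write_fastq()` returns `path` invisibly. Placeholder qualities
#'   (`"I"`) are emitted since the pipeline ignores them.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  out <- character(4 * length(reads))
  if (length(reads)) {
    out[seq(1, length(out), 4)] <- paste0("@", ids)
    out[seq(2, length(out), 4)] <- reads
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- strrep("I", nchar(reads))
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences
#' restricted to the A/C/G/T/N alphabet. Names must be unique and sequences
#' non-empty.
#'
#' @param sequences named character vector, chromosome name -> sequence.
#' @return an object of class `srna_genome`.
#' @export
genome <- function(sequences) {
  abort_if(is.null(names(sequences)) || any(names(sequences) == ""),
           "all chromosomes must be named")
  abort_if(anyDuplicated(names(sequences)) > 0, "duplicate chromosome name: %s",
           names(sequences)[duplicated(names(sequences))][1])
  sequences <- toupper(sequences)
  abort_if(any(nchar(sequences) == 0), "empty chromosome sequence")
  assert_dna(sequences, what = "genome")
  structure(sequences, class = "srna_genome")
}

#' @export
print.srna_genome <- function(x, ...) {
  cat(sprintf("<srna_genome> %d chromosome(s), %d nt total\n",
              length(x), sum(nchar(x))))
  for (nm in names(x)) cat(sprintf("  %-10s %d nt\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Read / write a genome FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] so that standard FASTA handling
#' (wrapping, headers) is delegated to the field's parser; sequences are
#' uppercased in memory.
#'
#' @param path FASTA file path.
#' @return `read_genome()` returns an `srna_genome`.
#' @export
read_genome <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  abort_if(anyDuplicated(nms) > 0, "duplicate chromosome name: %s",
           nms[duplicated(nms)][1])
  seqs <- as.character(ss)
  names(seqs) <- nms
  genome(seqs)
}

#' @rdname read_genome
#' @param g an `srna_genome` (or named character vector).
#' @export
write_genome <- function(g, path) {
  ss <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

TRACK_NAMES <- c("repeat", "ncrna", "mirna", "refseq", "est")

#' Construct an annotation track
#'
#' Intervals are stored 1-based inclusive. `feature_id` identifies the
#' annotated feature (e.g. a miRNA precursor name); `strand` is `+`, `-` or
#' `*` for unstranded features.
#'
#' @param intervals a data frame with columns `chrom`, `start`, `stop`,
#'   `strand`, `feature_id`.
#' @param name track label, one of `"repeat"`, `"ncrna"`, `"mirna"`,
#'   `"refseq"`, `"est"`.
#' @return a tibble of class `srna_track` with a `track_name` attribute.
#' @export
annotation_track <- function(intervals, name) {
  abort_if(!name %in% TRACK_NAMES, "unknown track name '%s'", name)
  x <- tibble::as_tibble(intervals)
  need <- c("chrom", "start", "stop", "strand", "feature_id")
  miss <- setdiff(need, names(x))
  abort_if(length(miss) > 0, "track missing column(s): %s",
           paste(miss, collapse = ", "))
  x <- dplyr::mutate(x[need], start = as.integer(.data$start),
                     stop = as.integer(.data$stop))
  bad <- x$start > x$stop
  abort_if(any(bad), "interval start > stop at row %d", which(bad)[1])
  structure(x, class = c("srna_track", class(x)), track_name = name)
}

#' Read / write an annotation interval track
#'
#' Two plain-text conventions are supported: `format = "tsv"` is a
#' tab-separated file with a header line and 1-based inclusive `start`/`stop`
#' columns (the pipeline's internal convention, matching UCSC-style printed
#' loci); `format = "bed"` is headerless 6-column BED with 0-based half-open
#' coordinates, converted at the boundary.
#'
#' @param path file path.
#' @param name track label (see [annotation_track()]).
#' @param format `"tsv"` or `"bed"`.
#' @return `read_track()` returns an `srna_track` tibble.
#' @export
read_track <- function(path, name, format = c("tsv", "bed")) {
  format <- match.arg(format)
  abort_if(!file.exists(path), "file not found: %s", path)
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    x <- readr::read_tsv(path,
      col_names = c("chrom", "bed_start", "bed_end", "feature_id", "score", "strand"),
      show_col_types = FALSE, progress = FALSE)
    x <- dplyr::transmute(x, chrom = .data$chrom,
                          start = as.integer(.data$bed_start) + 1L,
                          stop = as.integer(.data$bed_end),
                          strand = .data$strand, feature_id = .data$feature_id)
  }
  annotation_track(x, name)
}

#' @rdname read_track
#' @param track an `srna_track`.
#' @export
write_track <- function(track, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as.data.frame(unclass(track))[
      , c("chrom", "start", "stop", "strand", "feature_id")], path)
  } else {
    bed <- dplyr::transmute(tibble::as_tibble(unclass(track)),
                            chrom = .data$chrom,
                            bed_start = .data$start - 1L,
                            bed_end = .data$stop,
                            feature_id = .data$feature_id,
                            score = 0L, strand = .data$strand)
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}

#' Extract a genome subsequence (1-based inclusive)
#'
#' @param g an `srna_genome`.
#' @param chrom chromosome name.
#' @param start,stop 1-based inclusive coordinates.
#' @param strand `"+"` returns the plus-strand slice; `"-"` its reverse
#'   complement.
#' @return character scalar.
#' @export
genome_slice <- function(g, chrom, start, stop, strand = "+") {
  abort_if(!chrom %in% names(g), "chromosome '%s' not in genome", chrom)
  abort_if(start < 1 || stop > nchar(g[[chrom]]) || start > stop,
           "slice %d-%d outside chromosome '%s' (1-%d)",
           start, stop, chrom, nchar(g[[chrom]]))
  s <- substr(g[[chrom]], start, stop)
  if (strand == "-") s <- revcomp(s)
  s
}
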