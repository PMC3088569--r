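#' Select candidate tags for novel miRNA discovery
#'
#' Candidates are the unique-locus tags annotated to RefSeq, EST or nothing
#' (`unique_no_annotation`): repeats, infrastructure ncRNAs and known
#' miRNAs are excluded, as are multi-locus tags. No abundance floor is
#' applied — single-count tags are retained.
#'
#' @param records tibble from [annotate_tags()].
#' @param hits tibble from [align_tags()].
#' @param classified classified tag table from [classify_adaptors()]
#'   (collapsed tags with insert columns).
#' @return tibble with one row per candidate: tag metadata, the mature
#'   (insert) sequence, and the genomic locus of the mature sequence
#'   inferred from the tag's single non-redundant hit.
#' @export
select_candidates <- function(records, hits, classified) {
  eligible <- records |>
    dplyr::filter(.data$category %in% c("refseq", "est", "unique_no_annotation")) |>
    dplyr::rename(source_annotation = "category")
  loci <- hits |>
    dplyr::filter(!.data$redundant, .data$uniqueness == "unique") |>
    dplyr::select("tag_id", "end_used", "chrom", "start", "stop", "strand")
  out <- eligible |>
    dplyr::inner_join(loci, by = "tag_id") |>
    dplyr::inner_join(
      classified[, c("tag_id", "sequence", "count", "overlap_5p", "overlap_3p",
                     "insert", "insert_length")],
      by = "tag_id")
  if (nrow(out) == 0) {
    return(dplyr::mutate(out, mature = character(0), mature_start = integer(0),
                         mature_stop = integer(0)))
  }
  # genomic span of the insert, projected through the matched end query:
  # tag position p maps to start + (p - qpos) on '+', stop - (p - qpos) on '-'
  # where qpos is the tag position at the query's 5' genomic edge
  rl <- nchar(out$sequence)
  k <- out$stop - out$start + 1L
  qpos <- ifelse(out$end_used == "end3", 1L, rl - k + 1L)
  p1 <- out$overlap_5p + 1L
  p2 <- rl - out$overlap_3p
  out |>
    dplyr::mutate(
      mature = .data$insert,
      mature_start = as.integer(ifelse(.data$strand == "+",
                                       .data$start + (p1 - qpos),
                                       .data$stop - (p2 - qpos))),
      mature_stop = as.integer(ifelse(.data$strand == "+",
                                      .data$start + (p2 - qpos),
                                      .data$stop - (p1 - qpos)))) |>
    dplyr::select("tag_id", "source_annotation", "count", "mature",
                  "insert_length", "chrom", "mature_start", "mature_stop",
                  "strand")
}

#' Extract a flanking genomic window around a locus
#'
#' Returns the window `[start - flank, stop + flank]` read on the locus
#' strand (reverse-complemented for `-`), truncated at chromosome ends with
#' the offsets recorded so window coordinates remain convertible to genomic
#' ones. `mature_offset` is the 1-based position of the locus start within
#' the returned (strand-oriented) window.
#'
#' @param g an [genome()] object.
#' @param chrom,start,stop,strand the locus (1-based inclusive).
#' @param flank flanking width in nt; must lie in
#'   `[config$flank_min, config$flank_max]`.
#' @param config an [run_config()] object.
#' @return list with `window`, `win_start`, `win_stop` (plus-strand genomic
#'   bounds), `strand`, `mature_offset`, `mature_length`.
#' @export
extract_window <- function(g, chrom, start, stop, strand = "+",
                           flank = NULL, config = run_config()) {
  if (is.null(flank)) flank <- config$flank_default
  abort_if(flank < config$flank_min || flank > config$flank_max,
           "flank %d outside [%d, %d]", flank, config$flank_min, config$flank_max)
  abort_if(!chrom %in% names(g), "chromosome '%s' not in genome", chrom)
  clen <- nchar(g[[chrom]])
  abort_if(start < 1 || stop > clen || start > stop,
           "locus %d-%d outside chromosome '%s'", start, stop, chrom)
  win_start <- max(1L, as.integer(start - flank))
  win_stop <- min(clen, as.integer(stop + flank))
  window <- genome_slice(g, chrom, win_start, win_stop, strand)
  mature_offset <- if (strand == "+") start - win_start + 1L else win_stop - stop + 1L
  list(window = window, chrom = chrom, win_start = win_start,
       win_stop = win_stop, strand = strand,
       mature_offset = as.integer(mature_offset),
       mature_length = as.integer(stop - start + 1L))
}

#' Evaluate a precursor structure against the hairpin criteria
#'
#' The seven acceptance flags:
#' \describe{
#'   \item{length_ok}{precursor length within the final size range
#'     (default 60-80 nt).}
#'   \item{mfe_ok}{free energy at or below the MFE cutoff (default
#'     -30 kcal/mol).}
#'   \item{unbranched_ok}{exactly one terminal hairpin loop (no multiloop,
#'     no multiple stems).}
#'   \item{arm_ok}{the mature sequence lies entirely within one arm — no
#'     mature nucleotide participates in or crosses the terminal loop.}
#'   \item{pairing_ok}{at least `min_mature_pairs` mature nucleotides are
#'     paired to the opposite arm; with `mature_pair_mode = "total"` all
#'     paired mature positions count, with `"contiguous"` only the unbroken
#'     run from the mature 5' end.}
#'   \item{loop_ok}{no interior loop side longer than `max_internal_loop`.}
#'   \item{bulge_ok}{no interior loop with side-length difference above
#'     `max_bulge_asymmetry`.}
#' }
#' The verdict is the conjunction of all seven.
#'
#' @param fold an [fold_min_energy()] result for the precursor.
#' @param mature_offset 1-based start of the mature sequence within the
#'   precursor.
#' @param mature_length mature length in nt.
#' @param config an [run_config()] object.
#' @return list with `flags` (named logical), `verdict`, `mature_arm`
#'   (`"5p"`, `"3p"` or `"spans_loop"`), `n_mature_pairs`.
#' @export
evaluate_precursor <- function(fold, mature_offset, mature_length,
                               config = run_config()) {
  n <- nchar(fold$sequence)
  m1 <- mature_offset
  m2 <- mature_offset + mature_length - 1L
  abort_if(m1 < 1 || m2 > n, "mature sequence outside precursor")
  partner <- pairs_to_partner(fold$pairs, n)
  dec <- structure_loops(fold$pairs)
  p <- dec$pairs
  n_children <- lengths(dec$children)
  hairpin_idx <- which(n_children == 0)
  interior_idx <- which(n_children == 1)

  length_ok <- n >= config$precursor_final_min & n <= config$precursor_final_max
  mfe_ok <- fold$energy <= config$mfe_cutoff
  unbranched_ok <- length(hairpin_idx) == 1 && length(dec$roots) == 1

  mature_arm <- NA_character_
  n_mature_pairs <- 0L
  arm_ok <- FALSE
  pairing_ok <- FALSE
  if (length(hairpin_idx) == 1) {
    hi <- p[hairpin_idx, 1]
    hj <- p[hairpin_idx, 2]
    mature_arm <- if (m2 <= hi) "5p" else if (m1 >= hj) "3p" else "spans_loop"
    arm_ok <- mature_arm != "spans_loop"
    if (arm_ok) {
      pos <- m1:m2
      opposite <- if (mature_arm == "5p") partner[pos] >= hj else
        (partner[pos] > 0 & partner[pos] <= hi)
      n_mature_pairs <- if (config$mature_pair_mode == "total") {
        sum(opposite)
      } else {
        # run of consecutively opposite-paired positions from the mature 5' end
        as.integer(which.min(c(opposite, FALSE)) - 1L)
      }
      pairing_ok <- n_mature_pairs >= config$min_mature_pairs
    }
  }

  side_max <- 0L
  asym_max <- 0L
  for (k in interior_idx) {
    child <- dec$children[[k]]
    n1 <- p[child, 1] - p[k, 1] - 1L
    n2 <- p[k, 2] - p[child, 2] - 1L
    side_max <- max(side_max, n1, n2)
    asym_max <- max(asym_max, abs(n1 - n2))
  }
  flags <- c(length_ok = length_ok, mfe_ok = mfe_ok,
             arm_ok = arm_ok, pairing_ok = pairing_ok,
             loop_ok = side_max <= config$max_internal_loop,
             bulge_ok = asym_max <= config$max_bulge_asymmetry,
             unbranched_ok = unbranched_ok)
  list(flags = flags, verdict = all(flags), mature_arm = mature_arm,
       n_mature_pairs = n_mature_pairs)
}

new_hairpin_candidate <- function(window_info, fold, eval, sub_start,
                                  mature_offset_in_sub, mature_length) {
  L <- nchar(fold$sequence)
  # genomic bounds of the precursor subwindow
  if (is.null(window_info)) {
    locus <- list(chrom = NA_character_, start = NA_integer_,
                  stop = NA_integer_, strand = NA_character_)
  } else if (window_info$strand == "+") {
    s <- window_info$win_start + sub_start - 1L
    locus <- list(chrom = window_info$chrom, start = s, stop = s + L - 1L,
                  strand = "+")
  } else {
    e <- window_info$win_stop - sub_start + 1L
    locus <- list(chrom = window_info$chrom, start = e - L + 1L, stop = e,
                  strand = "-")
  }
  structure(list(
    precursor = fold$sequence, chrom = locus$chrom, start = locus$start,
    stop = locus$stop, strand = locus$strand, structure = fold,
    energy = fold$energy, mature_offset = mature_offset_in_sub,
    mature_length = mature_length, mature_arm = eval$mature_arm,
    n_mature_pairs = eval$n_mature_pairs, flags = eval$flags,
    verdict = eval$verdict), class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("<hairpin_candidate> %d nt %s:%s-%s(%s) %.2f kcal/mol verdict=%s\n",
              nchar(x$precursor), x$chrom, x$start, x$stop, x$strand,
              x$energy, x$verdict))
  cat(" ", x$precursor, "\n ", x$structure$dotbracket, "\n")
  cat("  flags:", paste(names(x$flags)[!x$flags], collapse = " "),
      if (all(x$flags)) "(all pass)" else "(failing)", "\n")
  invisible(x)
}

#' Scan a flanking window for the best passing precursor
#'
#' Enumerates every subwindow in the scan length range (default 60-150 nt)
#' that fully contains the mature sequence, scores each by MFE from a single
#' table fill, and — in order of increasing energy, then shorter precursor,
#' then 5'-most position — folds and evaluates candidates until one passes
#' all seven criteria. Subwindows whose energy is above the MFE cutoff or
#' whose length is outside the final precursor range can never pass and are
#' skipped without folding.
#'
#' @param window window sequence, or a list from [extract_window()].
#' @param mature_offset,mature_length mature placement within the window
#'   (taken from the window list if given).
#' @param config an [run_config()] object.
#' @return the best passing [`hairpin_candidate`][evaluate_precursor] or
#'   `NULL` when no subwindow passes.
#' @export
scan_precursors <- function(window, mature_offset = NULL,
                            mature_length = NULL, config = run_config()) {
  window_info <- NULL
  if (is.list(window)) {
    window_info <- window
    mature_offset <- window_info$mature_offset
    mature_length <- window_info$mature_length
    window <- window_info$window
  }
  abort_if(is.null(mature_offset) || is.null(mature_length),
           "mature_offset and mature_length are required")
  m2 <- mature_offset + mature_length - 1L
  abort_if(mature_offset < 1 || m2 > nchar(window),
           "mature sequence outside window")
  if (nchar(window) < config$precursor_scan_min) return(NULL)
  sub <- subwindow_energies(window, mature_offset, m2,
                            config$precursor_scan_min, config$precursor_scan_max)
  sub <- sub |>
    dplyr::filter(.data$energy <= config$mfe_cutoff,
                  .data$len >= config$precursor_final_min,
                  .data$len <= config$precursor_final_max) |>
    dplyr::arrange(.data$energy, .data$len, .data$start)
  for (r in seq_len(nrow(sub))) {
    s <- sub$start[r]
    L <- sub$len[r]
    fold <- fold_min_energy(substr(window, s, s + L - 1L))
    eval <- evaluate_precursor(fold, mature_offset - s + 1L, mature_length,
                               config)
    if (eval$verdict) {
      return(new_hairpin_candidate(window_info, fold, eval, s,
                                   mature_offset - s + 1L, mature_length))
    }
  }
  NULL
}

#' Homology search of a mature sequence against known miRNAs
#'
#' Full-length matches use Levenshtein edit distance (threshold
#' `config$homology_max_edit`); seed matches require exact identity of the
#' seed sequence, nucleotides 2-8 of the mature miRNA.
#'
#' @param mature mature sequence (>= 8 nt).
#' @param known_mirnas tibble with `id` and `sequence`.
#' @param config an [run_config()] object.
#' @return list of tibbles `full_length` (`id`, `distance`) and `seed`
#'   (`id`).
#' @export
search_mirna_homology <- function(mature, known_mirnas, config = run_config()) {
  abort_if(nchar(mature) < 8, "mature sequence shorter than 8 nt")
  norm <- function(x) chartr("Uu", "Tt", toupper(x))
  m <- norm(mature)
  if (nrow(known_mirnas) == 0) {
    return(list(full_length = tibble::tibble(id = character(), distance = integer()),
                seed = tibble::tibble(id = character())))
  }
  kn <- norm(known_mirnas$sequence)
  d <- as.integer(utils::adist(m, kn))
  full <- tibble::tibble(id = known_mirnas$id, distance = d) |>
    dplyr::filter(.data$distance <= config$homology_max_edit) |>
    dplyr::arrange(.data$distance, .data$id)
  seed <- tibble::tibble(id = known_mirnas$id[
    substr(kn, 2, 8) == substr(m, 2, 8)])
  list(full_length = full, seed = seed)
}
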