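#' Synthetic dataset generator configuration
#'
#' The defaults emulate the read composition the pipeline was designed for:
#' fixed 36-nt reads; adaptor-class fractions 82.1% legitimate inserts, 6.9%
#' adaptor-free contamination from longer transcripts and 11.0% adaptor-only
#' cloning artefacts; inserts of 16-30 nt dominated by ~22-nt miRNAs; a
#' heavy-tailed (log-normal) abundance law over features; and a genome small
#' enough (100 kb over 3 chromosomes) that exhaustive-scan alignment oracles
#' stay tractable while 22-mers remain unique with high probability.
#'
#' Within the legitimate class, reads are split across feature kinds so that
#' known miRNAs carry ~60% of legitimate reads (~49.6% of all reads) with
#' minor repeat/ncRNA/RefSeq/EST components and a small novel-miRNA and
#' unannotated component, mirroring the annotation mix of a developing-brain
#' small RNA library.
#'
#' @param genome_size total genome length (nt).
#' @param n_chrom number of chromosomes.
#' @param n_reads reads to emit.
#' @param class_fractions named fractions (`legitimate`, `no_adaptor`,
#'   `adaptor_only`), summing to 1.
#' @param kind_fractions named fractions of legitimate reads per feature
#'   kind, summing to 1.
#' @param n_known_mirna,n_novel_mirna,n_repeat,n_ncrna,n_refseq,n_est,n_anon
#'   planted feature counts (`n_anon`: legitimate inserts at unannotated
#'   unique loci).
#' @param n_noadaptor_frag distinct 36-nt transcript fragments for the
#'   `no_adaptor` class.
#' @param n_random distinct non-genomic inserts for the unmatched class.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance-law
#'   parameters over features within a kind.
#' @param rng_seed integer seed; identical seeds give byte-identical output.
#' @return list of class `srna_gen_config`.
#' @export
generator_config <- function(genome_size = 100000L,
                             n_chrom = 3L,
                             n_reads = 100000L,
                             class_fractions = c(legitimate = 0.821,
                                                 no_adaptor = 0.069,
                                                 adaptor_only = 0.110),
                             kind_fractions = c(known_mirna = 0.600,
                                                repeat_frag = 0.075,
                                                ncrna_frag = 0.006,
                                                refseq_frag = 0.002,
                                                est_frag = 0.016,
                                                anon_frag = 0.003,
                                                novel_mirna = 0.008,
                                                random_unmapped = 0.290),
                             n_known_mirna = 40L, n_novel_mirna = 4L,
                             n_repeat = 12L, n_ncrna = 8L, n_refseq = 10L,
                             n_est = 10L, n_anon = 6L,
                             n_noadaptor_frag = 25L, n_random = 30L,
                             abundance_meanlog = 2, abundance_sdlog = 2,
                             rng_seed = 1L) {
  abort_if(abs(sum(class_fractions) - 1) > 1e-9,
           "class fractions must sum to 1")
  abort_if(abs(sum(kind_fractions) - 1) > 1e-9,
           "kind fractions must sum to 1")
  structure(as.list(environment()), class = "srna_gen_config")
}

rand_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Construct a hairpin precursor guaranteed to pass the criteria
#'
#' Builds a precursor as a complementary stem (GC-biased for stability) of
#' `stem_length` base pairs closed by a `loop_length`-nt terminal loop, with
#' optionally `n_bulges` small symmetric internal loops, and the mature
#' sequence as the first `mature_length` nt of the 5' arm. The construct is
#' folded and checked with [evaluate_precursor()]; random letters are
#' redrawn until the verdict passes (the loop can otherwise occasionally
#' pair into the arms).
#'
#' Uses the session RNG; seed externally for reproducibility.
#'
#' @param mature_length mature length (nt).
#' @param stem_length stem base pairs.
#' @param loop_length terminal loop size (nt).
#' @param n_bulges number of symmetric internal loops inserted.
#' @param bulge_size side length of each inserted internal loop.
#' @param config an [run_config()] object (criteria to satisfy).
#' @param max_tries redraw attempts before giving up.
#' @return list with `precursor` (DNA), `mature`, `structure` (an
#'   `rna_fold`), and `evaluation` (from [evaluate_precursor()]).
#' @export
plant_hairpin <- function(mature_length = 22L, stem_length = 28L,
                          loop_length = 8L, n_bulges = 0L, bulge_size = 1L,
                          config = run_config(), max_tries = 50L) {
  plen <- 2L * (stem_length + n_bulges * bulge_size) + loop_length
  abort_if(plen < config$precursor_final_min || plen > config$precursor_final_max,
           "precursor length %d outside [%d, %d]",
           plen, config$precursor_final_min, config$precursor_final_max)
  abort_if(mature_length > stem_length,
           "mature (%d nt) longer than the stem (%d bp)",
           mature_length, stem_length)
  gc_prob <- c(0.2, 0.3, 0.3, 0.2)
  for (try in seq_len(max_tries)) {
    stem5 <- strsplit(rand_dna(stem_length, gc_prob), "")[[1]]
    arm3 <- strsplit(revcomp(paste(stem5, collapse = "")), "")[[1]]
    # a G.U wobble inside the mature span: stems of real precursors are
    # imperfect, and a perfect stem would place an exact reverse complement
    # of the mature query on the star arm, destroying unique mapping
    wp <- sample(6:min(16L, mature_length - 2L), 1)
    stem5[wp] <- "G"
    arm3[stem_length - wp + 1L] <- "T"
    arm5 <- stem5
    if (n_bulges > 0) {
      qs <- sort(sample(seq(5L, stem_length - 5L), n_bulges))
      for (b in rev(seq_len(n_bulges))) {
        q <- qs[b]
        ins5 <- strsplit(rand_dna(bulge_size, gc_prob), "")[[1]]
        ins3 <- strsplit(rand_dna(bulge_size, gc_prob), "")[[1]]
        arm5 <- append(arm5, ins5, after = q)
        arm3 <- append(arm3, ins3, after = stem_length - q)
      }
    }
    loop <- rand_dna(loop_length)
    precursor <- paste0(paste(arm5, collapse = ""), loop,
                        paste(arm3, collapse = ""))
    fold <- fold_min_energy(precursor)
    ev <- evaluate_precursor(fold, 1L, mature_length, config)
    if (ev$verdict) {
      return(list(precursor = precursor,
                  mature = substr(precursor, 1L, mature_length),
                  structure = fold, evaluation = ev))
    }
  }
  stop(sprintf("no passing hairpin found in %d tries", max_tries), call. = FALSE)
}

# non-overlapping placement blocks across chromosomes; features are centred
# in their own block so flanking windows only reach random background
allocate_blocks <- function(chrom_lengths, n_needed, block = 600L) {
  slots <- purrr::imap(chrom_lengths, function(len, chrom) {
    n_blocks <- len %/% block
    if (n_blocks == 0) return(NULL)
    tibble::tibble(chrom = chrom, block_start = (seq_len(n_blocks) - 1L) * block + 1L)
  })
  slots <- dplyr::bind_rows(slots)
  abort_if(nrow(slots) < n_needed,
           "genome too small: %d placement blocks for %d features",
           nrow(slots), n_needed)
  slots[sample.int(nrow(slots), n_needed), ]
}

# largest-remainder apportionment of n into parts proportional to w
apportion <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# heavy-tailed per-feature counts summing to n (each feature may get 0)
lognormal_counts <- function(n, n_features, meanlog, sdlog) {
  if (n_features == 0 || n == 0) return(integer(n_features))
  w <- stats::rlnorm(n_features, meanlog, sdlog)
  as.integer(stats::rmultinom(1, n, w / sum(w)))
}

assemble_read <- function(insert, adaptor_3p, read_length) {
  need <- read_length - nchar(insert)
  paste0(insert, substr(adaptor_3p, 1L, need))
}

#' Generate a synthetic small RNA dataset with ground truth
#'
#' Builds a random genome, plants annotated features (repeats — some at two
#' loci to exercise multi-mapping —, infrastructure ncRNAs, RefSeq- and
#' EST-like transcripts, known miRNA precursors) by sampling feature
#' sequences from the genome itself, splices in constructed novel miRNA
#' hairpins verified to pass [evaluate_precursor()], and emits a read
#' multiset that exactly matches the returned truth table: legitimate reads
#' are insert + 3'-adaptor fill, `no_adaptor` reads are 36-nt transcript
#' interiors, `adaptor_only` reads are 5'/3' adaptor dimers.
#'
#' Planted 22-mers are checked against the genome: a feature whose end query
#' occurs at unplanned loci (or collides with another feature's) is flagged
#' `collision = TRUE` in the truth table rather than silently kept, so
#' uniqueness ground truth is exact.
#'
#' @param gcfg a [generator_config()].
#' @param config an [run_config()] (adaptors, read length, criteria).
#' @return list with `genome`, `tracks` (named list of 5), `mirna_meta`,
#'   `reads` (character vector), `truth` (tibble; one row per planted
#'   feature) and the two configs.
#' @export
generate_dataset <- function(gcfg = generator_config(), config = run_config()) {
  withr::with_seed(gcfg$rng_seed, generate_dataset_impl(gcfg, config))
}

generate_dataset_impl <- function(gcfg, config) {
  rl <- config$read_length
  chrom_lengths <- stats::setNames(
    rep(gcfg$genome_size %/% gcfg$n_chrom, gcfg$n_chrom),
    paste0("chr", seq_len(gcfg$n_chrom)))
  seqs <- purrr::map_chr(chrom_lengths, rand_dna)
  n_dup_repeat <- gcfg$n_repeat %/% 3L       # repeats planted at two loci
  n_blocks <- gcfg$n_known_mirna + gcfg$n_novel_mirna + gcfg$n_repeat +
    n_dup_repeat + gcfg$n_ncrna + gcfg$n_refseq + gcfg$n_est + gcfg$n_anon
  blocks <- allocate_blocks(chrom_lengths, n_blocks)
  bi <- 0L
  next_block <- function() {
    bi <<- bi + 1L
    blocks[bi, ]
  }
  truth <- list()
  tracks <- list()

  place_feature <- function(kind, id, feat_len, track, insert_len,
                            dup_of = NULL) {
    slot <- next_block()
    start <- slot$block_start + (600L - feat_len) %/% 2L
    stop <- start + feat_len - 1L
    strand <- sample(c("+", "-"), 1)
    if (!is.null(dup_of)) {
      # copy the original feature's sequence to this second locus
      src <- dup_of
      seq_plus <- genome_slice(genome(seqs), src$chrom, src$start, src$stop, "+")
      substr(seqs[[slot$chrom]], start, stop) <<- seq_plus
    }
    list(kind = kind, id = id, chrom = slot$chrom, start = start, stop = stop,
         strand = strand, track = track, insert_len = insert_len)
  }

  feats <- list()
  # repeats: feature sequence is the genome substring; duplicated copies
  for (i in seq_len(gcfg$n_repeat)) {
    f <- place_feature("repeat_frag", paste0("rep_", i),
                       sample(80:200, 1), "repeat",
                       sample(22:30, 1))
    feats[[length(feats) + 1L]] <- f
    if (i <= n_dup_repeat) {
      f2 <- place_feature("repeat_frag", paste0("rep_", i),
                          f$stop - f$start + 1L, "repeat", f$insert_len,
                          dup_of = f)
      f2$strand <- f$strand
      f2$dup <- TRUE
      feats[[length(feats) + 1L]] <- f2
    }
  }
  for (i in seq_len(gcfg$n_ncrna)) {
    feats[[length(feats) + 1L]] <- place_feature(
      "ncrna_frag", paste0("ncrna_", i), sample(70:150, 1), "ncrna",
      sample(22:30, 1))
  }
  for (i in seq_len(gcfg$n_refseq)) {
    feats[[length(feats) + 1L]] <- place_feature(
      "refseq_frag", paste0("refseq_", i), sample(200:400, 1), "refseq",
      sample(22:30, 1))
  }
  for (i in seq_len(gcfg$n_est)) {
    feats[[length(feats) + 1L]] <- place_feature(
      "est_frag", paste0("est_", i), sample(150:300, 1), "est",
      sample(22:30, 1))
  }
  for (i in seq_len(gcfg$n_known_mirna)) {
    feats[[length(feats) + 1L]] <- place_feature(
      "known_mirna", paste0("mir_", i), 22L + 50L, "mirna",
      sample(22:23, 1, prob = c(0.7, 0.3)))
  }
  for (i in seq_len(gcfg$n_anon)) {
    feats[[length(feats) + 1L]] <- place_feature(
      "anon_frag", paste0("anon_", i), sample(60:120, 1), NA_character_,
      sample(22:30, 1))
  }
  # novel miRNA hairpins: constructed, verified, then spliced into the genome;
  # stem/loop/bulge draws are constrained to 70-78 nt precursors, the size
  # range of validated novel pre-miRNAs in developing-brain libraries
  novels <- list()
  for (i in seq_len(gcfg$n_novel_mirna)) {
    repeat {
      stem <- sample(28:30, 1)
      loop <- sample(4:10, 1)
      nb <- sample(0:2, 1)
      bs <- sample(1:2, 1)
      plen <- 2L * (stem + nb * bs) + loop
      if (plen >= 70L && plen <= 78L) break
    }
    hp <- plant_hairpin(sample(22:23, 1), stem, loop,
                        n_bulges = nb, bulge_size = bs, config = config)
    plen <- nchar(hp$precursor)
    slot <- next_block()
    start <- slot$block_start + (600L - plen) %/% 2L
    stop <- start + plen - 1L
    strand <- sample(c("+", "-"), 1)
    spliced <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
    # unstructured single-stranded basal segments flank real pre-miRNAs
    # (required for Microprocessor cleavage): emulate with 6-nt poly-A
    # spacers on the precursor's strand
    spacer <- strrep(if (strand == "+") "A" else "T", 6L)
    substr(seqs[[slot$chrom]], start - 6L, start - 1L) <- spacer
    substr(seqs[[slot$chrom]], stop + 1L, stop + 6L) <- spacer
    substr(seqs[[slot$chrom]], start, stop) <- spliced
    novels[[i]] <- list(hp = hp, chrom = slot$chrom, start = start,
                        stop = stop, strand = strand)
    mlen <- nchar(hp$mature)
    feats[[length(feats) + 1L]] <- list(
      kind = "novel_mirna", id = paste0("novel_", i), chrom = slot$chrom,
      start = if (strand == "+") start else stop - mlen + 1L,
      stop = if (strand == "+") start + mlen - 1L else stop,
      strand = strand, track = NA_character_, insert_len = mlen,
      precursor = hp$precursor, precursor_start = start,
      precursor_stop = stop, dotbracket = hp$structure$dotbracket)
  }

  g <- genome(seqs)

  # feature insert sequences: read off the (possibly re-spliced) genome; the
  # insert is the 5'-anchored slice of the feature on its strand
  feat_tbl <- purrr::map_dfr(feats, function(f) {
    L <- f$insert_len
    if (f$strand == "+") {
      ins <- genome_slice(g, f$chrom, f$start, f$start + L - 1L, "+")
      ms <- f$start; me <- f$start + L - 1L
    } else {
      ins <- genome_slice(g, f$chrom, f$stop - L + 1L, f$stop, "-")
      ms <- f$stop - L + 1L; me <- f$stop
    }
    tibble::tibble(kind = f$kind, feature_id = f$id, chrom = f$chrom,
                   feat_start = f$start, feat_stop = f$stop,
                   strand = f$strand, track = f$track,
                   insert = ins, mature_start = ms, mature_stop = me,
                   is_dup = isTRUE(f$dup),
                   precursor = if (!is.null(f$precursor)) f$precursor else NA_character_,
                   precursor_start = if (!is.null(f$precursor_start)) f$precursor_start else NA_integer_,
                   precursor_stop = if (!is.null(f$precursor_stop)) f$precursor_stop else NA_integer_,
                   dotbracket = if (!is.null(f$dotbracket)) f$dotbracket else NA_character_)
  })

  # annotation tracks (1-based inclusive intervals); known-miRNA intervals
  # span the precursor context around the mature sequence
  mk_track <- function(nm) {
    rows <- dplyr::filter(feat_tbl, .data$track == nm, !is.na(.data$track))
    annotation_track(tibble::tibble(
      chrom = rows$chrom, start = rows$feat_start, stop = rows$feat_stop,
      strand = rows$strand, feature_id = rows$feature_id), nm)
  }
  tracks <- stats::setNames(lapply(TRACK_NAMES, mk_track), TRACK_NAMES)
  mirna_rows <- dplyr::filter(feat_tbl, .data$kind == "known_mirna")
  mirna_meta <- tibble::tibble(
    feature_id = mirna_rows$feature_id,
    mirna_id = paste0("syn-mir-", sub("^mir_", "", mirna_rows$feature_id)),
    accession = sprintf("SYN%07d", seq_len(nrow(mirna_rows))),
    chrom = mirna_rows$chrom, start = mirna_rows$feat_start,
    stop = mirna_rows$feat_stop, strand = mirna_rows$strand)

  # ---- read-bearing truth rows -------------------------------------------
  # distinct tags for the three adaptor classes
  legit <- feat_tbl |>
    dplyr::filter(!.data$is_dup) |>
    dplyr::mutate(adaptor_class = "legitimate",
                  read = purrr::map_chr(.data$insert, assemble_read,
                                        adaptor_3p = config$adaptor_3p,
                                        read_length = rl))
  # no-adaptor contamination: 36-nt interiors of refseq/est transcripts
  pool <- dplyr::filter(feat_tbl, .data$kind %in% c("refseq_frag", "est_frag"),
                        !.data$is_dup)
  noad <- purrr::map_dfr(seq_len(gcfg$n_noadaptor_frag), function(i) {
    for (try in 1:50) {
      src <- pool[sample.int(nrow(pool), 1), ]
      lo <- src$feat_start + sample.int(src$feat_stop - src$feat_start - rl, 1)
      frag <- genome_slice(g, src$chrom, lo, lo + rl - 1L, src$strand)
      cls <- classify_adaptors(frag, config)
      if (cls$category[1] == "no_adaptor") {
        return(tibble::tibble(kind = src$kind, feature_id = paste0("noad_", i),
                              chrom = src$chrom, strand = src$strand,
                              mature_start = lo, mature_stop = lo + rl - 1L,
                              adaptor_class = "no_adaptor", insert = frag,
                              read = frag))
      }
    }
    stop("could not draw an adaptor-free transcript fragment", call. = FALSE)
  })
  # random unmatched inserts: verified absent from the genome
  genome_has <- function(q) {
    any(purrr::map_lgl(seqs, function(s) {
      grepl(q, s, fixed = TRUE) || grepl(revcomp(q), s, fixed = TRUE)
    }))
  }
  rnd <- purrr::map_dfr(seq_len(gcfg$n_random), function(i) {
    for (try in 1:50) {
      ins <- rand_dna(sample(16:30, 1))
      probe <- substr(ins, 1L, min(nchar(ins), config$end_query_length))
      if (!genome_has(probe)) {
        return(tibble::tibble(kind = "random_unmapped",
                              feature_id = paste0("rand_", i),
                              chrom = NA_character_, strand = NA_character_,
                              mature_start = NA_integer_, mature_stop = NA_integer_,
                              adaptor_class = "legitimate", insert = ins,
                              read = assemble_read(ins, config$adaptor_3p, rl)))
      }
    }
    stop("could not draw a non-genomic insert", call. = FALSE)
  })
  # adaptor dimers: j nt of the 5' adaptor tail + (36 - j) nt of the 3' head
  a5 <- config$adaptor_5p
  dimer_j <- seq(rl - nchar(config$adaptor_3p), min(nchar(a5), rl - config$min_adaptor_overlap))
  dimers <- tibble::tibble(
    kind = "adaptor_only", feature_id = paste0("dimer_", dimer_j),
    chrom = NA_character_, strand = NA_character_,
    mature_start = NA_integer_, mature_stop = NA_integer_,
    adaptor_class = "adaptor_only", insert = "",
    read = paste0(substring(a5, nchar(a5) - dimer_j + 1L, nchar(a5)),
                  substring(config$adaptor_3p, 1L, rl - dimer_j)))

  # ---- read counts --------------------------------------------------------
  class_n <- stats::setNames(
    as.integer(stats::rmultinom(1, gcfg$n_reads, gcfg$class_fractions)),
    names(gcfg$class_fractions))
  kf <- gcfg$kind_fractions
  legit_split <- stats::setNames(apportion(class_n[["legitimate"]], kf), names(kf))

  count_kind <- function(tbl, n_kind, even = FALSE) {
    if (nrow(tbl) == 0) return(integer(0))
    if (even) {
      cnt <- apportion(n_kind, rep(1, nrow(tbl)))
    } else {
      cnt <- lognormal_counts(n_kind, nrow(tbl), gcfg$abundance_meanlog,
                              gcfg$abundance_sdlog)
    }
    cnt
  }
  legit$count <- 0L
  for (kd in c("known_mirna", "repeat_frag", "ncrna_frag", "refseq_frag",
               "est_frag", "anon_frag")) {
    sel <- legit$kind == kd
    legit$count[sel] <- count_kind(legit[sel, ], legit_split[[kd]],
                                   even = kd %in% c("refseq_frag", "anon_frag"))
  }
  sel <- legit$kind == "novel_mirna"
  legit$count[sel] <- count_kind(legit[sel, ], legit_split[["novel_mirna"]],
                                 even = TRUE)
  rnd$count <- count_kind(rnd, legit_split[["random_unmapped"]])
  noad$count <- count_kind(noad, class_n[["no_adaptor"]])
  dimers$count <- count_kind(dimers, class_n[["adaptor_only"]])

  truth <- dplyr::bind_rows(
    dplyr::transmute(legit, .data$kind, .data$feature_id, .data$chrom,
                     .data$strand, .data$mature_start, .data$mature_stop,
                     .data$adaptor_class, .data$insert, .data$read,
                     .data$count, .data$precursor, .data$precursor_start,
                     .data$precursor_stop, .data$dotbracket),
    dplyr::mutate(noad, precursor = NA_character_,
                  precursor_start = NA_integer_, precursor_stop = NA_integer_,
                  dotbracket = NA_character_),
    dplyr::mutate(rnd, precursor = NA_character_,
                  precursor_start = NA_integer_, precursor_stop = NA_integer_,
                  dotbracket = NA_character_),
    dplyr::mutate(dimers, precursor = NA_character_,
                  precursor_start = NA_integer_, precursor_stop = NA_integer_,
                  dotbracket = NA_character_))

  # collision audit: distinct reads, and each genomic feature's 22-nt end
  # query occurring only at its planted loci
  count_occ <- function(q, s) {
    m <- gregexpr(q, s, fixed = TRUE)[[1]]
    sum(m > 0)
  }
  truth$collision <- duplicated(truth$read) | duplicated(truth$read, fromLast = TRUE)
  for (r in which(!is.na(truth$chrom) & truth$adaptor_class == "legitimate")) {
    q <- substr(truth$insert[r], 1L, config$end_query_length)
    n_genome <- sum(purrr::map_int(
      seqs, function(s) count_occ(q, s) + count_occ(revcomp(q), s)))
    n_expected <- if (truth$kind[r] == "repeat_frag")
      sum(feat_tbl$feature_id == truth$feature_id[r]) else 1L
    if (n_genome != n_expected) truth$collision[r] <- TRUE
  }

  reads <- rep(truth$read, truth$count)
  reads <- reads[sample.int(length(reads))]

  list(genome = g, tracks = tracks, mirna_meta = mirna_meta, reads = reads,
       truth = truth, generator_config = gcfg, config = config)
}

#' Write a generated dataset to disk
#'
#' Emits `genome.fasta`, `reads.fastq`, one TSV per annotation track,
#' `truth.tsv`, `mirna_meta.tsv` and `generator_config.yaml`.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(dataset$genome, file.path(dir, "genome.fasta"))
  write_fastq(dataset$reads, file.path(dir, "reads.fastq"))
  for (nm in names(dataset$tracks)) {
    write_track(dataset$tracks[[nm]], file.path(dir, paste0("track_", nm, ".tsv")))
  }
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(dataset$mirna_meta, file.path(dir, "mirna_meta.tsv"))
  yaml::write_yaml(unclass(dataset$generator_config),
                   file.path(dir, "generator_config.yaml"))
  invisible(dir)
}
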