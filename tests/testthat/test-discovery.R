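cfg <- run_config()

test_that("candidate selection keeps unique RefSeq/EST/unannotated tags only", {
  cats <- c("repeat", "ncrna", "mirna", "refseq", "est",
            "unique_no_annotation", "multi_no_annotation")
  records <- tibble::tibble(
    tag_id = paste0("t", 1:7),
    category = factor(c("repeat", "mirna", "refseq", "est",
                        "unique_no_annotation", "multi_no_annotation", "est"),
                      levels = cats),
    feature_id = NA_character_)
  hits <- tibble::tibble(
    tag_id = paste0("t", 1:7), end_used = "end3", chrom = "chr1",
    start = 100L * (1:7), stop = 100L * (1:7) + 21L, strand = "+",
    end_uniqueness = "unique", end_n_loci = 1L, redundant = FALSE,
    n_loci = c(1L, 1L, 1L, 1L, 1L, 3L, 2L),
    uniqueness = c(rep("unique", 5), "multi", "multi"))
  classified <- tibble::tibble(
    tag_id = paste0("t", 1:7), sequence = replicate(7, random_dna(36)),
    count = c(9L, 9L, 1L, 2L, 1L, 9L, 9L),
    overlap_5p = 0L, overlap_3p = 14L,
    insert = substr(replicate(7, random_dna(36)), 1, 22), insert_length = 22L)
  sel <- select_candidates(records, hits, classified)
  # unique refseq/est/unannotated are in -- including the count-1 tags;
  # repeat, mirna and all multi-locus tags are out
  expect_setequal(sel$tag_id, c("t3", "t4", "t5"))
  expect_true(all(sel$count >= 1))
})

test_that("the insert locus projects correctly through either end query", {
  set.seed(71)
  g <- genome(c(chr1 = random_dna(2000)))
  idx <- build_index(g, 22)
  # 26-nt insert: mature spans 4 nt beyond the end3 query
  ins <- genome_slice(g, "chr1", 501, 526, "+")
  tag <- paste0(ins, substr(cfg$adaptor_3p, 1, 10))
  tags <- collapse_reads(rep(tag, 3), "cand")
  classified <- classify_adaptors(tags, cfg)
  hits <- align_tags(tags, idx, cfg)
  records <- annotate_tags(hits, list())
  sel <- select_candidates(records, hits, classified)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$mature_start, 501L)
  expect_equal(sel$mature_stop, 526L)
  expect_equal(sel$mature, ins)

  # minus strand: same projection on the reverse complement
  insm <- genome_slice(g, "chr1", 1001, 1022, "-")
  tagm <- paste0(insm, substr(cfg$adaptor_3p, 1, 14))
  tagsm <- collapse_reads(rep(tagm, 2), "cm")
  selm <- select_candidates(annotate_tags(align_tags(tagsm, idx, cfg), list()),
                            align_tags(tagsm, idx, cfg),
                            classify_adaptors(tagsm, cfg))
  expect_equal(selm$strand, "-")
  expect_equal(c(selm$mature_start, selm$mature_stop), c(1001L, 1022L))
  expect_equal(genome_slice(g, "chr1", selm$mature_start, selm$mature_stop, "-"),
               insm)
})

test_that("window extraction handles flanks, truncation and the minus strand", {
  set.seed(72)
  g <- genome(c(chr1 = random_dna(3000)))
  w <- extract_window(g, "chr1", 1000, 1021, "+", flank = 100, config = cfg)
  expect_equal(nchar(w$window), 222L)
  expect_equal(w$mature_offset, 101L)
  expect_equal(substr(w$window, 101, 122), genome_slice(g, "chr1", 1000, 1021, "+"))

  # left truncation at the chromosome start keeps offsets consistent
  wt <- extract_window(g, "chr1", 10, 31, "+", flank = 100, config = cfg)
  expect_equal(wt$win_start, 1L)
  expect_equal(wt$mature_offset, 10L)
  expect_equal(nchar(wt$window), 131L)

  # minus-strand window is the reverse complement of the plus-strand slice
  wm <- extract_window(g, "chr1", 1000, 1021, "-", flank = 100, config = cfg)
  plus_slice <- substr(g[["chr1"]], 900, 1121)
  expect_equal(wm$window, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(plus_slice))))
  expect_equal(substr(wm$window, wm$mature_offset, wm$mature_offset + 21),
               genome_slice(g, "chr1", 1000, 1021, "-"))

  expect_error(extract_window(g, "chr9", 10, 31, "+", config = cfg), "not in genome")
  expect_error(extract_window(g, "chr1", 10, 31, "+", flank = 50, config = cfg),
               "outside")
})

test_that("precursor criteria flag constructed defects", {
  set.seed(73)
  hp <- plant_hairpin(22, 30, 8)
  ev <- evaluate_precursor(hp$structure, 1L, 22L, cfg)
  expect_true(ev$verdict)
  expect_true(all(ev$flags))
  expect_equal(ev$mature_arm, "5p")
  expect_gte(ev$n_mature_pairs, 16L)

  # synthetic structure with a 15-nt internal loop on one side
  n <- 76L
  mk_fold <- function(pairs, energy, n) {
    structure(list(sequence = strrep("A", n), pairs = pairs, energy = energy,
                   dotbracket = pairs_to_dotbracket(pairs, n)),
              class = "rna_fold")
  }
  stem1 <- cbind(1:10, n + 1 - (1:10))
  stem2 <- cbind(26:36, 56:46)  # interior loop sides 15 and 10
  f <- mk_fold(rbind(stem1, stem2), -40, n)
  ev2 <- evaluate_precursor(f, 1L, 22L, cfg)
  expect_false(ev2$flags[["loop_ok"]])
  expect_false(ev2$flags[["bulge_ok"]])  # asymmetry 15 > 4
  expect_false(ev2$verdict)

  # mature crossing the terminal loop fails arm_ok
  ev3 <- evaluate_precursor(hp$structure, 25L, 22L, cfg)
  expect_false(ev3$flags[["arm_ok"]])
  expect_false(ev3$verdict)

  # energy above the cutoff fails mfe_ok even with perfect geometry
  weak <- hp$structure
  weak$energy <- -10
  ev4 <- evaluate_precursor(weak, 1L, 22L, cfg)
  expect_false(ev4$flags[["mfe_ok"]])

  # length outside 60-80 fails length_ok
  long_pairs <- cbind(1:25, 90 - (1:25))
  f5 <- mk_fold(long_pairs, -45, 90L)
  expect_false(evaluate_precursor(f5, 1L, 22L, cfg)$flags[["length_ok"]])

  expect_error(evaluate_precursor(hp$structure, 60L, 22L, cfg), "outside")
})

test_that("branched structures fail unbranched_ok and the opposite-arm rule holds", {
  n <- 70L
  two_stems <- rbind(cbind(1:8, 30:23), cbind(40:47, 70:63))
  f <- structure(list(sequence = strrep("A", n), pairs = two_stems,
                      energy = -40, dotbracket = pairs_to_dotbracket(two_stems, n)),
                 class = "rna_fold")
  ev <- evaluate_precursor(f, 1L, 20L, run_config())
  expect_false(ev$flags[["unbranched_ok"]])
  expect_false(ev$verdict)
})

test_that("the window scan returns the planted hairpin and rejects homopolymers", {
  set.seed(74)
  hp <- plant_hairpin(22, 30, 8)   # 68-nt precursor
  window <- paste0(random_dna(120), hp$precursor, random_dna(120))
  res <- scan_precursors(window, 121L, 22L, cfg)
  expect_s3_class(res, "hairpin_candidate")
  expect_true(res$verdict)
  expect_lte(res$energy, cfg$mfe_cutoff)
  # recovered subwindow overlaps the planted precursor
  s <- regexpr(substr(hp$precursor, 1, 22), window, fixed = TRUE)[1]
  expect_equal(s, 121L)

  expect_null(scan_precursors(strrep("A", 300), 140L, 22L, cfg))
})

test_that("planted generator windows are recovered within +/-3 nt", {
  ok <- 0L; tot <- 0L
  for (s in 1:5) {
    ds <- generate_dataset(generator_config(n_reads = 500, rng_seed = 500 + s))
    novel <- dplyr::filter(ds$truth, kind == "novel_mirna")
    for (r in seq_len(nrow(novel))) {
      w <- extract_window(ds$genome, novel$chrom[r], novel$mature_start[r],
                          novel$mature_stop[r], novel$strand[r], config = cfg)
      res <- scan_precursors(w, config = cfg)
      tot <- tot + 1L
      if (!is.null(res) &&
          abs(res$start - novel$precursor_start[r]) <= 3 &&
          abs(res$stop - novel$precursor_stop[r]) <= 3) {
        ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("homology search separates full-length and seed matches", {
  known <- tibble::tibble(id = c("mirA", "mirB", "mirC"),
                          sequence = c("TAGGCTAGAGAGAGGTTAGGCT",
                                       "AAGGCTAGTTTTTTTTTTTTTT",
                                       "CCCCCCCCCCCCCCCCCCCCCC"))
  m <- "TAGGCTAGAGAGAGGTTAGGCT"
  res <- search_mirna_homology(m, known, cfg)
  expect_equal(res$full_length$id, "mirA")
  expect_equal(res$full_length$distance, 0L)
  # mirB shares nt 2-8 (AGGCTAG) only
  expect_setequal(res$seed$id, c("mirA", "mirB"))

  strict <- search_mirna_homology(m, known, run_config(homology_max_edit = 0L))
  expect_equal(strict$full_length$id, "mirA")

  none <- search_mirna_homology(random_dna(22),
                                tibble::tibble(id = character(),
                                               sequence = character()), cfg)
  expect_equal(nrow(none$full_length), 0L)
  expect_equal(nrow(none$seed), 0L)
  expect_error(search_mirna_homology("ACGTACG", known, cfg), "shorter")
})

test_that("lowering the MFE cutoff can only shrink the passing set", {
  set.seed(76)
  windows <- purrr::map(1:8, function(i) {
    if (i <= 4) {
      hp <- plant_hairpin(22, sample(28:30, 1), 8)
      paste0(random_dna(100), hp$precursor, random_dna(100))
    } else {
      paste0(random_dna(100), random_dna(70), random_dna(100))
    }
  })
  pass_at <- function(cutoff) {
    purrr::map_lgl(windows, function(w) {
      !is.null(scan_precursors(w, 101L, 22L, run_config(mfe_cutoff = cutoff)))
    })
  }
  loose <- pass_at(-30)
  tight <- pass_at(-45)
  tighter <- pass_at(-60)
  expect_true(all(tight <= loose))      # tight passing set is a subset
  expect_true(all(tighter <= tight))
  expect_true(any(loose))
})
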