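# minimal hit-table builder: one row per locus
mk_hits <- function(...) {
  loci <- list(...)
  purrr::imap_dfr(loci, function(l, i) {
    tibble::tibble(tag_id = l$tag_id, end_used = l$end %||% "end3",
                   chrom = l$chrom, start = l$start, stop = l$start + 21L,
                   strand = l$strand %||% "+",
                   end_uniqueness = "unique", end_n_loci = 1L,
                   redundant = FALSE, n_loci = l$n_loci %||% 1L,
                   uniqueness = if ((l$n_loci %||% 1L) == 1L) "unique" else "multi")
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_tracks <- function() {
  list(
    "repeat" = annotation_track(tibble::tibble(
      chrom = "chr1", start = 100L, stop = 300L, strand = "+",
      feature_id = "rep1"), "repeat"),
    ncrna = annotation_track(tibble::tibble(
      chrom = "chr1", start = 1000L, stop = 1100L, strand = "+",
      feature_id = "trna1"), "ncrna"),
    mirna = annotation_track(tibble::tibble(
      chrom = "chr1", start = 2000L, stop = 2080L, strand = "-",
      feature_id = "mir1"), "mirna"),
    refseq = annotation_track(tibble::tibble(
      chrom = "chr1", start = c(150L, 3000L), stop = c(400L, 3400L),
      strand = c("+", "+"), feature_id = c("nm1", "nm2")), "refseq"),
    est = annotation_track(tibble::tibble(
      chrom = "chr1", start = 4000L, stop = 4300L, strand = "+",
      feature_id = "est1"), "est"))
}

test_that("the first overlapping track in precedence order wins", {
  tracks <- mk_tracks()
  hits <- mk_hits(list(tag_id = "t1", chrom = "chr1", start = 190L),  # repeat & refseq
                  list(tag_id = "t2", chrom = "chr1", start = 2010L), # mirna only
                  list(tag_id = "t3", chrom = "chr1", start = 5000L), # nothing
                  list(tag_id = "t4", chrom = "chr1", start = 6000L, n_loci = 3L))
  rec <- annotate_tags(hits, tracks)
  expect_equal(as.character(rec$category[rec$tag_id == "t1"]), "repeat")
  expect_equal(rec$feature_id[rec$tag_id == "t1"], "rep1")
  expect_equal(as.character(rec$category[rec$tag_id == "t2"]), "mirna")
  expect_equal(as.character(rec$category[rec$tag_id == "t3"]), "unique_no_annotation")
  expect_equal(as.character(rec$category[rec$tag_id == "t4"]), "multi_no_annotation")
  # every matched tag gets exactly one category
  expect_equal(nrow(rec), 4L)
  expect_false(any(is.na(rec$category)))
})

test_that("a 1-nt overlap suffices and strand-awareness is switchable", {
  tracks <- mk_tracks()
  # query [2080, 2101] touches the mirna interval [2000, 2080] by 1 nt
  hits <- mk_hits(list(tag_id = "t1", chrom = "chr1", start = 2080L, strand = "+"))
  expect_equal(as.character(annotate_tags(hits, tracks)$category), "mirna")
  # with strand-aware mirna matching, the + hit misses the - feature
  rec2 <- annotate_tags(hits, tracks, strand_aware_tracks = "mirna")
  expect_equal(as.character(rec2$category), "unique_no_annotation")
  # just outside: no overlap
  hits3 <- mk_hits(list(tag_id = "t1", chrom = "chr1", start = 2081L, strand = "-"))
  expect_equal(as.character(annotate_tags(hits3, tracks)$category),
               "unique_no_annotation")
})

test_that("annotation is invariant to track interval order and errors on unknown chrom", {
  set.seed(41)
  tracks <- mk_tracks()
  hits <- do.call(mk_hits, purrr::map(1:40, function(i) {
    list(tag_id = paste0("t", i), chrom = "chr1",
         start = sample(50:4500, 1))
  }))
  rec1 <- annotate_tags(hits, tracks)
  shuffled <- purrr::map(tracks, function(tr) {
    annotation_track(tibble::as_tibble(unclass(tr))[sample(nrow(tr)), ],
                     attr(tr, "track_name"))
  })
  rec2 <- annotate_tags(hits, shuffled)
  expect_equal(dplyr::arrange(rec1, tag_id), dplyr::arrange(rec2, tag_id))

  g <- genome(c(chrX = "ACGT"))
  expect_error(annotate_tags(hits, tracks, g = g), "absent")
})

test_that("the annotation table recounts per-tag records with a total row", {
  set.seed(42)
  n <- 200
  all_cats <- c("repeat", "ncrna", "mirna", "refseq", "est",
                "unique_no_annotation", "multi_no_annotation")
  cats <- sample(all_cats, n, replace = TRUE)
  records <- tibble::tibble(tag_id = paste0("t", 1:n),
                            category = factor(cats, levels = all_cats),
                            feature_id = NA_character_)
  tags <- tibble::tibble(tag_id = paste0("t", 1:n),
                         count = sample(1:50, n, replace = TRUE))
  ends <- sample(c("end3", "end5", "both"), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  hits <- dplyr::bind_rows(
    tibble::tibble(tag_id = records$tag_id[ends != "end5"], end_used = "end3"),
    tibble::tibble(tag_id = records$tag_id[ends != "end3"], end_used = "end5"))
  tab <- annotation_table(records, hits, tags)
  # brute-force recount
  for (cat in all_cats) {
    ids <- records$tag_id[cats == cat]
    row <- tab[tab$category == cat, ]
    expect_equal(row$n_tags_combined, length(ids))
    expect_equal(row$n_reads, sum(tags$count[tags$tag_id %in% ids]))
    expect_equal(row$n_tags_end3,
                 length(intersect(ids, hits$tag_id[hits$end_used == "end3"])))
  }
  total <- tab[tab$category == "total", ]
  expect_equal(total$n_tags_combined, n)
  expect_equal(total$n_reads, sum(tags$count))
  # partition: category counts sum to the totals
  body <- tab[tab$category != "total", ]
  expect_equal(sum(body$n_tags_combined), total$n_tags_combined)
  expect_equal(sum(body$n_reads), total$n_reads)

  one <- annotation_table(records[1, ], hits[hits$tag_id == "t1", ], tags[1, ])
  expect_equal(one$n_reads[one$category == "total"],
               one$n_reads[one$category == as.character(records$category[1])])
})
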