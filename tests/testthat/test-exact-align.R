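cfg <- run_config()

test_that("the k-mer index stores both strands and excludes N", {
  g <- genome(c(chr1 = "ACGTACGT"))
  idx <- build_index(g, k = 4)
  acgt <- dplyr::filter(idx$lookup, kmer == "ACGT", strand == "+")
  expect_equal(sort(acgt$start), c(1L, 5L))
  # minus strand stores the reverse complement of the genome substring
  expect_true(all(c("ACGT") %in% idx$lookup$kmer[idx$lookup$strand == "-"]))
  expect_equal(nrow(dplyr::filter(idx$lookup, kmer == "GGGG")), 0L)

  gn <- genome(c(chr1 = "ACGTNACGT"))
  idxn <- build_index(gn, k = 4)
  expect_false(any(grepl("N", idxn$lookup$kmer)))
  # k longer than the chromosome gives an empty (not failing) index
  expect_equal(nrow(build_index(genome(c(c1 = "ACG")), k = 22)$lookup), 0L)
})

test_that("index contents equal a brute-force sliding-window enumeration", {
  set.seed(31)
  g <- genome(c(chr1 = random_dna(1200), chr2 = random_dna(800)))
  k <- 8
  idx <- build_index(g, k)
  manual <- dplyr::bind_rows(purrr::map(names(g), function(ch) {
    s <- g[[ch]]
    starts <- seq_len(nchar(s) - k + 1)
    kmers <- substring(s, starts, starts + k - 1)
    dplyr::bind_rows(
      tibble::tibble(kmer = kmers, chrom = ch, start = starts, strand = "+"),
      tibble::tibble(kmer = revcomp(kmers), chrom = ch, start = starts, strand = "-"))
  }))
  expect_equal(dplyr::arrange(idx$lookup, kmer, chrom, start, strand),
               dplyr::arrange(manual, kmer, chrom, start, strand))
})

test_that("planted queries align at their loci with correct uniqueness", {
  set.seed(32)
  back <- random_dna(3000)
  q1 <- random_dna(22)
  q2 <- random_dna(22)
  chr <- paste0(substr(back, 1, 500), q1, substr(back, 523, 1500),
                q2, substr(back, 1523, 2000), q2, substr(back, 2023, 2500))
  g <- genome(c(chr1 = chr))
  idx <- build_index(g, 22)
  tags <- tibble::tibble(
    tag_id = c("t1", "t2", "t3"),
    sequence = c(paste0(q1, substr(cfg$adaptor_3p, 1, 14)),
                 paste0(q2, substr(cfg$adaptor_3p, 1, 14)),
                 paste0(strrep("N", 22), substr(cfg$adaptor_3p, 1, 14))),
    count = c(5L, 2L, 1L))
  hits <- align_tags(tags, idx, cfg)
  h1 <- dplyr::filter(hits, tag_id == "t1")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$start, 501L)
  expect_equal(h1$strand, "+")
  expect_equal(h1$uniqueness, "unique")
  h2 <- dplyr::filter(hits, tag_id == "t2", end_used == "end3")
  expect_equal(unique(h2$end_uniqueness), "multi")
  expect_equal(unique(h2$end_n_loci), 2L)
  expect_false("t3" %in% hits$tag_id)  # N can never exact-match
})

test_that("hit sets equal the exhaustive-scan oracle on a 5 kb genome", {
  set.seed(33)
  g <- genome(c(chr1 = random_dna(3000), chr2 = random_dna(2000)))
  idx <- build_index(g, 22)
  # tags drawn from the genome (both strands) and at random
  mk_tag <- function() {
    if (stats::runif(1) < 0.6) {
      ch <- sample(names(g), 1)
      s <- sample(nchar(g[[ch]]) - 36, 1)
      seqv <- genome_slice(g, ch, s, s + 35, sample(c("+", "-"), 1))
    } else {
      seqv <- random_dna(36)
    }
    seqv
  }
  tags <- tibble::tibble(tag_id = paste0("t", 1:300),
                         sequence = replicate(300, mk_tag()),
                         count = 1L)
  hits <- align_tags(tags, idx, run_config(multi_locus_report_cap = 10000L))
  for (r in sample(nrow(tags), 60)) {
    for (end in c("end3", "end5")) {
      q <- if (end == "end3") substr(tags$sequence[r], 1, 22) else
        substr(tags$sequence[r], 15, 36)
      got <- hits |>
        dplyr::filter(tag_id == tags$tag_id[r], end_used == end) |>
        dplyr::select(chrom, start, strand) |>
        dplyr::arrange(chrom, start, strand)
      expect_equal(as.data.frame(got), as.data.frame(oracle_hits(g, q)),
                   ignore_attr = TRUE)
    }
  }
  # soundness: every hit reproduces its query from the genome
  for (r in seq_len(nrow(hits))) {
    q <- if (hits$end_used[r] == "end3") substr(tags$sequence[match(hits$tag_id[r], tags$tag_id)], 1, 22) else
      substr(tags$sequence[match(hits$tag_id[r], tags$tag_id)], 15, 36)
    expect_equal(genome_slice(g, hits$chrom[r], hits$start[r], hits$stop[r],
                              hits$strand[r]), q)
  }
})

test_that("dual-end hits on the same footprint combine non-redundantly", {
  set.seed(34)
  g <- genome(c(chr1 = random_dna(2000)))
  idx <- build_index(g, 22)
  # a fully genomic 36-mer: both end queries hit the same tag footprint
  tag <- genome_slice(g, "chr1", 301, 336, "+")
  tags <- tibble::tibble(tag_id = "t1", sequence = tag, count = 1L)
  hits <- align_tags(tags, idx, cfg)
  expect_equal(sort(unique(hits$end_used)), c("end3", "end5"))
  nonred <- dplyr::filter(hits, !redundant)
  expect_equal(nrow(nonred), 1L)
  expect_equal(nonred$end_used, "end3")   # end3 preferred
  expect_equal(unique(hits$n_loci), 1L)
  expect_equal(unique(hits$uniqueness), "unique")

  # minus-strand placement combines the same way
  tagm <- genome_slice(g, "chr1", 801, 836, "-")
  hm <- align_tags(tibble::tibble(tag_id = "m", sequence = tagm, count = 1L),
                   idx, cfg)
  expect_equal(nrow(dplyr::filter(hm, !redundant)), 1L)
  expect_equal(dplyr::filter(hm, !redundant)$end_used, "end3")
})

test_that("alignment accounting matches the union of matched ends", {
  set.seed(35)
  g <- genome(c(chr1 = random_dna(2000)))
  idx <- build_index(g, 22)
  e3 <- paste0(genome_slice(g, "chr1", 101, 122, "+"), random_dna(14))
  e5 <- paste0(random_dna(14), genome_slice(g, "chr1", 501, 522, "+"))
  both <- genome_slice(g, "chr1", 901, 936, "+")
  none <- random_dna(36)
  tags <- tibble::tibble(tag_id = c("a", "b", "c", "d"),
                         sequence = c(e3, e5, both, none),
                         count = c(10L, 20L, 30L, 40L))
  hits <- align_tags(tags, idx, cfg)
  acc <- alignment_accounting(hits, tags)
  expect_equal(acc$n_tags_matched, 3L)
  expect_equal(acc$n_reads_matched, 60L)
  expect_equal(acc$n_reads_unmatched, 40L)
  expect_equal(acc$pct_reads_matched, 60.0)

  empty_acc <- alignment_accounting(align_tags(
    tibble::tibble(tag_id = "x", sequence = random_dna(36), count = 7L),
    idx, cfg), tibble::tibble(tag_id = "x", sequence = "x", count = 7L))
  expect_equal(empty_acc$n_tags_matched, 0L)
  expect_equal(empty_acc$pct_reads_unmatched, 100.0)
})
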