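cfg <- run_config()

test_that("adaptor remnants at either end classify tags by construction", {
  insert <- random_dna(22)
  tag <- paste0(insert, substr(cfg$adaptor_3p, 1, 14))
  cls <- classify_adaptor(tag, cfg)
  expect_equal(as.character(cls$category), "legitimate")
  expect_equal(cls$insert_length, 22L)
  expect_equal(cls$insert, insert)
  expect_equal(cls$overlap_3p, 14L)
  expect_equal(cls$overlap_5p, 0L)

  dimer <- paste0(substr(cfg$adaptor_5p, 13, 26), substr(cfg$adaptor_3p, 1, 22))
  cls2 <- classify_adaptor(dimer, cfg)
  expect_equal(as.character(cls2$category), "adaptor_only")
  expect_equal(cls2$insert_length, 0L)
  expect_equal(cls2$insert, "")

  # a 5'-adaptor-only remnant is still a legitimate insert
  tag5 <- paste0(substr(cfg$adaptor_5p, 17, 26), random_dna(26))
  cls3 <- classify_adaptor(tag5, cfg)
  expect_equal(as.character(cls3$category), "legitimate")
  expect_equal(cls3$overlap_5p, 10L)
  expect_equal(cls3$insert_length, 26L)
})

test_that("tags sharing no adaptor run are no_adaptor (exhaustive scan check)", {
  set.seed(21)
  has_overlap <- function(tag) {
    any(vapply(cfg$min_adaptor_overlap:22, function(L) {
      substr(tag, 37 - L, 36) == substr(cfg$adaptor_3p, 1, L)
    }, logical(1))) ||
      any(vapply(cfg$min_adaptor_overlap:26, function(L) {
        substr(tag, 1, L) == substr(cfg$adaptor_5p, 27 - L, 26)
      }, logical(1)))
  }
  repeat {
    tag <- random_dna(36)
    if (!has_overlap(tag)) break
  }
  cls <- classify_adaptor(tag, cfg)
  expect_equal(as.character(cls$category), "no_adaptor")
  expect_equal(cls$overlap_5p + cls$overlap_3p, 0L)
})

test_that("size classes bin insert lengths disjointly", {
  expect_equal(as.character(classify_size(c(22, 15, 19, 16, 20, 25, 26, 29, 30, 0))),
               c("20_25", "lt16", "16_19", "16_19", "20_25", "20_25",
                 "26_29", "26_29", "ge30", "lt16"))
  expect_error(classify_size(-1), "negative")
})

test_that("classification is a partition and screen percentages use total reads", {
  set.seed(22)
  inserts <- replicate(30, random_dna(sample(16:30, 1)))
  tags <- collapse_reads(c(
    vapply(inserts, function(i) paste0(i, substr(cfg$adaptor_3p, 1, 36 - nchar(i))), ""),
    replicate(10, random_dna(36)),
    rep(paste0(substr(cfg$adaptor_5p, 13, 26), substr(cfg$adaptor_3p, 1, 22)), 4)))
  cls <- classify_adaptors(tags, cfg)
  expect_false(any(is.na(cls$category)))
  rep_ <- screen_report(cls)
  expect_equal(sum(rep_$categories$n_reads), sum(tags$count))
  expect_equal(sum(rep_$categories$n_tags), nrow(tags))
  # size classes over legitimate tags only, but percentages of total reads
  legit <- sum(cls$count[cls$category == "legitimate"])
  expect_equal(sum(rep_$size_classes$n_reads), legit)

  simple <- classify_adaptors(collapse_reads(c(
    rep(paste0(random_dna(22), substr(cfg$adaptor_3p, 1, 14)), 8),
    rep(random_dna(36), 2))), cfg)
  sr <- screen_report(simple)
  expect_equal(sr$categories$pct_reads[sr$categories$category == "legitimate"], 80.0)
  one <- classify_adaptors(collapse_reads(
    rep(paste0(random_dna(22), substr(cfg$adaptor_3p, 1, 14)), 5)), cfg)
  expect_equal(screen_report(one)$categories$pct_reads[3], 100.0)
})

test_that("extending an adaptor suffix never decreases the detected overlap", {
  # poly-A insert: the relevant 3'-adaptor region contains no A, so the
  # detected overlap is exactly the planted length and the planted-length
  # sweep isolates monotonicity from chance extensions
  Ls <- cfg$min_adaptor_overlap:20
  overlaps <- vapply(Ls, function(L) {
    tag <- paste0(strrep("A", 36 - L), substr(cfg$adaptor_3p, 1, L))
    classify_adaptor(tag, cfg)$overlap_3p
  }, integer(1))
  expect_equal(overlaps, Ls)
  expect_true(all(diff(overlaps) >= 0))

  # planted overlaps are always detected at least at their planted length
  set.seed(23)
  insert <- random_dna(30)
  detected <- vapply(Ls, function(L) {
    tag <- paste0(substr(insert, 1, 36 - L), substr(cfg$adaptor_3p, 1, L))
    classify_adaptor(tag, cfg)$overlap_3p
  }, integer(1))
  expect_true(all(detected >= Ls))
})
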