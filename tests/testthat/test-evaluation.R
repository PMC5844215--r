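test_that("gold TSV reads, validates and round-trips", {
  gold <- tibble::tibble(
    pmid = c("1", "1", "2"),
    rsid = c("rs1", "rs2", "rs3"),
    p_value = c(3.54e-18, 0.03, NA),
    or_value = c(NA, NA, 1.79),
    sentence_id = c(1L, 2L, NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gold(gold, path)
  back <- read_gold(path)
  expect_identical(back$pmid, gold$pmid)
  expect_identical(back$rsid, gold$rsid)
  expect_equal(back$p_value, gold$p_value, tolerance = 1e-6)
  expect_equal(back$or_value, gold$or_value, tolerance = 1e-6)

  # values in published dialects parse with the extractor's grammar
  dial <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "pmid\trsid\tp_value\tor_value\tsentence_id",
    "9\trs9\t3.54 × 10(−18)\t\t1"
  ), dial, useBytes = TRUE)
  expect_equal(read_gold(dial)$p_value, 3.54e-18)

  # a row with neither value violates the contract
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pmid\trsid\tp_value\tor_value\tsentence_id", "9\trs9\t\t\t1"), bad)
  expect_error(read_gold(bad), "without any value")
  # missing columns named in the error
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pmid\trsid", "9\trs9"), bad2)
  expect_error(read_gold(bad2), "p_value")
})

test_that("the XML gold dialect reads behind the same record type", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    "<annotations>",
    '<annotation pmid="7" rsid="rs7" p_value="4.4e-7" sentence_id="2"/>',
    '<annotation pmid="7" rsid="rs8" or_value="1.40"/>',
    "</annotations>"
  ), path)
  g <- read_gold(path, dialect = "snpphena_xml")
  expect_equal(nrow(g), 2)
  expect_equal(g$p_value[1], 4.4e-7)
  expect_equal(g$or_value[2], 1.40)
})

test_that("scoring counts greedily matched pairs and derives P/R/F1", {
  gold <- tibble::tibble(
    pmid = c("1", "1"), rsid = c("rs1", "rs2"),
    p_value = c(0.01, 0.02), or_value = NA_real_, sentence_id = NA_integer_
  )
  # exact match
  perfect <- tibble::tibble(pmid = gold$pmid, rsid = gold$rsid,
                            p_value = gold$p_value, or_value = NA_real_)
  m <- score_associations(perfect, gold)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  # one correct + one spurious prediction over two gold
  half <- tibble::tibble(pmid = c("1", "1"), rsid = c("rs1", "rs9"),
                         p_value = c(0.01, 0.5), or_value = NA_real_)
  m2 <- score_associations(half, gold)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 1L))
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(0.5, 0.5, 0.5))

  # wrong value is not a match even with the right rsid
  wrongv <- tibble::tibble(pmid = "1", rsid = "rs1", p_value = 0.02,
                           or_value = NA_real_)
  m3 <- score_associations(wrongv, gold)
  expect_equal(m3$tp, 0L)

  # empty inputs hit the 0-denominator rules
  m4 <- score_associations(perfect[0, ], gold[0, ])
  expect_equal(c(m4$precision, m4$recall, m4$f1), c(0, 0, 0))

  # permutation invariance of the counts
  set.seed(5)
  m5 <- score_associations(perfect[sample(2), ], gold[sample(2), ])
  expect_equal(c(m5$tp, m5$fp, m5$fn), c(2L, 0L, 0L))
})

test_that("metrics expose tidy and glance views with bounded F1", {
  gold <- tibble::tibble(pmid = "1", rsid = "rs1", p_value = 0.01,
                         or_value = NA_real_, sentence_id = 1L)
  m <- score_associations(
    tibble::tibble(pmid = c("1", "1"), rsid = c("rs1", "rs2"),
                   p_value = c(0.01, 0.3), or_value = NA_real_),
    gold
  )
  td <- tidy(m)
  expect_identical(td$metric,
                   c("tp", "fp", "fn", "precision", "recall", "f1"))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_true(gl$f1 <= max(gl$precision, gl$recall))
  expect_true(gl$f1 >= min(gl$precision, gl$recall))
})

test_that("the generator is deterministic and its corpus files round-trip", {
  c1 <- generate_synthetic_abstracts(10, seed = 1)
  c2 <- generate_synthetic_abstracts(10, seed = 1)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_corpus(c1, d1)
  write_synthetic_corpus(c2, d2)
  expect_identical(readBin(file.path(d1, "abstracts.txt"), "raw", 1e6),
                   readBin(file.path(d2, "abstracts.txt"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "gold.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "gold.tsv"), "raw", 1e6))

  # reading back reproduces the in-memory corpus
  back <- read_abstract_txt(file.path(d1, "abstracts.txt"))
  expect_identical(back$pmid, c1$abstracts$pmid)
  expect_identical(back$abstract, c1$abstracts$text)
  gold_back <- read_gold(file.path(d1, "gold.tsv"))
  expect_identical(gold_back$rsid, c1$gold$rsid)
  expect_equal(gold_back$p_value, c1$gold$p_value, tolerance = 1e-6)

  expect_error(generate_synthetic_abstracts(0, seed = 1), "n")
  expect_error(generate_synthetic_abstracts(2, seed = 1,
                                            params = list(bogus = 1)),
               "Unknown generator params")

  # generator restores the caller's RNG state
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_synthetic_abstracts(2, seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("noise-free synthetic abstracts are recovered perfectly", {
  corpus <- generate_synthetic_abstracts(25, seed = 2024)
  m <- evaluate_corpus(as_records(corpus), corpus$gold)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  # cohort truths are recovered on the same corpus
  mined <- mine_abstracts(as_records(corpus))
  per_abs <- dplyr::distinct(mined, pmid, patient_size, control_size, ethnicity)
  joined <- dplyr::inner_join(per_abs, corpus$cohort, by = "pmid",
                              suffix = c(".got", ".want"))
  expect_equal(joined$patient_size.got, joined$patient_size.want)
  expect_equal(joined$control_size.got, joined$control_size.want)
  expect_identical(joined$ethnicity.got, joined$ethnicity.want)
})

test_that("unmarked second values depress recall by exactly the planted count", {
  corpus <- generate_synthetic_abstracts(40, seed = 6,
                                         params = list(p_unmarked_second = 1))
  # count planted unmarked-second sentences from the corpus text
  n_unmarked <- sum(stringr::str_count(
    corpus$abstracts$text,
    "Two SNPs rs[0-9]+ and rs[0-9]+ in [A-Z0-9]+ were associated"
  ))
  m <- evaluate_corpus(as_records(corpus), corpus$gold)
  expect_equal(m$fn, n_unmarked)
  if (n_unmarked > 0) expect_lt(m$recall, 1)
})
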