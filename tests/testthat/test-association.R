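test_that("exponent dialects normalise to canonical e-notation", {
  cases <- list(
    c("P = 3.54 × 10(−18)", "P = 3.54e-18"),
    c("P = 2.67 ×10^−9^,", "P = 2.67e-9,"),
    c("combined P = 4.4 × 10(−7)", "P = 4.4e-7"),
    c("(P ≤ 5.0 × 10(−8))", "P ≤ 5.0e-8"),
    c("p-value = 0.045", "P = 0.045"),
    c("P < 10(−5)", "P < 1e-5"),
    c("at 2.1 x 10(-4) and 7.3 X 10(-2)", "at 2.1e-4 and 7.3e-2")
  )
  for (cs in cases) {
    expect_identical(normalize_sentence(cs[1])$text, cs[2])
  }
  # a sentence with no digits only loses quotes/brackets
  expect_identical(
    normalize_sentence('We "quote" (bracket) text')$text,
    "We quote bracket text"
  )
})

test_that("the offset map points canonical values back to parseable source spans", {
  sent <- "rs7086803 showed combined P = 3.54 × 10(−18) in meta-analysis"
  norm <- normalize_sentence(sent)
  vals <- parse_stat_values(norm)
  expect_equal(vals$value, 3.54e-18)
  # slicing the original at the mapped span must reparse to the same float
  slice <- substr(sent, vals$start, vals$end)
  reparsed <- parse_stat_values(normalize_sentence(slice))
  expect_equal(reparsed$value, vals$value)
  # the span must cover the whole source construct including the dialected number
  expect_match(slice, "10(−18)", fixed = TRUE)
})

test_that("stat-value grammar binds only marker-adjacent numbers", {
  vals <- parse_stat_values(normalize_sentence(
    "associated with COPD P = 0.045 and 0.032"
  ))
  expect_equal(nrow(vals), 1)
  expect_equal(vals$value, 0.045)

  # kinds and comparators
  v2 <- parse_stat_values(normalize_sentence("OR = 2.47, P = 4.74 × 10(−20)"))
  expect_setequal(v2$kind, c("OR", "P"))
  expect_equal(v2$value[v2$kind == "OR"], 2.47)
  expect_equal(v2$value[v2$kind == "P"], 4.74e-20)

  # "odds ratio" spelled out
  v3 <- parse_stat_values(normalize_sentence("an odds ratio = 1.35 was seen"))
  expect_identical(v3$kind, "OR")
  expect_equal(v3$value, 1.35)

  # bare marker without a number never parses
  expect_equal(nrow(parse_stat_values(normalize_sentence("We measured P waves in ECG."))), 0)
  # integers are not statistic candidates
  expect_equal(nrow(parse_stat_values(normalize_sentence("P = 1 was meaningless"))), 0)
})

test_that("threshold flagging depends on coexisting equality values", {
  # threshold with '=' values present: excluded from pairing
  both <- parse_stat_values(normalize_sentence(
    "(P ≤ 5.0 × 10(−8)) while rs1 had P = 7.2 × 10(−26)"
  ))
  expect_identical(both$is_threshold, c(TRUE, FALSE))
  # '<' standing alone stays pairable
  alone <- parse_stat_values(normalize_sentence("rs1 showed P < 0.05"))
  expect_false(alone$is_threshold)
})

test_that("canonical rendering of a stat value re-parses exactly", {
  set.seed(3)
  for (i in 1:30) {
    value <- 10^stats::runif(1, -30, -1) * stats::runif(1, 1, 9.99)
    comparator <- sample(c("=", "<", "≤"), 1)
    rendered <- render_stat_value("P", comparator, value)
    vals <- parse_stat_values(normalize_sentence(rendered))
    expect_identical(vals$comparator, comparator)
    expect_identical(vals$value, value)
  }
})

test_that("result sentences require a P marker bound to a number", {
  p <- nlp_analyze(paste(
    "We measured P waves in ECG.",
    "Strong association emerged (P = 0.002).",
    "No statistics appeared here."
  ))
  flagged <- find_result_sentences(p)
  expect_equal(nrow(flagged), 1)
  expect_match(flagged$text, "0.002", fixed = TRUE)
  empty <- find_result_sentences(nlp_analyze(""))
  expect_equal(nrow(empty), 0)
})

test_that("six-SNP sentence pairs nearest-unconsumed with threshold excluded", {
  a <- extract_associations(example_sentence(4), pmid = "21725308")
  expected <- c(
    rs4488809 = 7.2e-26, rs465498 = 1.2e-20, rs2736100 = 1.0e-27,
    rs753955 = 1.5e-12, rs17728461 = 1.1e-11, rs36600 = 6.2e-13
  )
  expect_identical(a$rsid, names(expected))
  expect_equal(stats::setNames(a$p_value, a$rsid), expected)
  # injectivity outside broadcast: six distinct values consumed once each
  expect_false(any(duplicated(a$p_value)))
  expect_false(any(a$p_broadcast))
})

test_that("P and OR pools are consumed independently in the same sentence", {
  a <- extract_associations(example_sentence(3), pmid = "24880342")
  expect_identical(a$rsid, c("rs11571833", "rs17879961"))
  expect_equal(a$p_value, c(4.74e-20, 1.27e-13))
  expect_equal(a$or_value, c(2.47, 0.38))
})

test_that("duplicate mentions dedupe to group-minimum distance pairing", {
  a <- extract_associations(example_sentence(10), pmid = "18820697")
  expect_equal(nrow(a), 1)
  expect_identical(a$rsid, "rs5770917")
  expect_equal(a$p_value, 4.4e-7)
  expect_equal(a$or_value, 1.79)
})

test_that("a single value broadcasts to every SNP in the sentence", {
  a <- extract_associations(example_sentence(11), pmid = "17383819")
  expect_identical(a$rsid, c("rs2254298", "rs53576"))
  expect_equal(a$p_value, c(0.03, 0.03))
  expect_true(all(a$p_broadcast))

  # the unmarked second number leaves one value that broadcasts
  a2 <- extract_associations(example_sentence(9), pmid = "22914670")
  expect_identical(a2$rsid, c("rs2656069", "rs10851906"))
  expect_equal(a2$p_value, c(0.045, 0.045))
})

test_that("caret-dialect single-SNP sentence extracts its P-value", {
  a <- extract_associations(example_sentence(1), pmid = "21552555")
  expect_identical(a$rsid, "rs11624704")
  expect_equal(a$p_value, 2.67e-9)
})

test_that("pairing matches the brute-force consumption oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_pairing_instance()
    got <- pair_snps_to_values(inst$groups, inst$values)
    want <- oracle_pairing(inst$groups, inst$values)
    expect_identical(got$rsid, want$rsid)
    expect_identical(got$value, want$value)
  }
})

test_that("pairing is invariant to the input order of the values list", {
  set.seed(55)
  for (i in 1:25) {
    inst <- random_pairing_instance()
    shuffled <- inst$values[sample(nrow(inst$values)), , drop = FALSE]
    expect_identical(
      pair_snps_to_values(inst$groups, inst$values),
      pair_snps_to_values(inst$groups, shuffled)
    )
  }
})

test_that("extraction is deterministic and evidence is the original sentence", {
  sent <- example_sentence(2)
  a1 <- extract_associations(sent, pmid = "23143601")
  a2 <- extract_associations(sent, pmid = "23143601")
  expect_identical(a1, a2)
  expect_identical(unique(a1$evidence_sentence), sent)
  # no flagged sentences -> empty
  expect_equal(nrow(extract_associations("Nothing to see here at all.")), 0)
})
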