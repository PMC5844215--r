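test_that("build_query substitutes the disease into the fixed MeSH template", {
  expect_identical(
    build_query("obesity"),
    paste0(
      'obesity AND("Polymorphism, Single Nucleotide"[Mesh Terms]',
      ' OR "Genetic Predisposition to Disease"[Mesh Terms]',
      ' OR "Genome-Wide Association Study"[Mesh Terms])'
    )
  )
  # multi-word disease, template otherwise unchanged
  expect_identical(
    build_query("lung cancer"),
    sub("^obesity", "lung cancer", build_query("obesity"))
  )
  # byte-stable and exactly three MeSH clauses for any input
  for (d in c("obesity", "type 2 diabetes", "asthma")) {
    q <- build_query(d)
    expect_identical(q, build_query(d))
    expect_equal(stringr::str_count(q, stringr::fixed("[Mesh Terms]")), 3)
  }
  expect_error(build_query(""), "non-empty")
  expect_error(build_query("   "), "non-empty")
})

test_that("fetch_pmids replays a stubbed esearch response and honours retmax", {
  stub <- function(url) {
    paste0(
      "<eSearchResult><IdList>",
      "<Id>101</Id><Id>102</Id><Id>103</Id>",
      "</IdList></eSearchResult>"
    )
  }
  expect_identical(
    suppressMessages(fetch_pmids("q", retmax = 10, transport = stub)),
    c("101", "102", "103")
  )
  expect_identical(
    suppressMessages(fetch_pmids("q", retmax = 1, transport = stub)),
    "101"
  )
  failing <- function(url) stop("HTTP 503 Service Unavailable")
  expect_error(
    fetch_pmids("q", transport = failing),
    class = "snpminer_fetch_error"
  )
  expect_error(fetch_pmids("q", retmax = 0), "positive")
})

test_that("read_pubmed_xml parses records field by field", {
  recs <- suppressWarnings(read_pubmed_xml(pubmed_xml_two_articles()))
  expect_equal(nrow(recs), 2)
  expect_identical(recs$pmid, c("11111111", "22222222"))
  expect_identical(recs$abstract[1], "We found rs123 with P = 0.01.")
  expect_identical(recs$abstract[2], "")
  expect_identical(recs$language, c("eng", "fre"))
  expect_identical(recs$pub_date[1], "2015-06-02")

  # labelled sections concatenate with single spaces in document order
  sec <- read_pubmed_xml(pubmed_xml_sectioned())
  expect_identical(sec$abstract, "Part one. Part two. Part three.")

  expect_equal(nrow(read_pubmed_xml("<PubmedArticleSet/>")), 0)
  expect_error(read_pubmed_xml("<unclosed"), "Malformed")
  no_pmid <- paste0(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>X</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"
  )
  expect_warning(out <- read_pubmed_xml(no_pmid), "without a PMID")
  expect_equal(nrow(out), 0)
})

test_that("plain-text dialect round-trips PMIDs and abstracts byte-for-byte", {
  recs <- tibble::tibble(
    pmid = c("123", "456"),
    abstract = c("One abstract with rs1 and P = 0.01 inside.",
                 "Another, shorter text.")
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_abstract_txt(recs, path)
  back <- read_abstract_txt(path)
  expect_identical(back$pmid, recs$pmid)
  expect_identical(back$abstract, recs$abstract)

  expect_error(read_abstract_txt(c("NOTPMID\t12", "text")), "Malformed")
  dup <- c("PMID\t9", "abc", "", "PMID\t9", "def")
  expect_warning(kept <- read_abstract_txt(dup), "Duplicate")
  expect_identical(kept$abstract, "abc")
})

test_that("filter_records assigns reasons by the fixed rule order", {
  long_pad <- paste(rep("Genome-wide association analysis of this cohort.", 3),
                    collapse = " ")
  recs <- tibble::tibble(
    pmid = as.character(1:5),
    title = "",
    abstract = c(
      "",                                        # missing
      "short",                                   # incomplete (< 50 chars)
      paste(long_pad, "No identifiers here."),   # no SNP mention
      paste(long_pad, "We found rs7086803 significant."),  # kept
      paste(long_pad, "We found rs7086803 significant.")   # non-English
    ),
    pub_date = NA_character_,
    language = c(NA, NA, "eng", "eng", "fre")
  )
  out <- filter_records(recs)
  expect_identical(
    out$reason,
    c("missing_abstract", "missing_abstract", "no_snp_mention", "kept",
      "non_english")
  )
  expect_identical(out$kept, out$reason == "kept")
  # never mutates, preserves order and row count
  expect_identical(out$pmid, recs$pmid)
  expect_identical(out$abstract, recs$abstract)
  expect_equal(nrow(out), nrow(recs))
  # missing language tag keeps the record
  expect_true(out$kept[4])
})
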