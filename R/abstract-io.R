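# Abstract acquisition and filtering: PubMed query construction,
# E-utilities retrieval (pluggable transport), offline readers for
# PubMed/MEDLINE XML and a plain-text dialect, and the usable-record
# filter.

eutils_base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

#' Build the PubMed disease query
#'
#' Combines the disease term with the three MeSH clauses used to restrict
#' retrieval to SNP-association literature: "Polymorphism, Single
#' Nucleotide", "Genetic Predisposition to Disease" and "Genome-Wide
#' Association Study", OR-ed together and AND-ed with the disease term.
#' Output is byte-stable for a given input.
#'
#' @param disease disease name (non-empty after trimming).
#' @return the query string.
#' @export
#' @examples
#' build_query("obesity")
build_query <- function(disease) {
  if (length(disease) != 1 || is.na(disease)) {
    abort("`disease` must be a single non-missing string.")
  }
  disease <- trimws(disease)
  if (!nzchar(disease)) {
    abort("`disease` must be non-empty after whitespace trimming.")
  }
  paste0(
    disease,
    ' AND("Polymorphism, Single Nucleotide"[Mesh Terms]',
    ' OR "Genetic Predisposition to Disease"[Mesh Terms]',
    ' OR "Genome-Wide Association Study"[Mesh Terms])'
  )
}

#' Fetch matching PMIDs through E-utilities esearch
#'
#' Issues an esearch request and returns at most `retmax` PubMed ids in
#' service order. The transport is pluggable: `transport` is a function
#' `url -> response text`, so recorded responses can be replayed offline;
#' the default transport performs a live HTTP request.
#'
#' @param query a query string, e.g. from [build_query()].
#' @param retmax maximum number of ids to request (default 3000).
#' @param transport function mapping a URL to response text.
#' @param tool,email identification parameters passed to the service.
#' @return character vector of PMIDs.
#' @export
fetch_pmids <- function(query, retmax = 3000, transport = default_transport,
                        tool = "snpminer", email = NULL) {
  if (!is.numeric(retmax) || retmax < 1) abort("`retmax` must be a positive integer.")
  url <- paste0(
    eutils_base, "/esearch.fcgi?db=pubmed&retmax=", as.integer(retmax),
    "&term=", utils::URLencode(query, reserved = TRUE),
    "&tool=", utils::URLencode(tool, reserved = TRUE),
    if (!is.null(email)) paste0("&email=", utils::URLencode(email, reserved = TRUE)) else ""
  )
  resp <- tryCatch(
    transport(url),
    error = function(e) {
      abort(
        paste0("E-utilities esearch request failed: ", conditionMessage(e)),
        class = "snpminer_fetch_error"
      )
    }
  )
  doc <- xml2::read_xml(paste(resp, collapse = "\n"))
  ids <- xml2::xml_text(xml2::xml_find_all(doc, ".//IdList/Id"))
  rlang::inform(paste0("esearch returned ", length(ids), " PMIDs (retmax=",
                       as.integer(retmax), ")."))
  utils::head(ids, as.integer(retmax))
}

default_transport <- function(url) {
  con <- url(url, open = "rb")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

#' Fetch abstract records through E-utilities efetch
#'
#' Retrieves PubMed XML for the given ids and parses it with
#' [read_pubmed_xml()]. Transport is pluggable as in [fetch_pmids()].
#'
#' @param pmids character vector of PubMed ids.
#' @param transport function mapping a URL to response text.
#' @return an abstract-record tibble (see [read_pubmed_xml()]).
#' @export
fetch_abstracts <- function(pmids, transport = default_transport) {
  if (!length(pmids)) return(empty_records())
  url <- paste0(
    eutils_base, "/efetch.fcgi?db=pubmed&retmode=xml&id=",
    paste(pmids, collapse = ",")
  )
  resp <- tryCatch(
    transport(url),
    error = function(e) {
      abort(
        paste0("E-utilities efetch request failed: ", conditionMessage(e)),
        class = "snpminer_fetch_error"
      )
    }
  )
  read_pubmed_xml(paste(resp, collapse = "\n"))
}

empty_records <- function() {
  tibble(
    pmid = character(), title = character(), abstract = character(),
    pub_date = character(), language = character()
  )
}

#' Read PubMed/MEDLINE XML into abstract records
#'
#' Parses a `PubmedArticleSet` document. Multi-paragraph abstracts
#' (several `AbstractText` sections) are concatenated with single spaces
#' in document order; the language tag is taken from the citation when
#' present; the publication date is rendered ISO-style from the journal
#' issue `PubDate` (year, or year-month-day when available). Articles
#' without a PMID are skipped with a warning; duplicate PMIDs keep the
#' first record.
#'
#' @param x a file path, URL, or XML text.
#' @return a tibble: `pmid`, `title`, `abstract`, `pub_date`, `language`.
#' @export
read_pubmed_xml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) abort(paste0("Malformed PubMed XML: ", conditionMessage(e)))
  )
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- list()
  for (a in articles) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warn("Skipping article without a PMID.")
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- if (length(abs_nodes)) {
      paste(xml2::xml_text(abs_nodes), collapse = " ")
    } else {
      ""
    }
    language <- xml2::xml_text(xml2::xml_find_first(a, ".//Language"))
    rows[[length(rows) + 1L]] <- tibble(
      pmid = pmid,
      title = ifelse(is.na(title), "", title),
      abstract = abstract,
      pub_date = pubmed_date(a),
      language = ifelse(is.na(language), NA_character_, language)
    )
  }
  if (!length(rows)) return(empty_records())
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out$pmid)
  if (any(dup)) {
    warn(paste0("Duplicate PMIDs dropped (first kept): ",
                paste(unique(out$pmid[dup]), collapse = ", ")))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

pubmed_date <- function(article) {
  nd <- xml2::xml_find_first(article, ".//Journal/JournalIssue/PubDate")
  if (is.na(nd)) nd <- xml2::xml_find_first(article, ".//ArticleDate")
  if (is.na(nd)) return(NA_character_)
  year <- xml2::xml_text(xml2::xml_find_first(nd, "./Year"))
  if (is.na(year)) return(NA_character_)
  month <- xml2::xml_text(xml2::xml_find_first(nd, "./Month"))
  day <- xml2::xml_text(xml2::xml_find_first(nd, "./Day"))
  mnum <- suppressWarnings(as.integer(month))
  if (is.na(mnum) && !is.na(month)) {
    mnum <- match(substr(tolower(month), 1, 3), tolower(month.abb))
  }
  if (is.na(mnum)) return(year)
  dnum <- suppressWarnings(as.integer(day))
  if (is.na(dnum)) return(sprintf("%s-%02d", year, mnum))
  sprintf("%s-%02d-%02d", year, mnum, dnum)
}

#' Read abstracts in the plain-text dialect
#'
#' Records are separated by blank lines; the first line of each record is
#' `PMID<TAB>pmid`, the remaining lines are the abstract (joined with
#' single spaces). Duplicate PMIDs keep the first record.
#'
#' @param x a file path or a character vector of lines.
#' @return a tibble: `pmid`, `title` (empty), `abstract`, `pub_date`,
#'   `language` (both `NA`).
#' @export
read_abstract_txt <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) {
    readLines(x, warn = FALSE, encoding = "UTF-8")
  } else {
    x
  }
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  rows <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    hdr <- stringr::str_split_fixed(b[1], "\t", 2)
    if (hdr[1, 1] != "PMID" || !grepl("^[0-9]+$", hdr[1, 2])) {
      abort(paste0("Malformed plain-text record header: ", b[1]))
    }
    rows[[length(rows) + 1L]] <- tibble(
      pmid = hdr[1, 2], title = "",
      abstract = paste(b[-1], collapse = " "),
      pub_date = NA_character_, language = NA_character_
    )
  }
  if (!length(rows)) return(empty_records())
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out$pmid)
  if (any(dup)) {
    warn(paste0("Duplicate PMIDs dropped (first kept): ",
                paste(unique(out$pmid[dup]), collapse = ", ")))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Write abstracts in the plain-text dialect
#'
#' Inverse of [read_abstract_txt()] for single-paragraph abstracts.
#'
#' @param records an abstract-record tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abstract_txt <- function(records, path) {
  blocks <- purrr::map2_chr(
    records$pmid, records$abstract,
    ~ paste0("PMID\t", .x, "\n", .y)
  )
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Filter abstract records to usable, SNP-relevant ones
#'
#' Applies the exclusion rules in fixed order and reports the first
#' failing rule for each record: `missing_abstract` (empty or shorter
#' than `min_abstract_chars`, i.e. a title-only stub), `non_english`
#' (metadata language tag present and not English; records without a tag
#' are kept), then `no_snp_mention` (no rsID in title or abstract).
#' Input order is preserved and records are never mutated.
#'
#' @param records an abstract-record tibble.
#' @param snp_detector predicate over text, by default [has_snp_mention()].
#' @param min_abstract_chars minimum abstract length.
#' @return `records` with `kept` (logical) and `reason` (one of `kept`,
#'   `missing_abstract`, `non_english`, `no_snp_mention`) appended.
#' @export
filter_records <- function(records, snp_detector = has_snp_mention,
                           min_abstract_chars = snp_config()$min_abstract_chars) {
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    abs_txt <- records$abstract[i]
    lang <- records$language[i]
    reason[i] <- if (is.na(abs_txt) || nchar(abs_txt) < min_abstract_chars) {
      "missing_abstract"
    } else if (!is.na(lang) && nzchar(lang) &&
               !startsWith(tolower(lang), "en")) {
      "non_english"
    } else if (!snp_detector(paste(records$title[i], abs_txt))) {
      "no_snp_mention"
    } else {
      "kept"
    }
  }
  out <- records
  out$kept <- reason == "kept"
  out$reason <- reason
  out
}
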