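# Shared fixtures and independent oracles, all built in code.

worked_examples <- function() example_sentences()

example_sentence <- function(id) {
  ex <- worked_examples()
  ex$sentence[ex$row_id == id]
}

as_records <- function(corpus) {
  tibble::tibble(
    pmid = corpus$abstracts$pmid, title = "",
    abstract = corpus$abstracts$text,
    pub_date = NA_character_, language = NA_character_
  )
}

# two-article PubMed XML fixture: one complete, one without AbstractText
pubmed_xml_two_articles <- function() {
  paste0(
    '<?xml version="1.0"?>\n<PubmedArticleSet>\n',
    "<PubmedArticle><MedlineCitation><PMID>11111111</PMID>",
    "<Article><Journal><JournalIssue><PubDate><Year>2015</Year><Month>Jun</Month><Day>2</Day></PubDate></JournalIssue></Journal>",
    "<ArticleTitle>First title</ArticleTitle>",
    "<Abstract><AbstractText>We found rs123 with P = 0.01.</AbstractText></Abstract>",
    "<Language>eng</Language></Article></MedlineCitation></PubmedArticle>\n",
    "<PubmedArticle><MedlineCitation><PMID>22222222</PMID>",
    "<Article><ArticleTitle>Second title</ArticleTitle>",
    "<Language>fre</Language></Article></MedlineCitation></PubmedArticle>\n",
    "</PubmedArticleSet>"
  )
}

# three labelled abstract sections to check concatenation order
pubmed_xml_sectioned <- function() {
  paste0(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation><PMID>33333333</PMID>",
    "<Article><ArticleTitle>T</ArticleTitle><Abstract>",
    '<AbstractText Label="BACKGROUND">Part one.</AbstractText>',
    '<AbstractText Label="METHODS">Part two.</AbstractText>',
    '<AbstractText Label="RESULTS">Part three.</AbstractText>',
    "</Abstract><Language>eng</Language></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"
  )
}

# brute-force pairing oracle: simulates the sequential consumption
# literally with explicit loops, independent of the implementation
oracle_pairing <- function(groups, values) {
  values <- values[!values$is_threshold, , drop = FALSE]
  if (nrow(groups) == 0 || nrow(values) == 0) {
    return(data.frame(rsid = character(), value = double()))
  }
  if (nrow(values) == 1) {
    return(data.frame(rsid = groups$rsid, value = rep(values$value, nrow(groups))))
  }
  pool <- values[order(values$start), , drop = FALSE]
  alive <- rep(TRUE, nrow(pool))
  out_rsid <- character(0)
  out_value <- double(0)
  for (g in seq_len(nrow(groups))) {
    spans <- groups$spans[[g]]
    best_vi <- NA_integer_
    best_d <- Inf
    best_follows <- FALSE
    for (vi in seq_len(nrow(pool))) {
      if (!alive[vi]) next
      d <- Inf
      for (si in seq_len(nrow(spans))) {
        gap <- if (pool$start[vi] > spans$end[si]) {
          pool$start[vi] - spans$end[si] - 1
        } else if (pool$end[vi] < spans$start[si]) {
          spans$start[si] - pool$end[vi] - 1
        } else {
          0
        }
        if (gap < d) d <- gap
      }
      follows <- pool$start[vi] > max(spans$end)
      better <- d < best_d || (d == best_d && follows && !best_follows)
      if (better) {
        best_vi <- vi
        best_d <- d
        best_follows <- follows
      }
    }
    if (is.na(best_vi)) break
    alive[best_vi] <- FALSE
    out_rsid <- c(out_rsid, groups$rsid[g])
    out_value <- c(out_value, pool$value[best_vi])
  }
  data.frame(rsid = out_rsid, value = out_value)
}

# random pairing instance: up to max_snps groups (1-2 spans each) and up
# to max_vals values scattered over a virtual sentence
random_pairing_instance <- function(max_snps = 5, max_vals = 5) {
  n_g <- sample(1:max_snps, 1)
  n_v <- sample(1:max_vals, 1)
  slots <- sort(sample(seq(1, 500, by = 12), n_g * 2 + n_v))
  slots <- sample(slots)
  groups <- tibble::tibble(
    rsid = paste0("rs", seq_len(n_g)),
    first_start = NA_integer_, n_mentions = NA_integer_, spans = vector("list", n_g)
  )
  si <- 1
  for (g in seq_len(n_g)) {
    k <- sample(1:2, 1)
    starts <- sort(slots[si:(si + k - 1)])
    si <- si + k
    groups$spans[[g]] <- tibble::tibble(start = starts, end = starts + 8L)
    groups$first_start[g] <- starts[1]
    groups$n_mentions[g] <- k
  }
  groups <- groups[order(groups$first_start), , drop = FALSE]
  v_starts <- slots[si:(si + n_v - 1)]
  values <- tibble::tibble(
    kind = "P", comparator = "=",
    value = round(stats::runif(n_v, 1e-10, 0.05), 12),
    surface = "x", start = as.integer(v_starts), end = as.integer(v_starts + 7L),
    norm_num_start = NA_integer_, norm_num_end = NA_integer_,
    is_threshold = FALSE
  )
  list(groups = groups, values = values)
}

# comparison-sort oracle for sort_records: selection sort with explicit
# missing-last placement
oracle_sort <- function(records, key, ascending) {
  v <- records[[key]]
  if (key %in% c("rsid", "pmid")) {
    v <- suppressWarnings(as.numeric(gsub("[^0-9]", "", v)))
  }
  present <- which(!is.na(v))
  missing <- which(is.na(v))
  ord <- present[order(xtfrm(v[present]) * (if (ascending) 1 else -1),
                       present)]
  records[c(ord, missing), , drop = FALSE]
}
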