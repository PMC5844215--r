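# End-to-end pipeline: records in, association report out.

#' Mine association records from abstract records
#'
#' Runs the full pipeline over a tibble of abstract records: usability
#' filtering, linguistic analysis, SNP-statistic association extraction,
#' cohort extraction, and report assembly. Abstract-level cohort fields
#' are copied onto every association row from that abstract.
#'
#' @param records an abstract-record tibble (from [read_pubmed_xml()],
#'   [read_abstract_txt()] or [fetch_abstracts()]).
#' @param config pipeline configuration, see [snp_config()].
#' @param filter apply [filter_records()] first (default `TRUE`).
#' @return a `snp_associations` tibble, one row per (sentence, rsid)
#'   pair across all kept abstracts.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   pmid = "1", title = "",
#'   abstract = paste(
#'     "We studied a cohort of 889 cases and 1005 controls.",
#'     "Association was detected at rs2254298 (P = 0.03) but not rs53576."
#'   ),
#'   pub_date = NA_character_, language = NA_character_
#' )
#' mine_abstracts(recs)
mine_abstracts <- function(records, config = snp_config(), filter = TRUE) {
  if (filter) {
    flt <- filter_records(records,
                          min_abstract_chars = config$min_abstract_chars)
    records <- records[flt$kept, , drop = FALSE]
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    parsed <- nlp_analyze(rec$abstract, config$nlp_backend, config$extra_demonyms)
    pairs <- extract_associations(rec$abstract, pmid = rec$pmid,
                                  config = config, parsed = parsed)
    cohort <- extract_cohort_info(parsed, config)
    out[[i]] <- assemble_records(rec, pairs, cohort)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_association_records())
  class(res) <- c("snp_associations", class(res))
  res
}

#' Extract associations and cohort information from raw text
#'
#' Convenience entry point for a single abstract or evidence sentence:
#' returns the assembled association records without the usability
#' filter, so desk examples can be run directly.
#'
#' @param text abstract or sentence text.
#' @param pmid id attached to the output rows.
#' @param config pipeline configuration, see [snp_config()].
#' @return a `snp_associations` tibble.
#' @export
#' @examples
#' extract_from_text("rs11624704, P = 2.67 ×10^−9^, was associated with obesity.")
extract_from_text <- function(text, pmid = NA_character_, config = snp_config()) {
  rec <- tibble(pmid = pmid, title = "", abstract = text,
                pub_date = NA_character_, language = NA_character_)
  mine_abstracts(rec, config = config, filter = FALSE)
}

#' Evaluate the pipeline on a gold-labelled corpus
#'
#' Mines the given abstract records and scores the result against gold
#' annotations.
#'
#' @param records an abstract-record tibble.
#' @param gold a gold-annotation tibble.
#' @param config pipeline configuration, see [snp_config()].
#' @return an `snp_metrics` object.
#' @export
evaluate_corpus <- function(records, gold, config = snp_config()) {
  score_associations(mine_abstracts(records, config = config),
                     gold, rel_tol = config$rel_tol)
}
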