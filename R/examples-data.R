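#' Bundled worked-example evidence sentences
#'
#' Published evidence sentences from GWAS abstracts that exercise the
#' extractor's notational dialects and pairing rules: exponent dialects,
#' P/OR co-reporting, multi-SNP "respectively" constructs with a leading
#' significance threshold, cohort-size phrasing with subgroup
#' breakdowns, nationality mentions, duplicate rsID mentions, and an
#' unmarked second value. Used by the worked examples in the README and
#' by the reproduction script.
#'
#' @return a tibble: `row_id`, `pmid`, `source_table`, `sentence`.
#' @export
#' @examples
#' example_sentences()
example_sentences <- function() {
  path <- system.file("extdata", "example_sentences.tsv", package = "snpminer")
  readr::read_tsv(
    path,
    col_types = readr::cols(
      row_id = readr::col_integer(),
      pmid = readr::col_character(),
      source_table = readr::col_integer(),
      sentence = readr::col_character()
    )
  )
}
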