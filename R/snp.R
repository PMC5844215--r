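#' Find dbSNP rsID mentions in text
#'
#' Matches refSNP identifiers: a case-insensitive `rs` prefix, at most one
#' intervening space, and one or more digits. A single trailing base
#' letter (A, C, G or T) immediately adjacent to the digits and followed
#' by a non-alphanumeric boundary is captured as the reported allele and
#' stripped from the normalised id; a bracketed allele as in
#' `rs5770917[C]` is not consumed. Submitted-SNP (`ss`) ids are not
#' matched. Recognition is pure text processing and identical under every
#' NLP backend.
#'
#' @param text a single string.
#' @return a tibble ordered by `start`: `surface`, `rsid` (normalised,
#'   `rs` + digits), `allele` (`NA` unless a trailing base was captured),
#'   `start`, `end` (1-based inclusive character offsets into `text`).
#' @export
#' @examples
#' find_snp_mentions("at 10q25.2 (rs7086803, P = 3.54e-18)")
find_snp_mentions <- function(text) {
  out <- tibble(
    surface = character(), rsid = character(), allele = character(),
    start = integer(), end = integer()
  )
  if (length(text) != 1 || is.na(text) || !nzchar(text)) return(out)

  m <- gregexpr("(?<![A-Za-z0-9])[rR][sS] ?[0-9]+", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L

  n <- nchar(text)
  nxt <- substring(text, ends + 1L, ends + 1L)
  after <- substring(text, ends + 2L, ends + 2L)
  take_allele <- nxt %in% c("A", "C", "G", "T") & !grepl("^[A-Za-z0-9]$", after)
  allele <- ifelse(take_allele, nxt, NA_character_)
  ends <- ends + as.integer(take_allele)
  surface <- substring(text, starts, ends)
  quick_tbl(
    surface = surface,
    rsid = paste0("rs", stringr::str_extract(surface, "[0-9]+")),
    allele = allele,
    start = starts, end = ends
  )
}

#' Group duplicate rsID mentions within one sentence
#'
#' Repeated mentions of the same rsID in a sentence (e.g. once bare and
#' once with a bracketed allele) are collapsed into a single group that
#' carries every span, so that downstream pairing measures distance as the
#' minimum over the group's mentions.
#'
#' @param mentions a tibble from [find_snp_mentions()], all from one
#'   sentence.
#' @return a tibble in first-occurrence order: `rsid`, `first_start`,
#'   `n_mentions`, and a `spans` list-column of `start`/`end` tibbles.
#' @export
dedupe_mentions <- function(mentions) {
  if (nrow(mentions) == 0) {
    return(tibble(rsid = character(), first_start = integer(),
                  n_mentions = integer(), spans = list()))
  }
  ids <- unique(mentions$rsid)
  idx <- split(seq_len(nrow(mentions)), match(mentions$rsid, ids))
  quick_tbl(
    rsid = ids,
    first_start = vapply(idx, function(i) min(mentions$start[i]), integer(1),
                         USE.NAMES = FALSE),
    n_mentions = unname(lengths(idx)),
    spans = unname(lapply(idx, function(i) {
      quick_tbl(start = mentions$start[i], end = mentions$end[i])
    }))
  )
}

#' Does a text contain at least one rsID mention?
#'
#' Predicate used by the relevance filter to keep only SNP-association
#' abstracts.
#'
#' @param text a single string.
#' @return `TRUE` or `FALSE`.
#' @export
has_snp_mention <- function(text) {
  nrow(find_snp_mentions(text)) > 0
}
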