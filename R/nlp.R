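# Linguistic-analysis layer. Downstream stages consume only this contract:
# sentence spans, tokens, dependency-style numeric-modifier arcs and
# nationality (NORP-like) entity spans. Two deterministic backends are
# provided: "syntactic" derives arcs via a noun-phrase-head heuristic and
# entities via a demonym lexicon; "minimal" supplies sentences and tokens
# only, so regex-only stages stay testable in isolation.

# Demonym lexicon for the NORP-style entity recogniser. Single-token
# nationality / ethnic-group adjectives as they appear capitalised in
# abstracts; extensible via snp_config(extra_demonyms = ...).
norp_demonyms <- c(
  "Afghan", "African", "Albanian", "Algerian", "American", "Arab",
  "Argentine", "Argentinian", "Armenian", "Asian", "Australian",
  "Austrian", "Bangladeshi", "Belgian", "Bengali", "Bosnian", "Brazilian",
  "British", "Bulgarian", "Cambodian", "Canadian", "Caucasian", "Chilean",
  "Chinese", "Colombian", "Croatian", "Cuban", "Czech", "Danish", "Dutch",
  "Egyptian", "English", "Estonian", "Ethiopian", "European", "Filipino",
  "Finn", "Finnish", "French", "German", "Ghanaian", "Greek", "Han",
  "Hispanic", "Hungarian", "Icelandic", "Indian", "Indonesian", "Iranian",
  "Iraqi", "Irish", "Israeli", "Italian", "Jamaican", "Japanese",
  "Jewish", "Jordanian", "Kazakh", "Kenyan", "Korean", "Kurdish",
  "Latino", "Latvian", "Lebanese", "Lithuanian", "Malay", "Malaysian",
  "Mexican", "Mongolian", "Moroccan", "Nepalese", "Nigerian", "Norwegian",
  "Pakistani", "Palestinian", "Persian", "Peruvian", "Polish",
  "Portuguese", "Romanian", "Russian", "Saudi", "Scottish", "Serbian",
  "Singaporean", "Slovak", "Slovenian", "Somali", "Spanish", "Sudanese",
  "Swedish", "Swiss", "Syrian", "Taiwanese", "Thai", "Tibetan",
  "Tunisian", "Turkish", "Ugandan", "Ukrainian", "Uyghur", "Vietnamese",
  "Welsh", "Yoruba", "Zulu"
)

# function words that terminate a noun-phrase run when locating the head
# of a numeric modifier
np_stopwords <- c(
  "and", "or", "of", "with", "in", "for", "to", "from", "the", "a", "an",
  "were", "was", "are", "is", "be", "been", "using", "at", "by", "on",
  "as", "that", "who", "which", "than", "but", "not", "between", "after",
  "before", "during", "versus", "vs", "we", "they", "it", "this", "these",
  "those", "other", "such", "including", "consisting", "had", "has",
  "have", "per"
)

#' Analyse abstract text into sentences, tokens, arcs and entities
#'
#' Splits `text` into sentences and tokenises each one; under the
#' `"syntactic"` backend it additionally emits numeric-modifier dependency
#' arcs (a number token attached to the head noun of the following noun
#' phrase) and nationality entity spans from a demonym lexicon. All
#' offsets are 1-based inclusive character positions into the original
#' `text`, so `substr(text, start, end)` recovers every surface form.
#'
#' @param text abstract text (a single string).
#' @param backend `"syntactic"` or `"minimal"`.
#' @param extra_demonyms additional nationality surface forms.
#' @return a tibble with one row per sentence: `sentence_id`, `text`,
#'   `start`, `end`, and list-columns `tokens` (`index`, `text`, `start`,
#'   `end`), `arcs` (`dependent`, `head`, `relation`) and `entities`
#'   (`text`, `category`, `start`, `end`).
#' @export
#' @examples
#' nlp_analyze("We studied 889 lung cancer cases. Controls were healthy.")
nlp_analyze <- function(text, backend = c("syntactic", "minimal"),
                        extra_demonyms = character()) {
  backend <- match.arg(backend)
  empty <- tibble(
    sentence_id = integer(), text = character(), start = integer(),
    end = integer(), tokens = list(), arcs = list(), entities = list()
  )
  if (length(text) != 1 || is.na(text) || !nzchar(text)) return(empty)

  sents <- split_sentences(text)
  if (nrow(sents) == 0) return(empty)

  lexicon <- c(norp_demonyms, extra_demonyms)
  sents$tokens <- purrr::map2(sents$text, sents$start, tokenize_sentence)
  if (backend == "syntactic") {
    sents$arcs <- purrr::map(sents$tokens, nummod_arcs)
    sents$entities <- purrr::map(sents$tokens, norp_entities, lexicon = lexicon)
  } else {
    sents$arcs <- purrr::map(sents$tokens, ~ empty_arcs())
    sents$entities <- purrr::map(sents$tokens, ~ empty_entities())
  }
  sents$sentence_id <- seq_len(nrow(sents))
  sents[, c("sentence_id", "text", "start", "end", "tokens", "arcs", "entities")]
}

# sentence boundary: terminal punctuation followed by whitespace;
# decimal points and clause-internal periods (no following space) never
# match. Sentences may start lowercase -- abstracts open sentences with
# rsIDs and gene symbols -- so no capitalisation requirement is imposed.
split_sentences <- function(text) {
  n <- nchar(text)
  locs <- stringr::str_locate_all(text, "[.!?]+(?=\\s)")[[1]]
  breaks <- integer(0)
  if (nrow(locs)) {
    for (i in seq_len(nrow(locs))) {
      rest <- substr(text, locs[i, 2] + 1L, n)
      if (grepl("^\\s+\\S", rest)) breaks <- c(breaks, locs[i, 2])
    }
  }
  bounds <- c(0L, breaks, n)
  lo <- bounds[-length(bounds)] + 1L
  hi <- bounds[-1]
  seg <- substring(text, lo, hi)
  lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
  trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
  s <- lo + lead
  e <- hi - trail
  keep <- s <= e
  quick_tbl(text = substring(text, s[keep], e[keep]),
            start = s[keep], end = e[keep])
}

# words (internal hyphens/apostrophes kept), numbers (thousands separators
# and decimals kept), any other non-space character as its own token
tokenize_sentence <- function(sentence_text, abs_start) {
  pat <- "[A-Za-z]+(?:[-'’][A-Za-z]+)*|[0-9]+(?:,[0-9]{3})*(?:\\.[0-9]+)?|[^ \t\r\n]"
  m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(quick_tbl(index = integer(), text = character(),
                     start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  quick_tbl(
    index = seq_along(starts),
    text = substring(sentence_text, starts, starts + lens - 1L),
    start = abs_start + starts - 1L,
    end = abs_start + starts + lens - 2L
  )
}

empty_arcs <- function() {
  tibble(dependent = integer(), head = integer(), relation = character())
}

empty_entities <- function() {
  tibble(text = character(), category = character(),
         start = integer(), end = integer())
}

is_integer_token <- function(x) grepl("^[0-9]+(,[0-9]{3})*$", x)
is_word_token <- function(x) grepl("^[A-Za-z]", x)

# numeric-modifier arcs: each integer token is attached to the last word
# of the contiguous content-word run that follows it (the noun-phrase
# head); if the run is empty the nearest adjacent word token serves as a
# placeholder head so the candidate still exists for window matching
# noun-phrase head of the number at token i: last word of the contiguous
# content-word run that follows; nearest adjacent word as placeholder
# when the run is empty
np_head_index <- function(tokens, i) {
  head_idx <- NA_integer_
  j <- i + 1L
  while (j <= nrow(tokens) && is_word_token(tokens$text[j]) &&
         !(tolower(tokens$text[j]) %in% np_stopwords)) {
    head_idx <- j
    j <- j + 1L
  }
  if (is.na(head_idx)) {
    after <- which(is_word_token(tokens$text) & seq_len(nrow(tokens)) > i)
    before <- which(is_word_token(tokens$text) & seq_len(nrow(tokens)) < i)
    head_idx <- if (length(after)) after[1] else if (length(before)) max(before) else NA_integer_
  }
  if (!is.na(head_idx) && head_idx == i) head_idx <- NA_integer_
  head_idx
}

nummod_arcs <- function(tokens) {
  deps <- which(is_integer_token(tokens$text))
  if (!length(deps)) return(empty_arcs())
  heads <- vapply(deps, function(i) np_head_index(tokens, i), integer(1))
  keep <- !is.na(heads)
  if (!any(keep)) return(empty_arcs())
  quick_tbl(dependent = deps[keep], head = heads[keep],
            relation = rep("nummod", sum(keep)))
}

norp_entities <- function(tokens, lexicon) {
  hit <- tokens$text %in% lexicon
  if (!any(hit)) return(empty_entities())
  quick_tbl(
    text = tokens$text[hit], category = rep("NORP", sum(hit)),
    start = tokens$start[hit], end = tokens$end[hit]
  )
}
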