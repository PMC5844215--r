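# Sentence normalisation with an offset map. Published abstracts report
# exponents in several dialects ("3.54 x 10(-18)", "2.67 x10^-9^",
# "5e-8"), use three different minus signs (hyphen-minus, en dash,
# Unicode minus U+2212), and name the P statistic in many variants
# ("P-value", "combined P", "Pmeta", ...). Everything is rewritten to one
# canonical form -- e-notation numbers, marker "P", marker "OR" -- while a
# per-character map back to the original sentence is maintained, so that
# spans of parsed values can be reported (and distances measured) in the
# coordinates of the un-normalised text.

norm_state <- function(text) {
  list(chars = strsplit(text, "")[[1]],
       map = seq_len(nchar(text)),
       original = text)
}

state_text <- function(st) paste(st$chars, collapse = "")

# apply non-overlapping replacements (current coordinates, ascending).
# Replacement characters map back into the replaced span, first char to
# its start and last char to its end, so slicing the original at a mapped
# span always covers the full source construct.
state_apply <- function(st, locs, repls) {
  if (is.null(locs) || nrow(locs) == 0) return(st)
  chars <- st$chars
  map <- st$map
  new_chars <- character(0)
  new_map <- integer(0)
  prev <- 1L
  for (i in seq_len(nrow(locs))) {
    s <- locs[i, 1]; e <- locs[i, 2]
    if (s > prev) {
      idx <- prev:(s - 1L)
      new_chars <- c(new_chars, chars[idx])
      new_map <- c(new_map, map[idx])
    }
    r <- strsplit(repls[i], "")[[1]]
    if (length(r)) {
      rmap <- as.integer(round(seq(map[s], map[e], length.out = length(r))))
      new_chars <- c(new_chars, r)
      new_map <- c(new_map, rmap)
    }
    prev <- e + 1L
  }
  if (prev <= length(chars)) {
    idx <- prev:length(chars)
    new_chars <- c(new_chars, chars[idx])
    new_map <- c(new_map, map[idx])
  }
  st$chars <- new_chars
  st$map <- new_map
  st
}

state_rewrite <- function(st, pattern, repl_fun, ignore_case = FALSE) {
  txt <- state_text(st)
  rx <- stringr::regex(pattern, ignore_case = ignore_case)
  locs <- stringr::str_locate_all(txt, rx)[[1]]
  if (nrow(locs) == 0) return(st)
  groups <- stringr::str_match_all(txt, rx)[[1]]
  repls <- repl_fun(groups)
  state_apply(st, locs, repls)
}

# any of hyphen-minus, en dash, Unicode minus
rx_minus <- "[-–−]"

canon_sign <- function(x) ifelse(is.na(x) | x == "", "", "-")

escape_literal <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

#' Normalise a sentence to canonical statistic notation
#'
#' Rewrites exponent dialects to e-notation *before* punctuation
#' stripping, collapses P-value marker variants to the canonical marker
#' `P` and odds-ratio markers to `OR`, normalises `<=`/`>=` and Unicode
#' minus signs, and finally removes quotes, brackets and emphasis
#' asterisks. Returns the rewritten text together with a character-level
#' offset map back to the original sentence.
#'
#' @param sentence one sentence of abstract text.
#' @param p_markers marker variants rewritten to `P` (see [snp_config()]).
#' @return a list: `text` (normalised sentence), `map` (integer vector,
#'   `map[i]` is the original position of normalised character `i`) and
#'   `original` (the input).
#' @export
#' @examples
#' normalize_sentence("combined P = 4.4 × 10(−7)")$text
normalize_sentence <- function(sentence, p_markers = snp_config()$p_markers) {
  st <- norm_state(sentence)

  # exponent dialects; mantissa forms first so the bare-10 rules cannot
  # orphan a mantissa
  mant <- "(\\d+(?:\\.\\d+)?)"
  times <- "[×xX]"
  st <- state_rewrite(
    st,
    paste0(mant, "\\s*", times, "\\s*10\\s*\\(\\s*(", rx_minus, "?)\\s*(\\d+)\\s*\\)"),
    function(g) paste0(g[, 2], "e", canon_sign(g[, 3]), g[, 4])
  )
  st <- state_rewrite(
    st,
    paste0(mant, "\\s*", times, "\\s*10\\s*\\^+\\s*(", rx_minus, "?)\\s*(\\d+)\\s*\\^*"),
    function(g) paste0(g[, 2], "e", canon_sign(g[, 3]), g[, 4])
  )
  st <- state_rewrite(
    st,
    paste0("10\\s*\\(\\s*(", rx_minus, ")\\s*(\\d+)\\s*\\)"),
    function(g) paste0("1e-", g[, 3])
  )
  st <- state_rewrite(
    st,
    paste0("10\\s*\\^+\\s*(", rx_minus, "?)\\s*(\\d+)\\s*\\^*"),
    function(g) paste0("1e", canon_sign(g[, 2]), g[, 3])
  )

  # residual e-notation with exotic minus signs or upper-case E
  st <- state_rewrite(
    st,
    paste0("(?<=\\d)[eE]\\s*[–−]\\s*(?=\\d)"),
    function(g) rep("e-", nrow(g))
  )
  st <- state_rewrite(
    st, "(?<=\\d)E(?=[-+]?\\d)",
    function(g) rep("e", nrow(g))
  )

  # comparators
  st <- state_rewrite(st, "<\\s*=", function(g) rep("≤", nrow(g)))
  st <- state_rewrite(st, ">\\s*=", function(g) rep("≥", nrow(g)))

  # odds-ratio markers
  st <- state_rewrite(
    st, "(?<![A-Za-z0-9])odds[ -]ratios?(?![A-Za-z0-9])",
    function(g) rep("OR", nrow(g)), ignore_case = TRUE
  )
  st <- state_rewrite(
    st, "(?<![A-Za-z0-9])ORs(?![A-Za-z0-9])",
    function(g) rep("OR", nrow(g))
  )

  # P-marker variants, longest first, then the bare letter
  for (v in p_markers[order(-nchar(p_markers))]) {
    st <- state_rewrite(
      st,
      paste0("(?<![A-Za-z0-9])", escape_literal(v), "(?![A-Za-z0-9])"),
      function(g) rep("P", nrow(g)), ignore_case = TRUE
    )
  }
  st <- state_rewrite(
    st, "(?<![A-Za-z0-9])[pP](?![A-Za-z0-9])",
    function(g) rep("P", nrow(g))
  )

  # strip quotes, brackets and emphasis asterisks (canonical numbers no
  # longer contain brackets at this point)
  st <- state_rewrite(
    st, "[\"'“”‘’()\\[\\]{}*]",
    function(g) rep("", nrow(g))
  )

  list(text = state_text(st), map = st$map, original = st$original)
}
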