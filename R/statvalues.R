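# Statistic parsing and SNP-statistic coupling.
#
# A parsed statistic is one row: kind (P or OR), comparator, numeric
# value, the surface string and span in the *original* sentence, and a
# threshold flag. Only marker-bound numbers are parsed: a number with no
# P/OR marker in front of it is invisible to the grammar (so in
# "P = 0.045 and 0.032" only 0.045 is a statistic). Number candidates
# must carry a decimal point or an exponent; bare integers and
# thousands-separated counts are never P/OR values.

# number grammar on normalised text: decimal, e-notation, or bare ".d"
rx_stat_number <- "(?:\\d+\\.\\d+(?:e[-+]?\\d+)?|\\d+e[-+]?\\d+|\\.\\d+)"

empty_stat_values <- function() {
  tibble(
    kind = character(), comparator = character(), value = double(),
    surface = character(), start = integer(), end = integer(),
    norm_num_start = integer(), norm_num_end = integer(),
    is_threshold = logical()
  )
}

#' Parse P-values and odds ratios from a normalised sentence
#'
#' Scans the canonical text produced by [normalize_sentence()] for
#' marker-comparator-number occurrences (`P = 3.54e-18`, `OR = 2.47`,
#' `P ≤ 5e-8`, ...). Spans are mapped back to the original sentence via
#' the offset map, so downstream distance measurements run in original
#' coordinates. A `<`/`≤` value is flagged as a significance threshold
#' (and excluded from pairing) when equality-comparator values of the
#' same kind coexist in the sentence; a sentence reporting *only* `<`
#' values keeps them pairable, since many papers state exact associations
#' that way.
#'
#' @param norm the list returned by [normalize_sentence()].
#' @return a tibble: `kind`, `comparator`, `value`, `surface`, `start`,
#'   `end` (original coordinates), `norm_num_start`, `norm_num_end`
#'   (number span in the normalised text), `is_threshold`.
#' @export
#' @examples
#' parse_stat_values(normalize_sentence("rs1 (P = 0.03, OR = 1.79)"))
parse_stat_values <- function(norm) {
  txt <- norm$text
  pat <- paste0(
    "(?<![A-Za-z0-9])(P|OR)\\s*(=|<|>|≤|≥)\\s*(", rx_stat_number, ")"
  )
  locs <- stringr::str_locate_all(txt, pat)[[1]]
  if (nrow(locs) == 0) return(empty_stat_values())
  g <- stringr::str_match_all(txt, pat)[[1]]

  n <- nrow(locs)
  num <- g[, 4]
  value <- as.numeric(num)
  start_o <- norm$map[locs[, 1]]
  end_o <- norm$map[locs[, 2]]
  out <- quick_tbl(
    kind = g[, 2],
    comparator = g[, 3],
    value = value,
    surface = substr(rep(norm$original, n), start_o, end_o),
    start = as.integer(start_o),
    end = as.integer(end_o),
    norm_num_start = as.integer(locs[, 2] - nchar(num) + 1L),
    norm_num_end = as.integer(locs[, 2]),
    is_threshold = rep(FALSE, n)
  )
  # drop unparseable numbers defensively (grammar should prevent them)
  bad <- is.na(out$value) | out$value <= 0
  if (any(bad)) {
    warn(paste0("Skipping unparseable statistic value(s): ",
                paste(out$surface[bad], collapse = "; ")))
    out <- out[!bad, , drop = FALSE]
  }
  for (k in unique(out$kind)) {
    sel <- out$kind == k
    has_eq <- any(out$comparator[sel] == "=")
    out$is_threshold[sel] <- out$comparator[sel] %in% c("<", "≤") & has_eq
  }
  if (any(out$kind == "P" & out$value > 1)) {
    rlang::inform(paste0(
      "P-value greater than 1 parsed (kept, flagged): ",
      paste(out$surface[out$kind == "P" & out$value > 1], collapse = "; ")
    ))
  }
  out
}

#' Render a parsed statistic canonically
#'
#' Produces a `marker comparator number` string whose re-parse reproduces
#' the value and comparator exactly (the number is printed with enough
#' digits for an exact double round-trip).
#'
#' @param kind `"P"` or `"OR"`.
#' @param comparator one of `=`, `<`, `>`, `≤`, `≥`.
#' @param value a positive number.
#' @return a single string.
#' @export
render_stat_value <- function(kind, comparator, value) {
  paste(kind, comparator, sprintf("%.17e", value))
}

#' Flag result sentences
#'
#' A result sentence contains a P-value marker bound to a parseable
#' number (after normalisation). The flagged subset is returned in input
#' order; a bare marker with no adjacent number ("We measured P waves")
#' never flags.
#'
#' @param parsed sentence tibble from [nlp_analyze()].
#' @param p_markers marker lexicon (see [snp_config()]).
#' @return the flagged subset of `parsed`, with a `stat_values`
#'   list-column of the parsed statistics of each sentence.
#' @export
find_result_sentences <- function(parsed, p_markers = snp_config()$p_markers) {
  if (nrow(parsed) == 0) {
    out <- parsed
    out$stat_values <- list()
    return(out)
  }
  vals <- purrr::map(parsed$text, ~ parse_stat_values(normalize_sentence(.x, p_markers)))
  flagged <- purrr::map_lgl(vals, ~ any(.x$kind == "P"))
  out <- parsed[flagged, , drop = FALSE]
  out$stat_values <- vals[flagged]
  out
}

span_gap <- function(spans, v_start, v_end) {
  d <- numeric(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    d[i] <- if (v_start > spans$end[i]) {
      v_start - spans$end[i] - 1
    } else if (v_end < spans$start[i]) {
      spans$start[i] - v_end - 1
    } else {
      0
    }
  }
  min(d)
}

#' Couple SNP mention groups to statistic values of one kind
#'
#' Implements the two pairing regimes. Broadcast: when the sentence holds
#' exactly one non-threshold value of the kind and at least one SNP
#' group, that value is assigned to every group. Otherwise
#' nearest-unconsumed: SNP groups are visited in first-occurrence order
#' and each takes the not-yet-consumed value minimising character
#' distance (measured between nearest span edges, minimum over the
#' group's mention spans); a consumed value is never reused, and groups
#' left without a value yield no pair. Ties at equal distance prefer the
#' value following the SNP, matching how association statistics are
#' conventionally reported after the variant id.
#'
#' @param groups mention groups from [dedupe_mentions()].
#' @param values a [parse_stat_values()] tibble already restricted to one
#'   kind; threshold values are dropped internally.
#' @return a tibble: `rsid`, `kind`, `comparator`, `value`, `surface`,
#'   `start`, `end`, `broadcast`.
#' @export
pair_snps_to_values <- function(groups, values) {
  out_cols <- tibble(
    rsid = character(), kind = character(), comparator = character(),
    value = double(), surface = character(), start = integer(),
    end = integer(), broadcast = logical()
  )
  if (nrow(values)) values <- values[!values$is_threshold, , drop = FALSE]
  if (nrow(groups) == 0 || nrow(values) == 0) return(out_cols)
  stopifnot(length(unique(values$kind)) == 1)
  values <- values[order(values$start), , drop = FALSE]

  emit <- function(g_idx, v_idx, broadcast) {
    quick_tbl(
      rsid = groups$rsid[g_idx], kind = values$kind[v_idx],
      comparator = values$comparator[v_idx], value = values$value[v_idx],
      surface = values$surface[v_idx], start = values$start[v_idx],
      end = values$end[v_idx], broadcast = broadcast
    )
  }

  if (nrow(values) == 1) {
    return(emit(seq_len(nrow(groups)), rep(1L, nrow(groups)),
                rep(nrow(groups) > 1, nrow(groups))))
  }

  consumed <- rep(FALSE, nrow(values))
  g_taken <- integer(0)
  v_taken <- integer(0)
  for (g in seq_len(nrow(groups))) {
    avail <- which(!consumed)
    if (!length(avail)) break
    spans <- groups$spans[[g]]
    d <- vapply(avail, function(vi) span_gap(spans, values$start[vi], values$end[vi]), numeric(1))
    follows <- vapply(avail, function(vi) values$start[vi] > max(spans$end), logical(1))
    best <- avail[order(d, !follows, values$start[avail])][1]
    consumed[best] <- TRUE
    g_taken <- c(g_taken, g)
    v_taken <- c(v_taken, best)
  }
  emit(g_taken, v_taken, rep(FALSE, length(g_taken)))
}

#' Extract SNP-statistic association pairs from an abstract
#'
#' Runs the full per-sentence procedure: flag result sentences, find and
#' deduplicate rsID mentions, parse P and OR statistics, and couple each
#' kind to the mention groups independently (separate consumption pools,
#' the same pairing procedure for both). Pairs from the two kinds are
#' merged by rsid within the sentence; every pair carries the original,
#' un-normalised sentence as its evidence.
#'
#' @param text abstract text.
#' @param pmid PubMed id attached to each pair.
#' @param config pipeline configuration, see [snp_config()].
#' @param parsed optional pre-computed [nlp_analyze()] result for `text`.
#' @return a tibble: `pmid`, `sentence_id`, `rsid`, `p_comparator`,
#'   `p_value`, `or_comparator`, `or_value`, `p_broadcast`,
#'   `evidence_sentence`.
#' @export
#' @examples
#' extract_associations(
#'   "Association was detected at rs2254298 (P = 0.03) but not rs53576."
#' )
extract_associations <- function(text, pmid = NA_character_,
                                 config = snp_config(), parsed = NULL) {
  if (is.null(parsed)) {
    parsed <- nlp_analyze(text, config$nlp_backend, config$extra_demonyms)
  }
  empty <- tibble(
    pmid = character(), sentence_id = integer(), rsid = character(),
    p_comparator = character(), p_value = double(),
    or_comparator = character(), or_value = double(),
    p_broadcast = logical(), evidence_sentence = character()
  )
  if (nrow(parsed) == 0) return(empty)

  rows <- list()
  for (i in seq_len(nrow(parsed))) {
    stext <- parsed$text[i]
    vals <- parse_stat_values(normalize_sentence(stext, config$p_markers))
    if (!any(vals$kind == "P")) next
    mentions <- find_snp_mentions(stext)
    if (nrow(mentions) == 0) next
    groups <- dedupe_mentions(mentions)

    pp <- pair_snps_to_values(groups, vals[vals$kind == "P", , drop = FALSE])
    op <- pair_snps_to_values(groups, vals[vals$kind == "OR", , drop = FALSE])

    pi <- match(groups$rsid, pp$rsid)
    oi <- match(groups$rsid, op$rsid)
    ng <- nrow(groups)
    merged <- quick_tbl(
      pmid = rep(pmid, ng),
      sentence_id = rep(parsed$sentence_id[i], ng),
      rsid = groups$rsid,
      p_comparator = pp$comparator[pi],
      p_value = pp$value[pi],
      or_comparator = op$comparator[oi],
      or_value = op$value[oi],
      p_broadcast = pp$broadcast[pi],
      evidence_sentence = rep(stext, ng)
    )
    merged <- merged[!(is.na(merged$p_value) & is.na(merged$or_value)), , drop = FALSE]
    if (nrow(merged) == 0) next
    rows[[length(rows) + 1L]] <- merged
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)[, names(empty)]
}
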