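# Cohort extraction: patient/control group sizes via numeric-modifier
# candidates matched against keyword sets, and ethnicity via a frequency
# vote over nationality entity mentions.

#' Collect numeric-modifier candidates from parsed sentences
#'
#' One candidate per numeric-modifier arc whose dependent token parses as
#' an integer (thousands separators as in `1,005` accepted, decimals
#' rejected). Each candidate records the head-token text and a window of
#' up to two word tokens on each side of the number. When a sentence
#' carries no dependency arcs (the minimal backend), candidates are
#' derived directly from its integer tokens, with a surrogate head taken
#' from plain token adjacency (the last word of the contiguous
#' content-word run after the number) so that compound phrases such as
#' "889 lung cancer cases" still expose their quantified noun.
#'
#' @param parsed sentence tibble from [nlp_analyze()].
#' @return a tibble in abstract order: `value`, `start`, `end`,
#'   `head_token`, `neighbors` (list of character vectors), `sentence_id`,
#'   `sentence`.
#' @export
#' @examples
#' p <- nlp_analyze("We recruited 889 lung cancer cases and 1005 controls.")
#' collect_numeric_candidates(p)
collect_numeric_candidates <- function(parsed) {
  empty <- tibble(
    value = integer(), start = integer(), end = integer(),
    head_token = character(), neighbors = list(),
    sentence_id = integer(), sentence = character()
  )
  if (nrow(parsed) == 0) return(empty)

  rows <- list()
  for (i in seq_len(nrow(parsed))) {
    toks <- parsed$tokens[[i]]
    arcs <- parsed$arcs[[i]]
    if (nrow(toks) == 0) next
    if (nrow(arcs) > 0) {
      arcs <- arcs[arcs$relation == "nummod", , drop = FALSE]
      dep_idx <- arcs$dependent
      head_txt <- toks$text[arcs$head]
    } else {
      dep_idx <- which(is_integer_token(toks$text))
      head_txt <- vapply(dep_idx, function(di) {
        hi <- np_head_index(toks, di)
        if (is.na(hi)) NA_character_ else toks$text[hi]
      }, character(1))
    }
    word_idx <- which(is_word_token(toks$text))
    for (k in seq_along(dep_idx)) {
      di <- dep_idx[k]
      tok <- toks$text[di]
      if (!is_integer_token(tok)) next
      val <- suppressWarnings(as.integer(gsub(",", "", tok, fixed = TRUE)))
      if (is.na(val)) next
      left <- utils::tail(word_idx[word_idx < di], 2)
      right <- utils::head(word_idx[word_idx > di], 2)
      rows[[length(rows) + 1L]] <- list(
        value = val, start = toks$start[di], end = toks$end[di],
        head_token = head_txt[k],
        neighbors = list(toks$text[c(left, right)]),
        sentence_id = parsed$sentence_id[i],
        sentence = parsed$text[i]
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- tibble(
    value = vapply(rows, `[[`, integer(1), "value"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    head_token = vapply(rows, `[[`, character(1), "head_token"),
    neighbors = lapply(rows, function(r) r$neighbors[[1]]),
    sentence_id = vapply(rows, `[[`, integer(1), "sentence_id"),
    sentence = vapply(rows, `[[`, character(1), "sentence")
  )
  out[order(out$start), , drop = FALSE]
}

# stem match: case-insensitive, plural-insensitive against singular stems
kw_hit <- function(words, stems) {
  words <- tolower(words[!is.na(words)])
  if (!length(words)) return(FALSE)
  singular <- sub("s$", "", words)
  any(words %in% stems) || any(singular %in% stems)
}

#' Match numeric candidates to patient and control group sizes
#'
#' A candidate is classified by comparing its head token and its
#' two-word neighbour window against the patient and control keyword
#' sets. Control keywords take precedence: a candidate whose context
#' matches both sets ("312 healthy subjects" -- "subject" is a patient
#' stem, "healthy" a control stem) counts as a control hit. The first
#' hit per set in abstract order wins, so stated totals beat subgroup
#' breakdowns that appear later in the sentence.
#'
#' @param candidates tibble from [collect_numeric_candidates()].
#' @param config pipeline configuration, see [snp_config()].
#' @return a one-row tibble: `patient_size`, `control_size`,
#'   `patient_evidence`, `control_evidence` (`NA` where no hit).
#' @export
match_group_sizes <- function(candidates, config = snp_config()) {
  res <- tibble(
    patient_size = NA_integer_, control_size = NA_integer_,
    patient_evidence = NA_character_, control_evidence = NA_character_
  )
  if (nrow(candidates) == 0) return(res)
  for (i in seq_len(nrow(candidates))) {
    ctx <- c(candidates$head_token[i], candidates$neighbors[[i]])
    control <- kw_hit(ctx, config$control_keywords)
    patient <- !control && kw_hit(ctx, config$patient_keywords)
    if (control && is.na(res$control_size)) {
      res$control_size <- candidates$value[i]
      res$control_evidence <- candidates$sentence[i]
    } else if (patient && is.na(res$patient_size)) {
      res$patient_size <- candidates$value[i]
      res$patient_evidence <- candidates$sentence[i]
    }
    if (!is.na(res$patient_size) && !is.na(res$control_size)) break
  }
  res
}

#' Extract the cohort ethnicity label from an abstract
#'
#' Counts nationality (NORP-category) entity mentions of at least
#' `min_chars` characters across the whole abstract and returns the most
#' frequent label; ties break towards the earliest first occurrence. The
#' length floor removes acronym noise while keeping short demonyms such
#' as "Thai".
#'
#' @param parsed sentence tibble from [nlp_analyze()].
#' @param min_chars minimum label length in characters.
#' @return a one-row tibble: `ethnicity` (`NA` when no qualifying
#'   entity) and `ethnicity_evidence` (sentence of the first occurrence).
#' @export
extract_ethnicity <- function(parsed,
                              min_chars = snp_config()$min_nationality_chars) {
  res <- tibble(ethnicity = NA_character_, ethnicity_evidence = NA_character_)
  if (nrow(parsed) == 0) return(res)
  ents <- dplyr::bind_rows(purrr::map2(
    parsed$entities, seq_len(nrow(parsed)),
    function(e, i) { if (nrow(e)) e$`.sent` <- i; e }
  ))
  if (is.null(ents) || nrow(ents) == 0) return(res)
  ents <- ents[ents$category == "NORP" & nchar(ents$text) >= min_chars, , drop = FALSE]
  if (nrow(ents) == 0) return(res)
  ents <- ents[order(ents$start), , drop = FALSE]
  counts <- ents |>
    mutate(.first = match(.data$text, unique(.data$text))) |>
    count(.data$text, .data$.first, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$.first)
  winner <- counts$text[1]
  first_row <- which(ents$text == winner)[1]
  tibble(
    ethnicity = winner,
    ethnicity_evidence = parsed$text[ents$`.sent`[first_row]]
  )
}

#' Extract full cohort information from an abstract
#'
#' Convenience wrapper combining [collect_numeric_candidates()],
#' [match_group_sizes()] and [extract_ethnicity()].
#'
#' @param parsed sentence tibble from [nlp_analyze()].
#' @param config pipeline configuration, see [snp_config()].
#' @return a one-row tibble: `patient_size`, `control_size`, `ethnicity`
#'   and the three evidence sentences.
#' @export
#' @examples
#' p <- nlp_analyze("We studied 889 cases and 1005 controls in a Finnish cohort.")
#' extract_cohort_info(p)
extract_cohort_info <- function(parsed, config = snp_config()) {
  sizes <- match_group_sizes(collect_numeric_candidates(parsed), config)
  eth <- extract_ethnicity(parsed, config$min_nationality_chars)
  dplyr::bind_cols(sizes[, c("patient_size", "control_size")], eth["ethnicity"],
                   sizes[, c("patient_evidence", "control_evidence")],
                   eth["ethnicity_evidence"])
}
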