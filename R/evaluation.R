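# Scoring extracted associations against gold annotations.

#' Read gold association annotations
#'
#' The contract-bearing dialect is TSV with header `pmid`, `rsid`,
#' `p_value`, `or_value`, `sentence_id`; values may be written in any of
#' the exponent dialects accepted by the extractor. A best-effort reader
#' for a simple XML layout (`<annotations><annotation pmid=... rsid=...
#' p_value=... or_value=... sentence_id=.../></annotations>`) is provided
#' behind the same record type. Every annotation must carry at least one
#' of `p_value`/`or_value`.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"snpphena_xml"`.
#' @return a tibble: `pmid`, `rsid`, `p_value`, `or_value`, `sentence_id`.
#' @export
read_gold <- function(path, dialect = c("tsv", "snpphena_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    raw <- readr::read_tsv(
      path, na = "", col_types = readr::cols(.default = readr::col_character())
    )
    need <- c("pmid", "rsid", "p_value", "or_value", "sentence_id")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      abort(paste0("Gold TSV is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    out <- tibble(
      pmid = raw$pmid,
      rsid = raw$rsid,
      p_value = parse_gold_number(raw$p_value),
      or_value = parse_gold_number(raw$or_value),
      sentence_id = suppressWarnings(as.integer(raw$sentence_id))
    )
  } else {
    doc <- xml2::read_xml(path)
    nodes <- xml2::xml_find_all(doc, ".//annotation")
    out <- tibble(
      pmid = xml2::xml_attr(nodes, "pmid"),
      rsid = xml2::xml_attr(nodes, "rsid"),
      p_value = parse_gold_number(xml2::xml_attr(nodes, "p_value")),
      or_value = parse_gold_number(xml2::xml_attr(nodes, "or_value")),
      sentence_id = suppressWarnings(as.integer(xml2::xml_attr(nodes, "sentence_id")))
    )
  }
  bad <- which(is.na(out$p_value) & is.na(out$or_value))
  if (length(bad)) {
    abort(paste0("Gold annotation without any value at line/record ",
                 paste(bad, collapse = ", ")))
  }
  out
}

# gold numbers share the extractor's number grammar: run a value through
# sentence normalisation and parse the canonical e-notation
parse_gold_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return(NA_real_)
    canon <- normalize_sentence(trimws(v), p_markers = character())$text
    out <- suppressWarnings(as.numeric(canon))
    if (is.na(out)) abort(paste0("Unparseable gold value: '", v, "'"))
    out
  }, double(1), USE.NAMES = FALSE)
}

#' Write gold annotations as TSV
#'
#' @param gold a gold-annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  flat <- tibble(
    pmid = gold$pmid, rsid = gold$rsid,
    p_value = ifelse(is.na(gold$p_value), "", sprintf("%.6e", gold$p_value)),
    or_value = ifelse(is.na(gold$or_value), "", sprintf("%.6e", gold$or_value)),
    sentence_id = ifelse(is.na(gold$sentence_id), "", as.character(gold$sentence_id))
  )
  readr::write_tsv(flat, path, na = "")
  invisible(path)
}

#' Score predicted associations against gold annotations
#'
#' A prediction matches a gold annotation iff `pmid` and `rsid` agree and
#' every value present in the gold record (`p_value` and/or `or_value`)
#' is present in the prediction within relative tolerance `rel_tol`.
#' Matching is one-to-one and greedy: gold records are visited in input
#' order and each takes the first unmatched compatible prediction.
#' Unmatched predictions count as false positives, unmatched gold as
#' false negatives. Precision and recall are 0 when their denominator is
#' 0; F1 is the harmonic mean (0 when both are 0).
#'
#' @param predicted a `snp_associations` tibble (or any tibble with
#'   `pmid`, `rsid`, `p_value`, `or_value`).
#' @param gold a gold-annotation tibble from [read_gold()] or
#'   [generate_synthetic_abstracts()].
#' @param rel_tol relative tolerance for value agreement.
#' @return an object of class `snp_metrics`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
#' @examples
#' gold <- tibble::tibble(pmid = "1", rsid = "rs1", p_value = 0.03,
#'                        or_value = NA_real_, sentence_id = 1L)
#' pred <- tibble::tibble(pmid = "1", rsid = "rs1", p_value = 0.03,
#'                        or_value = NA_real_)
#' score_associations(pred, gold)
score_associations <- function(predicted, gold, rel_tol = snp_config()$rel_tol) {
  value_ok <- function(gv, pv) {
    if (is.na(gv)) return(TRUE)
    if (is.na(pv)) return(FALSE)
    abs(pv - gv) <= rel_tol * abs(gv)
  }
  matched_pred <- rep(FALSE, nrow(predicted))
  tp <- 0L
  for (gi in seq_len(nrow(gold))) {
    for (pi in seq_len(nrow(predicted))) {
      if (matched_pred[pi]) next
      if (!identical(as.character(predicted$pmid[pi]), as.character(gold$pmid[gi]))) next
      if (!identical(predicted$rsid[pi], gold$rsid[gi])) next
      if (!value_ok(gold$p_value[gi], predicted$p_value[pi])) next
      if (!value_ok(gold$or_value[gi], predicted$or_value[pi])) next
      matched_pred[pi] <- TRUE
      tp <- tp + 1L
      break
    }
  }
  fp <- sum(!matched_pred)
  fn <- nrow(gold) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(tp = tp, fp = as.integer(fp), fn = as.integer(fn),
         precision = precision, recall = recall, f1 = f1, rel_tol = rel_tol),
    class = "snp_metrics"
  )
}

#' Compute F1 from precision and recall
#'
#' Harmonic mean, 0 when both inputs are 0.
#'
#' @param precision,recall reals in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' @export
print.snp_metrics <- function(x, ...) {
  cat(sprintf(
    "SNP association extraction metrics\n  tp = %d, fp = %d, fn = %d\n  precision = %.4f\n  recall    = %.4f\n  F1        = %.4f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1
  ))
  invisible(x)
}

#' Tidy an `snp_metrics` object
#'
#' @param x an `snp_metrics` object.
#' @param ... unused.
#' @return a tibble with one row per metric (`metric`, `value`).
#' @method tidy snp_metrics
#' @export
tidy.snp_metrics <- function(x, ...) {
  tibble(
    metric = c("tp", "fp", "fn", "precision", "recall", "f1"),
    value = c(x$tp, x$fp, x$fn, x$precision, x$recall, x$f1)
  )
}

#' One-row summary of an `snp_metrics` object
#'
#' @param x an `snp_metrics` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance snp_metrics
#' @export
glance.snp_metrics <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    precision = x$precision, recall = x$recall, f1 = x$f1
  )
}
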