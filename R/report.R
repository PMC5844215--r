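# Report assembly, sorting and tabular writers.

report_columns <- c(
  "rsid", "p_comparator", "p_value", "or_value", "patient_size",
  "control_size", "ethnicity", "pmid", "pub_date", "evidence_sentence"
)

empty_association_records <- function() {
  out <- tibble(
    rsid = character(), p_comparator = character(), p_value = double(),
    or_value = double(), patient_size = integer(), control_size = integer(),
    ethnicity = character(), pmid = character(), pub_date = character(),
    evidence_sentence = character()
  )
  class(out) <- c("snp_associations", class(out))
  out
}

#' Assemble per-abstract association records
#'
#' Joins the association pairs of one abstract with its abstract-level
#' cohort information: one output row per pair, with the cohort fields
#' copied onto every row.
#'
#' @param record one abstract record (one-row tibble with `pmid` and
#'   optionally `pub_date`).
#' @param pairs tibble from [extract_associations()].
#' @param cohort one-row tibble from [extract_cohort_info()].
#' @return a `snp_associations` tibble with the fixed report columns.
#' @export
assemble_records <- function(record, pairs, cohort) {
  if (nrow(pairs) == 0) return(empty_association_records())
  out <- tibble(
    rsid = pairs$rsid,
    p_comparator = pairs$p_comparator,
    p_value = pairs$p_value,
    or_value = pairs$or_value,
    patient_size = rep(cohort$patient_size, nrow(pairs)),
    control_size = rep(cohort$control_size, nrow(pairs)),
    ethnicity = rep(cohort$ethnicity, nrow(pairs)),
    pmid = rep(record$pmid, nrow(pairs)),
    pub_date = rep(if ("pub_date" %in% names(record)) record$pub_date else NA_character_,
                   nrow(pairs)),
    evidence_sentence = pairs$evidence_sentence
  )
  class(out) <- c("snp_associations", class(out))
  out
}

#' Sort association records
#'
#' Stable sort by one key. Records missing the key always sort last,
#' regardless of direction; `rsid` and `pmid` sort numerically by their
#' digit part.
#'
#' @param records a `snp_associations` tibble.
#' @param key one of `p_value`, `or_value`, `patient_size`,
#'   `control_size`, `pub_date`, `pmid`, `rsid`.
#' @param ascending sort direction for present values.
#' @return the sorted records (a permutation of the input).
#' @export
sort_records <- function(records, key, ascending = TRUE) {
  valid <- c("p_value", "or_value", "patient_size", "control_size",
             "pub_date", "pmid", "rsid")
  if (length(key) != 1 || !key %in% valid) {
    abort(paste0("Unknown sort key: ", paste(key, collapse = ", "),
                 ". Valid keys: ", paste(valid, collapse = ", ")))
  }
  v <- records[[key]]
  if (key %in% c("rsid", "pmid")) {
    v <- suppressWarnings(as.numeric(stringr::str_extract(v, "[0-9]+")))
  }
  keyed <- xtfrm(v)
  if (!ascending) keyed <- -keyed
  records[order(is.na(v), keyed, seq_along(v)), , drop = FALSE]
}

format_report_value <- function(x, float = FALSE) {
  out <- rep("", length(x))
  present <- !is.na(x)
  out[present] <- if (float) sprintf("%.6e", x[present]) else as.character(x[present])
  out
}

#' Write association records to TSV, CSV or JSON
#'
#' TSV/CSV carry the fixed header (`rsid`, `p_comparator`, `p_value`,
#' `or_value`, `patient_size`, `control_size`, `ethnicity`, `pmid`,
#' `pub_date`, `evidence_sentence`); floats are rendered in scientific
#' notation with 6 significant decimal digits (`3.540000e-18`), absent
#' values as empty fields. JSON is a list of flat objects with absent
#' keys omitted.
#'
#' @param records a `snp_associations` tibble.
#' @param path destination file path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  res <- tryCatch({
    if (format == "json") {
      objs <- purrr::map(seq_len(nrow(records)), function(i) {
        row <- as.list(records[i, report_columns])
        row[!vapply(row, is.na, logical(1))]
      })
      jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
    } else {
      flat <- tibble(
        rsid = records$rsid,
        p_comparator = format_report_value(records$p_comparator),
        p_value = format_report_value(records$p_value, float = TRUE),
        or_value = format_report_value(records$or_value, float = TRUE),
        patient_size = format_report_value(records$patient_size),
        control_size = format_report_value(records$control_size),
        ethnicity = format_report_value(records$ethnicity),
        pmid = records$pmid,
        pub_date = format_report_value(records$pub_date),
        evidence_sentence = records$evidence_sentence
      )
      if (format == "tsv") {
        readr::write_tsv(flat, path, na = "")
      } else {
        readr::write_csv(flat, path, na = "")
      }
    }
    invisible(path)
  }, error = function(e) {
    abort(paste0("Failed to write ", format, " output to '", path, "': ",
                 conditionMessage(e)))
  })
  res
}

#' Read association records written by [write_table()]
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return a `snp_associations` tibble.
#' @export
read_table_records <- function(path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- purrr::map(raw, function(o) {
      filled <- setNames(vector("list", length(report_columns)), report_columns)
      for (nm in names(o)) filled[[nm]] <- o[[nm]]
      tibble(
        rsid = filled$rsid %||% NA_character_,
        p_comparator = filled$p_comparator %||% NA_character_,
        p_value = as.numeric(filled$p_value %||% NA_real_),
        or_value = as.numeric(filled$or_value %||% NA_real_),
        patient_size = as.integer(filled$patient_size %||% NA_integer_),
        control_size = as.integer(filled$control_size %||% NA_integer_),
        ethnicity = filled$ethnicity %||% NA_character_,
        pmid = as.character(filled$pmid %||% NA_character_),
        pub_date = filled$pub_date %||% NA_character_,
        evidence_sentence = filled$evidence_sentence %||% NA_character_
      )
    })
    out <- dplyr::bind_rows(rows)
  } else {
    reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
    out <- reader(
      path, na = "",
      col_types = readr::cols(
        rsid = readr::col_character(),
        p_comparator = readr::col_character(),
        p_value = readr::col_double(),
        or_value = readr::col_double(),
        patient_size = readr::col_integer(),
        control_size = readr::col_integer(),
        ethnicity = readr::col_character(),
        pmid = readr::col_character(),
        pub_date = readr::col_character(),
        evidence_sentence = readr::col_character()
      )
    )
  }
  if (nrow(out) == 0) return(empty_association_records())
  class(out) <- c("snp_associations", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
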