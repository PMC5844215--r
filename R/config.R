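#' Pipeline configuration
#'
#' Returns the configuration list consumed by the extraction pipeline.
#' Defaults can be overridden by named arguments or by a config file
#' (YAML when the `yaml` package is installed, otherwise a flat
#' `key = value` file, one entry per line, with comma-separated vectors).
#'
#' Tunable entries:
#' \describe{
#'   \item{nlp_backend}{`"syntactic"` (rule-based annotator with
#'     numeric-modifier arcs and nationality entities) or `"minimal"`
#'     (sentence split + tokenisation only).}
#'   \item{patient_keywords, control_keywords}{stems matched against the
#'     head token and neighbour window of numeric candidates when locating
#'     patient/control group sizes.}
#'   \item{min_nationality_chars}{minimum character length for a
#'     nationality entity to count towards the ethnicity vote (default 4,
#'     long enough to drop acronym noise while keeping short demonyms).}
#'   \item{p_markers}{P-value marker variants normalised to the single
#'     canonical marker `P` before statistic parsing.}
#'   \item{extra_demonyms}{additional nationality surface forms for the
#'     syntactic backend's entity recogniser.}
#'   \item{rel_tol}{relative tolerance used when matching predicted
#'     statistic values against gold annotations.}
#'   \item{retmax}{maximum number of PMIDs requested from E-utilities.}
#'   \item{min_abstract_chars}{abstracts shorter than this are treated as
#'     missing/incomplete and filtered out.}
#' }
#'
#' @param ... named overrides of individual entries.
#' @param file optional path to a configuration file.
#' @return a named list of configuration values.
#' @export
#' @examples
#' cfg <- snp_config(min_nationality_chars = 5)
#' cfg$min_nationality_chars
snp_config <- function(..., file = NULL) {
  cfg <- list(
    nlp_backend = "syntactic",
    patient_keywords = c("patient", "case", "subject"),
    control_keywords = c("control", "normal", "healthy"),
    min_nationality_chars = 4L,
    p_markers = c(
      "combined P-value", "combined P", "P-values", "P-value",
      "P values", "P value", "P-combine", "P combine", "P-meta",
      "Pmeta", "meta P", "P-trend", "Ptrend", "P trend"
    ),
    extra_demonyms = character(),
    rel_tol = 1e-6,
    retmax = 3000L,
    min_abstract_chars = 50L
  )
  if (!is.null(file)) {
    cfg <- utils::modifyList(cfg, read_config_file(file))
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("Unknown config entries: ", paste(bad, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    return(yaml::read_yaml(path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- stringr::str_split_fixed(ln, "=", 2)
    key <- trimws(kv[1, 1])
    val <- trimws(kv[1, 2])
    if (!nzchar(key) || !nzchar(val)) abort(paste0("Malformed config line: ", ln))
    parts <- trimws(stringr::str_split(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
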