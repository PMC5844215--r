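# Synthetic gold-labelled abstracts. The generator emulates the writing
# conventions the extractor targets: rsIDs, P-values in the published
# exponent dialects, odds ratios, "respectively" multi-SNP constructs,
# single-value multi-SNP sentences, case/control cohort sentences,
# nationality mentions, and distractor sentences (significance
# thresholds, bare counts, gene symbols). Every planted association is
# listed in a machine-readable gold table, so planted-truth recovery is
# measurable end to end without any external corpus.

synthetic_nationalities <- c(
  "Finnish", "Chinese", "Japanese", "Turkish", "Korean", "Swedish",
  "Italian", "Spanish", "Mexican", "Egyptian", "Iranian", "Danish"
)

synthetic_genes <- c(
  "TP63", "CHEK2", "BRCA2", "TERT", "NRXN3", "IREB2", "CTSS", "APOA5",
  "CPT1B", "CHKB", "IL1B", "MIPEP"
)

synthetic_diseases <- c(
  "lung cancer", "obesity", "type 2 diabetes", "asthma", "narcolepsy",
  "metabolic syndrome", "ischemic stroke", "COPD"
)

sample_rsids <- function(k) {
  digits <- sample(1:8, k, replace = TRUE)
  vapply(digits, function(d) {
    paste0("rs", paste(c(sample(1:9, 1), sample(0:9, d - 1, replace = TRUE)),
                       collapse = ""))
  }, character(1))
}

# log-uniform P in [1e-30, 0.05]; returns value plus a rendering in a
# randomly chosen dialect
sample_p <- function() {
  k <- sample(2:30, 1)
  # keep values inside [1e-30, 0.05]
  mant <- if (k == 2) round(stats::runif(1, 1.0, 4.99), 2) else round(stats::runif(1, 1.0, 9.99), 2)
  value <- as.numeric(sprintf("%.2fe-%d", mant, k))
  dialect <- sample(c("paren", "caret", "enote", "plain"), 1)
  text <- switch(dialect,
    paren = sprintf("%.2f × 10(−%d)", mant, k),
    caret = sprintf("%.2f ×10^−%d^", mant, k),
    enote = sprintf("%.2fe-%d", mant, k),
    plain = if (k <= 4) {
      format(value, scientific = FALSE)
    } else {
      sprintf("%.2f × 10(−%d)", mant, k)
    }
  )
  list(value = value, text = text)
}

sample_or <- function() {
  value <- round(stats::runif(1, 0.2, 3.5), 2)
  list(value = value, text = sprintf("%.2f", value))
}

#' Generate synthetic gold-labelled abstracts
#'
#' Deterministic for a fixed `(n, seed, params)`. Each abstract contains
#' one or two association sentences drawn from three templates (single
#' SNP with optional odds ratio; two SNPs with two values and
#' "respectively"; two SNPs sharing a single value), a case/control
#' cohort sentence, a nationality sentence, and distractor sentences
#' including a genome-wide significance threshold. `params` controls the
#' composition:
#' \describe{
#'   \item{p_or}{probability that an association also reports an OR
#'     (default 0.5).}
#'   \item{p_unmarked_second}{probability that a two-SNP sentence uses the
#'     failure-mode style "P = a and b" where the second number carries no
#'     marker (default 0; the gold table still lists both planted
#'     associations, so recall drops by exactly one per such sentence).}
#' }
#'
#' @param n number of abstracts (>= 1).
#' @param seed integer seed; the generator restores the caller's RNG
#'   state on exit.
#' @param params list of noise/composition settings, see Details.
#' @return a list: `abstracts` (tibble `pmid`, `text`), `gold` (tibble
#'   `pmid`, `rsid`, `p_value`, `or_value`, `sentence_id`), `cohort`
#'   (tibble `pmid`, `patient_size`, `control_size`, `ethnicity`).
#' @export
#' @examples
#' corpus <- generate_synthetic_abstracts(3, seed = 1)
#' corpus$gold
generate_synthetic_abstracts <- function(n, seed, params = list()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  defaults <- list(p_or = 0.5, p_unmarked_second = 0)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    abort(paste0("Unknown generator params: ", paste(bad, collapse = ", ")))
  }
  params <- utils::modifyList(defaults, params)
  if (params$p_unmarked_second < 0 || params$p_unmarked_second > 1 ||
      params$p_or < 0 || params$p_or > 1) {
    abort("Generator probabilities must lie in [0, 1].")
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  abstracts <- vector("list", n)
  gold <- list()
  cohort <- vector("list", n)
  pmids <- as.character(sample(10000000:99999999, n))

  for (a in seq_len(n)) {
    pmid <- pmids[a]
    disease <- sample(synthetic_diseases, 1)
    gene_pool <- sample(synthetic_genes, 4)
    sentences <- character(0)
    add_sentence <- function(s) {
      sentences[[length(sentences) + 1L]] <<- s
      length(sentences)
    }

    add_sentence(sprintf(
      "This study investigated genetic susceptibility to %s in a genome-wide association framework.",
      disease
    ))

    n_assoc <- sample(1:2, 1)
    for (s in seq_len(n_assoc)) {
      template <- sample(c("single", "respectively", "shared"), 1)
      if (template == "single") {
        rs <- sample_rsids(1)
        p <- sample_p()
        with_or <- stats::runif(1) < params$p_or
        or <- if (with_or) sample_or() else NULL
        sid <- add_sentence(sprintf(
          "We identified a susceptibility locus in %s (%s, %sP = %s).",
          gene_pool[s], rs,
          if (with_or) sprintf("OR = %s, ", or$text) else "",
          p$text
        ))
        gold[[length(gold) + 1L]] <- tibble(
          pmid = pmid, rsid = rs, p_value = p$value,
          or_value = if (with_or) or$value else NA_real_, sentence_id = sid
        )
      } else if (template == "respectively") {
        rs <- sample_rsids(2)
        while (rs[1] == rs[2]) rs <- sample_rsids(2)
        p1 <- sample_p(); p2 <- sample_p()
        unmarked <- stats::runif(1) < params$p_unmarked_second
        sid <- if (unmarked) {
          add_sentence(sprintf(
            "Two SNPs %s and %s in %s were associated with %s P = %s and %s.",
            rs[1], rs[2], gene_pool[s], disease, p1$text, p2$text
          ))
        } else {
          add_sentence(sprintf(
            "%s and %s in %s were associated with %s (P = %s and P = %s, respectively).",
            rs[1], rs[2], gene_pool[s], disease, p1$text, p2$text
          ))
        }
        gold[[length(gold) + 1L]] <- tibble(
          pmid = pmid, rsid = rs, p_value = c(p1$value, p2$value),
          or_value = NA_real_, sentence_id = sid
        )
      } else {
        rs <- sample_rsids(2)
        while (rs[1] == rs[2]) rs <- sample_rsids(2)
        p <- sample_p()
        sid <- add_sentence(sprintf(
          "Both %s and %s were associated with %s (P = %s).",
          rs[1], rs[2], disease, p$text
        ))
        gold[[length(gold) + 1L]] <- tibble(
          pmid = pmid, rsid = rs, p_value = p$value,
          or_value = NA_real_, sentence_id = sid
        )
      }
    }

    patient <- sample(50:5000, 1)
    control <- sample(50:5000, 1)
    nationality <- sample(synthetic_nationalities, 1)
    add_sentence(sprintf(
      "We genotyped the variants in a case-control study with %d patients and %d healthy controls.",
      patient, control
    ))
    add_sentence(sprintf(
      "The study participants were of %s ancestry.", nationality
    ))
    add_sentence(
      "Associations reaching genome-wide significance (P ≤ 5.0 × 10(−8)) were examined."
    )
    add_sentence(sprintf(
      "Expression of %s and %s was additionally measured in 120 tissue samples.",
      gene_pool[3], gene_pool[4]
    ))

    abstracts[[a]] <- tibble(pmid = pmid, text = paste(unlist(sentences), collapse = " "))
    cohort[[a]] <- tibble(
      pmid = pmid, patient_size = patient, control_size = control,
      ethnicity = nationality
    )
  }

  list(
    abstracts = dplyr::bind_rows(abstracts),
    gold = dplyr::bind_rows(gold),
    cohort = dplyr::bind_rows(cohort)
  )
}

#' Write a synthetic corpus to disk
#'
#' Writes the abstracts in the plain-text dialect and the gold table as
#' TSV, the formats the offline pipeline reads back.
#'
#' @param corpus a list from [generate_synthetic_abstracts()].
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  abs_path <- file.path(dir, "abstracts.txt")
  gold_path <- file.path(dir, "gold.tsv")
  write_abstract_txt(
    tibble(pmid = corpus$abstracts$pmid, abstract = corpus$abstracts$text),
    abs_path
  )
  write_gold(corpus$gold, gold_path)
  invisible(c(abstracts = abs_path, gold = gold_path))
}
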