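#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot extracted association strengths
#'
#' Dot plot of -log10(P) per rsID, the view researchers use to spot the
#' variants with the strongest reported associations; the conventional
#' genome-wide significance level (5e-8) is drawn as a dashed line.
#'
#' @param object a `snp_associations` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot snp_associations
#' @export
autoplot.snp_associations <- function(object, ...) {
  df <- object[!is.na(object$p_value), , drop = FALSE]
  df$rsid <- factor(df$rsid, levels = unique(df$rsid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rsid, y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot extraction metrics
#'
#' Bar chart of precision, recall and F1.
#'
#' @param object an `snp_metrics` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot snp_metrics
#' @export
autoplot.snp_metrics <- function(object, ...) {
  df <- tibble(
    metric = factor(c("precision", "recall", "F1"),
                    levels = c("precision", "recall", "F1")),
    value = c(object$precision, object$recall, object$f1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
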