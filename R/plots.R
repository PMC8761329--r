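#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the pair-score distribution of a linkage
#'
#' Histogram of candidate-pair scores with the acceptance threshold marked;
#' the bimodal shape (non-match mass below, match mass above) is the usual
#' visual check that the weights separate the two classes.
#'
#' @param object A `linkage_result`.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_result <- function(object, binwidth = 2, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$threshold,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "pair score (sum of log2 field weights)",
      y = "candidate pairs",
      title = sprintf(
        "%s linkage: %d candidates, %d accepted at threshold %s",
        object$method, nrow(object$pairs),
        sum(object$pairs$accepted), format(object$threshold)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a linkage comparison
#'
#' Bar chart of the per-mortality-record grouping comparison categories.
#'
#' @param object A [compare_linkages()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_comparison <- function(object, ...) {
  d <- dplyr::count(object$records, .data$category, name = "n")
  d$category <- factor(
    d$category,
    levels = c("identical", "pprl_extra", "ct_extra", "both_extra")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "mortality records (log scale)",
      title = "Per-mortality-record grouping comparison"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-field missingness of an encoded dataset
#'
#' @param report A [profile_dataset()] report (or a list of them, named by
#'   dataset).
#' @return A ggplot object.
#' @export
plot_missingness <- function(report) {
  if (inherits(report, "validation_report")) report <- list(dataset = report)
  d <- purrr::map_dfr(names(report), function(nm) {
    m <- report[[nm]]$missingness
    m$dataset <- nm
    m$rate <- m$n_missing / (m$n_missing + m$n_present)
    m
  })
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$field, y = .data$rate, fill = .data$dataset
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "missing", title = "Per-field missingness") +
    ggplot2::theme_minimal()
}
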