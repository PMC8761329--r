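#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linkage result
#'
#' Returns the per-group summary: one row per person group with its size
#' and dataset composition.
#'
#' @param x A `linkage_result` from [pprl_pipeline()], [cleartext_pipeline()]
#'   or [cleartext_link()].
#' @param ... Unused.
#' @return A tibble `group_id`, `size`, `n_morbidity`, `n_mortality`.
#' @export
tidy.linkage_result <- function(x, ...) {
  g <- x$groups
  dplyr::summarise(
    dplyr::group_by(g, .data$group_id),
    size = dplyr::n(),
    n_morbidity = sum(.data$dataset == "morbidity"),
    n_mortality = sum(.data$dataset == "mortality"),
    .groups = "drop"
  )
}

#' Glance at a linkage result
#'
#' @inheritParams tidy.linkage_result
#' @return A one-row tibble: record, candidate-pair, accepted-pair and
#'   group counts, the threshold, and the linkage method.
#' @export
glance.linkage_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_records = nrow(x$groups),
    n_candidates = nrow(x$pairs),
    n_accepted = sum(x$pairs$accepted),
    n_groups = length(unique(x$groups$group_id)),
    n_multi_groups = sum(table(x$groups$group_id) > 1L),
    threshold = x$threshold
  )
}

#' Tidy a linkage comparison
#'
#' @param x A [compare_linkages()] object.
#' @param ... Unused.
#' @return The per-category summary tibble (counts and percentages of all
#'   mortality records), with truth-based correct/incorrect tallies
#'   appended when [classify_with_truth()] has been applied.
#' @export
tidy.linkage_comparison <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$truth_summary)) out <- dplyr::bind_rows(out, x$truth_summary)
  out
}

#' Glance at a linkage comparison
#'
#' @inheritParams tidy.linkage_comparison
#' @return One-row tibble: mortality record count, percentage with
#'   identical groupings, and per-side extra-link record counts.
#' @export
glance.linkage_comparison <- function(x, ...) {
  s <- stats::setNames(x$summary$n, x$summary$quantity)
  tibble::tibble(
    n_mortality = s[["mortality_records"]],
    pct_identical = x$summary$pct[x$summary$quantity == "identical"],
    n_pprl_extra = s[["pprl_extra"]],
    n_ct_extra = s[["ct_extra"]],
    n_both_extra = s[["both_extra"]]
  )
}
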