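#' Morbidity record sets linked to each mortality record
#'
#' The evaluation protocol looks only at the morbidity-to-mortality side of
#' the linkage: for every death record, which hospital (morbidity) records
#' ended up in its person group. Groups containing only morbidity records
#' are ignored; a mortality record grouped with no morbidity record maps to
#' the empty set.
#'
#' @param groups Groups tibble with columns `record_id`, `dataset`,
#'   `group_id`.
#' @return A tibble `mortality_id`, `morb_ids` (list column of character
#'   vectors, sorted).
#' @export
morbidity_sets <- function(groups) {
  stopifnot(all(c("record_id", "dataset", "group_id") %in% names(groups)))
  mort <- groups[groups$dataset == "mortality", , drop = FALSE]
  morb <- groups[groups$dataset == "morbidity", , drop = FALSE]
  morb_by_group <- split(morb$record_id, morb$group_id)
  sets <- lapply(mort$group_id, function(g) {
    v <- morb_by_group[[g]]
    if (is.null(v)) character(0) else sort(v)
  })
  tibble::tibble(mortality_id = mort$record_id, morb_ids = sets)
}

#' Compare two linkages mortality record by mortality record
#'
#' For each mortality record, the sets of morbidity records linked to it by
#' the privacy-preserving and the clear-text linkage are compared and
#' classified: `identical` (sets equal, including both empty), `pprl_extra`
#' (privacy-preserving linkage found morbidity records the clear-text one
#' did not), `ct_extra` (the reverse), or `both_extra` (each side found
#' records the other missed). A `both_extra` record is tallied on *both*
#' sides of the summary, so side counts can sum to more than the number of
#' differing records.
#'
#' @param map_pprl,map_ct Tibbles from [morbidity_sets()] over the same
#'   mortality record universe.
#' @return An object of class `linkage_comparison`: list with `records`
#'   (per-mortality-record tibble: sets, category, per-side extras) and
#'   `summary` (Table-style counts and percentages of all mortality
#'   records, one decimal place).
#' @export
compare_linkages <- function(map_pprl, map_ct) {
  if (!setequal(map_pprl$mortality_id, map_ct$mortality_id)) {
    stop("the two linkages cover different mortality record universes",
      call. = FALSE
    )
  }
  ct <- map_ct[match(map_pprl$mortality_id, map_ct$mortality_id), ]
  extra_p <- mapply(function(p, c) setdiff(p, c),
    map_pprl$morb_ids, ct$morb_ids,
    SIMPLIFY = FALSE
  )
  extra_c <- mapply(function(p, c) setdiff(c, p),
    map_pprl$morb_ids, ct$morb_ids,
    SIMPLIFY = FALSE
  )
  np <- lengths(extra_p)
  nc <- lengths(extra_c)
  category <- dplyr::case_when(
    np == 0L & nc == 0L ~ "identical",
    np > 0L & nc > 0L ~ "both_extra",
    np > 0L ~ "pprl_extra",
    TRUE ~ "ct_extra"
  )
  records <- tibble::tibble(
    mortality_id = map_pprl$mortality_id,
    morb_set_pprl = map_pprl$morb_ids,
    morb_set_ct = ct$morb_ids,
    category = category,
    extra_pprl = extra_p,
    extra_ct = extra_c
  )
  n <- nrow(records)
  n_ident <- sum(category == "identical")
  n_p <- sum(np > 0L)
  n_c <- sum(nc > 0L)
  pct <- function(x) round(100 * x / n, 1)
  summary <- tibble::tibble(
    quantity = c(
      "mortality_records", "identical",
      "pprl_extra", "ct_extra", "both_extra"
    ),
    n = c(n, n_ident, n_p, n_c, sum(category == "both_extra")),
    pct = c(100, pct(n_ident), pct(n_p), pct(n_c), pct(sum(category == "both_extra")))
  )
  structure(list(records = records, summary = summary),
    class = "linkage_comparison"
  )
}

#' @export
print.linkage_comparison <- function(x, ...) {
  cat("<linkage_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Classify linkage differences against known truth
#'
#' With synthetic ground truth (record to person map), every extra link is
#' marked correct when the mortality record and the extra morbidity record
#' belong to the same true person, and incorrect otherwise. Tallies follow
#' the evaluation convention for person-level counts: a mortality record is
#' counted under "correct" if any of its extra links on that side is
#' correct and under "incorrect" if any is incorrect — a record with both
#' appears in both tallies.
#'
#' @param comparison A [compare_linkages()] object.
#' @param truth Tibble `record_id`, `person_id` covering every referenced
#'   record.
#' @return The comparison object with a `truth_summary` tibble added
#'   (per-side counts of mortality records with correct / incorrect extra
#'   links, with percentages of all mortality records) and per-record
#'   columns `pprl_extra_correct` / `ct_extra_correct` (list columns of
#'   logicals) in `records`.
#' @export
classify_with_truth <- function(comparison, truth) {
  stopifnot(inherits(comparison, "linkage_comparison"))
  person <- stats::setNames(
    as.character(truth$person_id),
    as.character(truth$record_id)
  )
  rec <- comparison$records
  need <- unique(c(
    rec$mortality_id,
    unlist(rec$extra_pprl), unlist(rec$extra_ct)
  ))
  absent <- setdiff(need, names(person))
  if (length(absent) > 0L) {
    stop("record(s) missing from truth: ",
      paste(utils::head(absent, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  check <- function(mort_id, extras) {
    unname(person[extras] == person[[mort_id]])
  }
  rec$pprl_extra_correct <- mapply(check, rec$mortality_id, rec$extra_pprl,
    SIMPLIFY = FALSE
  )
  rec$ct_extra_correct <- mapply(check, rec$mortality_id, rec$extra_ct,
    SIMPLIFY = FALSE
  )
  n <- nrow(rec)
  pct <- function(x) round(100 * x / n, 1)
  tally <- function(lst, want) {
    sum(vapply(lst, function(v) length(v) > 0L && any(v == want), logical(1)))
  }
  truth_summary <- tibble::tibble(
    quantity = c(
      "pprl_extra_correct", "pprl_extra_incorrect",
      "ct_extra_correct", "ct_extra_incorrect"
    ),
    n = c(
      tally(rec$pprl_extra_correct, TRUE),
      tally(rec$pprl_extra_correct, FALSE),
      tally(rec$ct_extra_correct, TRUE),
      tally(rec$ct_extra_correct, FALSE)
    )
  )
  truth_summary$pct <- pct(truth_summary$n)
  comparison$records <- rec
  comparison$truth_summary <- truth_summary
  comparison
}

#' Pairwise precision, recall and F-measure of a grouping against truth
#'
#' Measures a predicted partition against the true person partition on the
#' pair level: a pair of records is predicted-linked when the two records
#' share a predicted group, and truly linked when they share a true person.
#'
#' @param groups Groups tibble (`record_id`, `group_id`).
#' @param truth Tibble `record_id`, `person_id` covering all records in
#'   `groups`.
#' @return One-row tibble `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure`.
#' @export
pairwise_quality <- function(groups, truth) {
  pid <- stats::setNames(
    as.character(truth$person_id),
    as.character(truth$record_id)
  )
  if (anyNA(pid[groups$record_id])) {
    stop("record(s) in `groups` missing from truth", call. = FALSE)
  }
  npairs <- function(sizes) sum(sizes * (sizes - 1) / 2)
  pred_sizes <- table(groups$group_id)
  true_sizes <- table(pid[groups$record_id])
  joint <- table(paste(groups$group_id, pid[groups$record_id], sep = "\r"))
  tp <- npairs(as.numeric(joint))
  n_pred <- npairs(as.numeric(pred_sizes))
  n_true <- npairs(as.numeric(true_sizes))
  fp <- n_pred - tp
  fn <- n_true - tp
  precision <- if (n_pred > 0) tp / n_pred else NA_real_
  recall <- if (n_true > 0) tp / n_true else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f_measure = f
  )
}
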