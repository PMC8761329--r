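#' Form person groups from accepted pairs by transitive closure
#'
#' Groups are the connected components of the accepted-pair graph; every
#' record not touched by an accepted pair is its own singleton group. Group
#' ids are deterministic — each group is labelled by its lexicographically
#' smallest member id — so membership does not depend on pair input order.
#'
#' @param accepted Tibble of accepted pairs with columns `id_a`, `id_b`
#'   (e.g. `dplyr::filter(scored, accepted)`).
#' @param all_ids All record ids in scope: either a character vector or a
#'   tibble with columns `record_id` and optionally `dataset` (carried
#'   through to the output).
#' @return A tibble `record_id`, (`dataset`,) `group_id`.
#' @export
build_groups <- function(accepted, all_ids) {
  if (is.data.frame(all_ids)) {
    ids <- as.character(all_ids$record_id)
    datasets <- if ("dataset" %in% names(all_ids)) as.character(all_ids$dataset)
  } else {
    ids <- as.character(all_ids)
    datasets <- NULL
  }
  if (anyDuplicated(ids)) stop("`all_ids` contains duplicate record ids", call. = FALSE)
  unknown <- setdiff(c(accepted$id_a, accepted$id_b), ids)
  if (length(unknown) > 0L) {
    stop("accepted pair references unknown record id(s): ",
      paste(utils::head(unknown, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(accepted$id_a == accepted$id_b)) {
    stop("a record cannot be paired with itself", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    accepted[, c("id_a", "id_b")],
    directed = FALSE, vertices = ids
  )
  comp <- igraph::components(g)$membership
  comp <- comp[ids]
  label <- stats::ave(ids, comp, FUN = min)
  out <- tibble::tibble(record_id = ids, group_id = label)
  if (!is.null(datasets)) {
    out <- tibble::add_column(out, dataset = datasets, .after = "record_id")
  }
  out
}

internal_pairs <- function(groups, pairs) {
  ga <- groups$group_id[match(pairs$id_a, groups$record_id)]
  gb <- groups$group_id[match(pairs$id_b, groups$record_id)]
  pairs$group_id <- ifelse(!is.na(ga) & !is.na(gb) & ga == gb, ga, NA_character_)
  pairs[!is.na(pairs$group_id), , drop = FALSE]
}

#' Flag groups needing quality-assurance review
#'
#' Applies the three post-linkage screening rules: groups containing a
#' low-weighted internal pair (score within the review band just above the
#' acceptance threshold), groups with many members, and groups containing
#' two or more death (mortality-dataset) records — a person can die only
#' once.
#'
#' @param groups Tibble from [build_groups()]; must carry a `dataset`
#'   column for the multiple-deaths rule.
#' @param pairs Accepted, scored pairs underlying the groups.
#' @param params A [qa_params()] object.
#' @return A tibble per group: `group_id`, `size`, `n_mortality`,
#'   `min_internal_score`, and logical flags `low_weight_pair`,
#'   `large_group`, `multiple_deaths`.
#' @export
flag_groups <- function(groups, pairs, params = qa_params()) {
  stopifnot(inherits(params, "qa_params"))
  sizes <- dplyr::count(groups, .data$group_id, name = "size")
  deaths <- dplyr::summarise(
    dplyr::group_by(groups, .data$group_id),
    n_mortality = if ("dataset" %in% names(groups)) {
      sum(.data$dataset == "mortality")
    } else {
      0L
    },
    .groups = "drop"
  )
  ip <- internal_pairs(groups, pairs)
  minsc <- dplyr::summarise(
    dplyr::group_by(ip, .data$group_id),
    min_internal_score = min(.data$score), .groups = "drop"
  )
  out <- dplyr::left_join(sizes, deaths, by = "group_id")
  out <- dplyr::left_join(out, minsc, by = "group_id")
  band <- params$low_weight_band
  out$low_weight_pair <- !is.na(out$min_internal_score) &
    out$min_internal_score >= band[1] & out$min_internal_score < band[2]
  out$large_group <- out$size > params$large_group
  out$multiple_deaths <- out$n_mortality >= 2L
  out
}

#' Detect the male-female twin pattern in scored pairs
#'
#' Distinct twins are the classic false-positive hazard of person linkage:
#' two people sharing surname, date of birth and full address. The
#' male-female signature is detectable even on encoded data — all
#' identifiers agree except first name and sex. A pair matches the pattern
#' when surname, date of birth, address, suburb and postcode fully agree,
#' the sex tokens differ, and the given-name Dice similarity is observed
#' and below `twin_name_ceiling`.
#'
#' @param scored Tibble from [compare_pairs()] (needs the `sim_` columns).
#' @param params A [qa_params()] object (supplies `twin_name_ceiling`).
#' @return Logical vector, one element per pair.
#' @export
detect_twin_pattern <- function(scored, params = qa_params()) {
  stopifnot(inherits(params, "qa_params"))
  agree <- function(col) !is.na(scored[[col]]) & scored[[col]] == 1
  agree("sim_surname") & agree("sim_dob") & agree("sim_address") &
    agree("sim_suburb") & agree("sim_postcode") &
    (!is.na(scored$sim_sex) & scored$sim_sex == 0) &
    (!is.na(scored$sim_given1) & scored$sim_given1 < params$twin_name_ceiling)
}

#' Split groups by removing named internal pairs
#'
#' Recomputes the connected components of each affected group after the
#' named pairs are deleted; the result always refines the input partition
#' (splitting never merges). Unaffected groups are returned unchanged.
#'
#' @param groups Tibble from [build_groups()].
#' @param pairs Accepted pairs underlying the groups.
#' @param remove_pairs Tibble with columns `id_a`, `id_b` naming internal
#'   pairs to delete; naming a pair that is not internal to any group is an
#'   error.
#' @return Re-partitioned groups tibble; attribute `"splits"` records the
#'   removed pairs.
#' @export
split_group <- function(groups, pairs, remove_pairs) {
  if (nrow(remove_pairs) == 0L) {
    attr(groups, "splits") <- remove_pairs
    return(groups)
  }
  ip <- internal_pairs(groups, pairs)
  key <- function(d) paste(pmin(d$id_a, d$id_b), pmax(d$id_a, d$id_b))
  if (!all(key(remove_pairs) %in% key(ip))) {
    stop("`remove_pairs` names a pair that is not internal to any group",
      call. = FALSE
    )
  }
  kept <- pairs[!(key(pairs) %in% key(remove_pairs)), , drop = FALSE]
  ids <- if ("dataset" %in% names(groups)) {
    groups[, c("record_id", "dataset")]
  } else {
    groups$record_id
  }
  out <- build_groups(kept[, c("id_a", "id_b")], ids)
  attr(out, "splits") <- remove_pairs
  out
}

#' Apply post-linkage quality assurance to a grouping
#'
#' Two corrective actions, mirroring operational review of a
#' privacy-preserving linkage: (1) accepted pairs matching the male-female
#' twin signature are removed and the affected groups split; (2) any group
#' still containing two or more death records is repeatedly split at its
#' weakest internal pair until no group holds more than one death record.
#' Splits only ever refine the partition; no merges are made.
#'
#' @param groups Tibble from [build_groups()] (with `dataset` column).
#' @param scored Accepted, scored pairs underlying the groups.
#' @param params A [qa_params()] object.
#' @return QA'd groups tibble; attribute `"qa"` is a list with the flag
#'   table computed before QA (`flags`), the removed twin pairs
#'   (`twin_pairs`) and the pairs removed to separate deaths
#'   (`death_split_pairs`).
#' @export
apply_group_qa <- function(groups, scored, params = qa_params()) {
  accepted <- scored[scored$accepted, , drop = FALSE]
  flags <- flag_groups(groups, accepted, params)
  twins <- accepted[detect_twin_pattern(accepted, params), c("id_a", "id_b")]
  kept <- accepted
  out <- groups
  if (nrow(twins) > 0L) {
    # only remove twin pairs that are internal (they always are, being accepted)
    out <- split_group(out, kept, twins)
    key <- paste(pmin(kept$id_a, kept$id_b), pmax(kept$id_a, kept$id_b))
    kept <- kept[!(key %in% paste(pmin(twins$id_a, twins$id_b), pmax(twins$id_a, twins$id_b))), ]
  }
  death_removed <- kept[0L, c("id_a", "id_b")]
  repeat {
    fl <- flag_groups(out, kept, params)
    bad <- fl$group_id[fl$multiple_deaths]
    if (length(bad) == 0L) break
    ip <- internal_pairs(out, kept)
    ip <- ip[ip$group_id %in% bad, , drop = FALSE]
    if (nrow(ip) == 0L) break # deaths directly multi-linked pairs exhausted
    weakest <- dplyr::slice_min(
      dplyr::group_by(ip, .data$group_id),
      order_by = .data$score, n = 1L, with_ties = FALSE
    )
    death_removed <- dplyr::bind_rows(
      death_removed, weakest[, c("id_a", "id_b")]
    )
    key <- paste(pmin(kept$id_a, kept$id_b), pmax(kept$id_a, kept$id_b))
    drop <- paste(
      pmin(weakest$id_a, weakest$id_b),
      pmax(weakest$id_a, weakest$id_b)
    )
    kept <- kept[!(key %in% drop), , drop = FALSE]
    ids <- out[, intersect(c("record_id", "dataset"), names(out))]
    out <- build_groups(kept[, c("id_a", "id_b")], ids)
  }
  attr(out, "qa") <- list(
    flags = flags,
    twin_pairs = twins,
    death_split_pairs = death_removed
  )
  out
}
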