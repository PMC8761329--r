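#' Generate candidate record pairs by blocking
#'
#' Pools the two encoded datasets and emits every distinct pair of records
#' (within-dataset and between-dataset) that shares at least one hashed
#' blocking key, across all blocking passes. Pairs are canonically ordered
#' (`id_a < id_b`) and deduplicated, so a pair sharing keys in several
#' passes appears once, attributed to the first pass (in configuration
#' order) that produced it. A record is never paired with itself.
#'
#' @param enc_a Encoded tibble of the first dataset.
#' @param enc_b Optional encoded tibble of the second dataset; omit (or
#'   `NULL`) to block a single dataset against itself only.
#' @return A tibble `id_a`, `id_b`, `block_pass`.
#' @export
build_candidates <- function(enc_a, enc_b = NULL) {
  pool <- if (is.null(enc_b)) enc_a else dplyr::bind_rows(enc_a, enc_b)
  if (anyDuplicated(pool$record_id)) {
    stop("record ids must be unique across the pooled datasets", call. = FALSE)
  }
  keys <- pool$block_keys
  keys[is.na(keys)] <- ""
  has <- nzchar(keys)
  if (!any(has)) {
    return(tibble::tibble(
      id_a = character(0), id_b = character(0), block_pass = character(0)
    ))
  }
  split_keys <- strsplit(keys[has], ";", fixed = TRUE)
  long <- tibble::tibble(
    record_id = rep(pool$record_id[has], lengths(split_keys)),
    key = unlist(split_keys)
  )
  # preserve configuration order of passes for provenance attribution
  pass_of <- sub("\\|.*$", "", long$key)
  pass_levels <- unique(pass_of)
  groups <- split(long$record_id, long$key)
  groups <- groups[lengths(groups) > 1L]
  if (length(groups) == 0L) {
    return(tibble::tibble(
      id_a = character(0), id_b = character(0), block_pass = character(0)
    ))
  }
  pass_of_group <- sub("\\|.*$", "", names(groups))
  pair_list <- purrr::map(groups, function(ids) {
    ids <- sort(unique(ids))
    if (length(ids) < 2L) {
      return(NULL)
    }
    m <- utils::combn(ids, 2L)
    tibble::tibble(id_a = m[1L, ], id_b = m[2L, ])
  })
  keep <- !vapply(pair_list, is.null, logical(1))
  pairs <- dplyr::bind_rows(pair_list[keep])
  pairs$block_pass <- rep(pass_of_group[keep],
    vapply(pair_list[keep], nrow, integer(1))
  )
  pairs$.ord <- match(pairs$block_pass, pass_levels)
  pairs <- dplyr::arrange(pairs, .data$id_a, .data$id_b, .data$.ord)
  pairs <- dplyr::distinct(pairs, .data$id_a, .data$id_b, .keep_all = TRUE)
  pairs$.ord <- NULL
  pairs
}

weight_contribution <- function(sim, w_agree, w_disagree, floor, bloom) {
  contrib <- numeric(length(sim))
  miss <- is.na(sim)
  contrib[miss] <- 0
  if (bloom) {
    full <- !miss & sim >= 1
    low <- !miss & sim < floor
    mid <- !miss & !full & !low
    contrib[full] <- w_agree
    contrib[low] <- w_disagree
    contrib[mid] <- w_disagree +
      (sim[mid] - floor) / (1 - floor) * (w_agree - w_disagree)
  } else {
    contrib[!miss & sim == 1] <- w_agree
    contrib[!miss & sim == 0] <- w_disagree
  }
  contrib
}

#' Compare candidate pairs field by field and score them
#'
#' Bloom-encoded fields are compared with the Sorensen-Dice coefficient;
#' token fields by exact equality. Each field contributes a Fellegi-Sunter
#' log2 weight: `w_agree` on full agreement, `w_disagree` on disagreement,
#' 0 when either value is missing, and — for Bloom fields — a linear
#' interpolation between `w_disagree` and `w_agree` for Dice similarity
#' between the field's `partial_floor` and 1. The total score is the sum of
#' the per-field contributions. The comparison is symmetric in the two
#' records of a pair.
#'
#' @param candidates Tibble from [build_candidates()].
#' @param encoded Pooled encoded tibble containing every record referenced
#'   by `candidates` (e.g. `dplyr::bind_rows(enc_a, enc_b)`).
#' @param weights A [match_weights()] table covering every configured field.
#' @param config The [encoding_config()].
#' @return `candidates` with one `sim_<field>` column per field (`NA` =
#'   not comparable) and a `score` column.
#' @export
compare_pairs <- function(candidates, encoded, weights, config) {
  stopifnot(inherits(weights, "match_weights"), inherits(config, "encoding_config"))
  fields <- c(config$bloom_fields, config$hash_fields)
  missing_w <- setdiff(fields, weights$field)
  if (length(missing_w) > 0L) {
    stop("no match weights for field(s): ", paste(missing_w, collapse = ", "),
      call. = FALSE
    )
  }
  ia <- match(candidates$id_a, encoded$record_id)
  ib <- match(candidates$id_b, encoded$record_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("candidate pair references a record id absent from `encoded`",
      call. = FALSE
    )
  }
  out <- candidates
  score <- numeric(nrow(candidates))
  z <- zero_hex(config$bloom_length)
  for (f in fields) {
    wrow <- weights[weights$field == f, ]
    bloom <- f %in% config$bloom_fields
    if (bloom) {
      va <- encoded[[f]][ia]
      vb <- encoded[[f]][ib]
      # unpack only the distinct filters involved
      uh <- unique(c(va, vb))
      words <- hex_to_words(uh, config$bloom_length)
      sim <- dice_words(
        words[match(va, uh), , drop = FALSE],
        words[match(vb, uh), , drop = FALSE]
      )
    } else {
      va <- encoded[[f]][ia]
      vb <- encoded[[f]][ib]
      sim <- ifelse(is.na(va) | is.na(vb), NA_real_,
        as.numeric(va == vb)
      )
    }
    out[[paste0("sim_", f)]] <- sim
    score <- score + weight_contribution(
      sim, wrow$w_agree, wrow$w_disagree, wrow$partial_floor, bloom
    )
  }
  out$score <- score
  out
}

#' Accept or reject scored pairs at a threshold
#'
#' A pair is accepted as a link when its total score is greater than or
#' equal to the threshold (inclusive boundary). Raising the threshold never
#' adds accepted pairs.
#'
#' @param scored Tibble from [compare_pairs()].
#' @param threshold Acceptance threshold on the total score (default 20).
#' @return `scored` with a logical `accepted` column.
#' @export
classify_pairs <- function(scored, threshold = 20) {
  scored$accepted <- scored$score >= threshold
  scored
}

#' Sample pairs within a score band for manual pattern review
#'
#' Threshold setting in a blinded linkage is done by inspecting the
#' *pattern* of per-field agreement of pairs scoring near candidate
#' thresholds — no identifier content is available or shown. Returns a
#' reproducible uniform sample of pairs with `low <= score < high`,
#' carrying only ids, per-field similarities and the score.
#'
#' @param scored Tibble from [compare_pairs()].
#' @param low,high Score band (inclusive low, exclusive high).
#' @param n Maximum sample size; the whole band is returned when smaller.
#' @param seed Integer seed making the sample reproducible.
#' @return A tibble of sampled pairs.
#' @export
sample_score_band <- function(scored, low, high, n, seed = 1L) {
  band <- dplyr::filter(scored, .data$score >= low, .data$score < high)
  keep <- c(
    "id_a", "id_b", "block_pass",
    grep("^sim_", names(band), value = TRUE), "score"
  )
  band <- band[, intersect(keep, names(band))]
  if (nrow(band) <= n) {
    return(band)
  }
  withr::with_seed(seed, dplyr::slice_sample(band, n = n))
}

#' Block, compare and classify two encoded datasets
#'
#' Convenience wrapper running [build_candidates()], [compare_pairs()] and
#' [classify_pairs()] in sequence.
#'
#' @inheritParams build_candidates
#' @inheritParams compare_pairs
#' @inheritParams classify_pairs
#' @return Scored, classified pair tibble.
#' @export
link_encoded <- function(enc_a, enc_b, weights, config, threshold = 20) {
  pool <- if (is.null(enc_b)) enc_a else dplyr::bind_rows(enc_a, enc_b)
  cands <- build_candidates(enc_a, enc_b)
  classify_pairs(compare_pairs(cands, pool, weights, config), threshold)
}
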