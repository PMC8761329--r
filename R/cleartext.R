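# Clear-text baseline linker.
#
# A deliberately simple un-encoded probabilistic linker used as the
# comparator for the privacy-preserving pipeline: the same blocking recipes
# and Fellegi-Sunter weights, with bigram-set Dice in place of Bloom-filter
# Dice for the approximate fields, exact equality for the token fields, and
# one inversion comparison (first name and surname swapped, keeping the
# better-scoring orientation). Bespoke production linkage engines add many
# per-block rules; this baseline keeps only what the evaluation needs.

cleartext_field_sims <- function(cands, clean, ia, ib, fields, bloom_fields,
                                 swap = FALSE) {
  sims <- list()
  for (f in fields) {
    fa <- f
    fb <- f
    if (swap && f %in% c("given1", "surname")) {
      fb <- if (f == "given1") "surname" else "given1"
    }
    va <- clean[[fa]][ia]
    vb <- clean[[fb]][ib]
    if (f %in% bloom_fields) {
      # cache distinct value pairs: the same name pair recurs across records
      pk <- paste(va, vb, sep = "\r")
      up <- !duplicated(pk)
      usim <- bigram_dice(va[up], vb[up])
      # values too short for a bigram are missing, matching the encoded side
      # (a one-character name encodes to the empty Bloom filter)
      sim <- usim[match(pk, pk[up])]
    } else {
      sim <- ifelse(!nzchar(va) | !nzchar(vb), NA_real_, as.numeric(va == vb))
    }
    sims[[f]] <- sim
  }
  sims
}

score_from_sims <- function(sims, weights, bloom_fields) {
  total <- numeric(length(sims[[1]]))
  for (f in names(sims)) {
    wrow <- weights[weights$field == f, ]
    total <- total + weight_contribution(
      sims[[f]], wrow$w_agree, wrow$w_disagree, wrow$partial_floor,
      bloom = f %in% bloom_fields
    )
  }
  total
}

#' Compare candidate pairs on clear-text records
#'
#' The clear-text analogue of [compare_pairs()]: Bloom-field analogues are
#' compared with bigram-set Dice on the cleaned values, token-field
#' analogues by exact equality, with identical weighting. Each pair is
#' additionally evaluated with first given name and surname swapped between
#' the records, and the orientation with the higher total score is kept
#' (inversion comparison for name-order errors).
#'
#' @param candidates Tibble `id_a`, `id_b` (from [build_candidates()]).
#' @param records Pooled clear-text record tibble covering all referenced
#'   ids.
#' @param weights A [match_weights()] table.
#' @param config The [encoding_config()] (field schema and cleaning rules).
#' @return `candidates` plus `sim_<field>` columns, `score`, and a logical
#'   `name_swapped` marking pairs scored in the swapped orientation.
#' @export
cleartext_compare_pairs <- function(candidates, records, weights, config) {
  stopifnot(inherits(weights, "match_weights"), inherits(config, "encoding_config"))
  clean <- preprocess_records(records, config)
  ia <- match(candidates$id_a, records$record_id)
  ib <- match(candidates$id_b, records$record_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("candidate pair references a record id absent from `records`",
      call. = FALSE
    )
  }
  fields <- c(config$bloom_fields, config$hash_fields)
  sims <- cleartext_field_sims(candidates, clean, ia, ib, fields, config$bloom_fields)
  sims_sw <- cleartext_field_sims(candidates, clean, ia, ib, fields,
    config$bloom_fields,
    swap = TRUE
  )
  sc <- score_from_sims(sims, weights, config$bloom_fields)
  sc_sw <- score_from_sims(sims_sw, weights, config$bloom_fields)
  use_swap <- sc_sw > sc
  out <- candidates
  for (f in fields) {
    s <- sims[[f]]
    s[use_swap] <- sims_sw[[f]][use_swap]
    out[[paste0("sim_", f)]] <- s
  }
  out$score <- pmax(sc, sc_sw)
  out$name_swapped <- use_swap
  out
}

#' Link two clear-text datasets end to end
#'
#' Runs the full baseline pipeline — blocking (identical recipes and key
#' derivation to the encoded side, so candidate sets match by
#' construction), clear-text comparison, threshold classification and
#' transitive-closure grouping. No post-linkage quality assurance is
#' applied: the baseline accepts all automated links.
#'
#' @param ds_a,ds_b Clear-text record tibbles (`ds_b` may be `NULL`).
#' @param weights A [match_weights()] table.
#' @param config The [encoding_config()].
#' @param threshold Acceptance threshold (default 20).
#' @return A `linkage_result` object (see [pprl_pipeline()]) with elements
#'   `pairs` and `groups`.
#' @export
cleartext_link <- function(ds_a, ds_b, weights, config, threshold = 20) {
  pool <- if (is.null(ds_b)) ds_a else dplyr::bind_rows(ds_a, ds_b)
  keyed <- tibble::tibble(
    record_id = as.character(pool$record_id),
    dataset = as.character(pool$dataset),
    block_keys = derive_blocking_keys(pool, config)
  )
  cands <- build_candidates(keyed, NULL)
  scored <- classify_pairs(
    cleartext_compare_pairs(cands, pool, weights, config),
    threshold
  )
  groups <- build_groups(
    scored[scored$accepted, c("id_a", "id_b")],
    keyed[, c("record_id", "dataset")]
  )
  new_linkage_result(
    pairs = scored, groups = groups, threshold = threshold,
    method = "cleartext", config = config
  )
}
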