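new_linkage_result <- function(pairs, groups, threshold, method, config,
                               validation = NULL, placeholders = NULL,
                               qa = NULL) {
  structure(
    list(
      pairs = pairs, groups = groups, threshold = threshold,
      method = method, config = config,
      validation = validation, placeholders = placeholders, qa = qa
    ),
    class = c(paste0(method, "_linkage"), "linkage_result")
  )
}

#' @export
print.linkage_result <- function(x, ...) {
  acc <- sum(x$pairs$accepted)
  multi <- sum(table(x$groups$group_id) > 1L)
  cat(
    "<", class(x)[1], "> ", nrow(x$groups), " records, ",
    nrow(x$pairs), " candidate pairs, ", acc, " accepted (threshold ",
    x$threshold, "), ", multi, " multi-record groups\n",
    sep = ""
  )
  invisible(x)
}

#' Run the full privacy-preserving linkage pipeline
#'
#' End-to-end encoded linkage of two clear-text datasets, the way the two
#' parties would run it: each dataset is encoded (custodian side) with the
#' shared key, the encoded files are validated (record counts, frequency
#' profiles, cross-encoding consistency), placeholder address/postcode
#' values are detected and blanked, candidate pairs are generated by
#' blocking, compared and scored on the encoded identifiers, accepted at
#' the threshold, grouped by transitive closure, and — optionally — put
#' through post-linkage quality assurance (twin splitting, multiple-death
#' separation).
#'
#' @param ds_a,ds_b Clear-text record tibbles (typically morbidity and
#'   mortality extracts); `ds_b` may be `NULL`.
#' @param config An [encoding_config()] (carries the shared secret key).
#' @param weights A [match_weights()] table; defaults to
#'   [default_weights()].
#' @param threshold Acceptance threshold on the pair score (default 20).
#' @param qa `TRUE` to apply post-linkage quality assurance.
#' @param qa_parameters A [qa_params()] object.
#' @param placeholder_multiplier Frequency multiplier for
#'   [detect_placeholders()]; `NULL` disables placeholder screening.
#' @return A `linkage_result` with elements `pairs` (scored pairs),
#'   `groups`, `validation` (per-dataset profiles and the cross-encoding
#'   verdicts), `placeholders` (flagged values) and `qa` (QA provenance,
#'   when applied).
#' @examples
#' \donttest{
#' synth <- synthesize_linkage_data(synth_config(n_persons = 150, seed = 7))
#' cfg <- encoding_config(key = "shared-secret")
#' res <- pprl_pipeline(synth$morbidity, synth$mortality, cfg)
#' res
#' }
#' @export
pprl_pipeline <- function(ds_a, ds_b, config,
                          weights = default_weights(),
                          threshold = 20,
                          qa = TRUE,
                          qa_parameters = qa_params(),
                          placeholder_multiplier = 10) {
  enc_a <- encode_records(ds_a, config)
  enc_b <- if (!is.null(ds_b)) encode_records(ds_b, config)
  rep_a <- profile_dataset(enc_a, config)
  rep_b <- if (!is.null(enc_b)) profile_dataset(enc_b, config)
  cross <- if (!is.null(rep_b)) check_cross_encoding(rep_a, rep_b)
  if (!is.null(cross) && any(cross$verdict == "inconsistent")) {
    warning(
      "cross-encoding check failed for field(s): ",
      paste(cross$field[cross$verdict == "inconsistent"], collapse = ", "),
      "; were both files encoded with the same key?",
      call. = FALSE
    )
  }
  flags <- NULL
  if (!is.null(placeholder_multiplier)) {
    pooled_enc <- if (is.null(enc_b)) enc_a else dplyr::bind_rows(enc_a, enc_b)
    pooled_rep <- profile_dataset(pooled_enc, config)
    flags <- detect_placeholders(pooled_rep,
      field = "address",
      multiplier = placeholder_multiplier
    )
    enc_a <- remove_placeholders(enc_a, flags, config)
    if (!is.null(enc_b)) enc_b <- remove_placeholders(enc_b, flags, config)
  }
  scored <- link_encoded(enc_a, enc_b, weights, config, threshold)
  pool <- if (is.null(enc_b)) enc_a else dplyr::bind_rows(enc_a, enc_b)
  groups <- build_groups(
    scored[scored$accepted, c("id_a", "id_b")],
    pool[, c("record_id", "dataset")]
  )
  qa_info <- NULL
  if (qa) {
    groups <- apply_group_qa(groups, scored, qa_parameters)
    qa_info <- attr(groups, "qa")
  }
  new_linkage_result(
    pairs = scored, groups = groups, threshold = threshold,
    method = "pprl", config = config,
    validation = list(a = rep_a, b = rep_b, cross_encoding = cross),
    placeholders = flags, qa = qa_info
  )
}

#' Run the clear-text baseline pipeline
#'
#' The comparator for [pprl_pipeline()]: identical blocking and weights on
#' un-encoded records, with clear-side placeholder screening (the same
#' frequency and association rules applied to the cleaned clear values) and
#' no post-linkage quality assurance.
#'
#' @inheritParams pprl_pipeline
#' @return A `linkage_result`.
#' @export
cleartext_pipeline <- function(ds_a, ds_b, config,
                               weights = default_weights(),
                               threshold = 20,
                               placeholder_multiplier = 10) {
  pool <- if (is.null(ds_b)) ds_a else dplyr::bind_rows(ds_a, ds_b)
  if (!is.null(placeholder_multiplier)) {
    pool <- blank_clear_placeholders(pool, config, placeholder_multiplier)
  }
  res <- cleartext_link(pool, NULL, weights, config, threshold)
  res
}

# Clear-side analogue of encoded placeholder screening: identical rule
# (count > multiplier x median of the top-20 value counts, plus the >= 90%
# postcode association rule) applied to cleaned clear values. Because a
# clear value and its encoding are in bijection under a fixed key, this
# blanks exactly the records the encoded side blanks.
blank_clear_placeholders <- function(pool, config, multiplier, assoc = 0.9) {
  clean <- preprocess_records(pool, config)
  addr <- clean$address
  fr <- sort(table(addr[nzchar(addr)]), decreasing = TRUE)
  if (length(fr) == 0L) {
    return(pool)
  }
  med_top <- stats::median(utils::head(as.integer(fr), 20L))
  flagged_addr <- names(fr)[as.integer(fr) > multiplier * med_top]
  if (length(flagged_addr) == 0L) {
    return(pool)
  }
  pc <- clean$postcode
  both <- nzchar(addr) & nzchar(pc)
  with_flag <- table(pc[both & addr %in% flagged_addr])
  tot <- table(pc[nzchar(pc)])
  prop <- as.integer(with_flag) / as.integer(tot[names(with_flag)])
  flagged_pc <- names(with_flag)[prop >= assoc]
  pool$address[addr %in% flagged_addr] <- ""
  pool$postcode[pc %in% flagged_pc] <- ""
  pool
}
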