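#' Encoding configuration for privacy-preserving linkage
#'
#' Bundles every parameter that both data custodians must share for their
#' encodings to be comparable: the Bloom filter length, the per-field number
#' of hash functions per bigram, the secret HMAC key, the split of fields
#' into Bloom-encoded and token-encoded, and the clear-side blocking recipes.
#'
#' Defaults follow common operational practice for field-level Bloom filter
#' linkage of names and addresses: 512-bit filters with 30 hashes per bigram
#' for name fields, 20 for address and 25 for suburb (fewer hashes for the
#' longer fields), inputs truncated to their first 20 characters after
#' cleaning.
#'
#' @param key Secret key string shared by the two encoding parties. Required;
#'   all HMAC-SHA-256 digests (bit positions, tokens, blocking keys) depend
#'   on it.
#' @param bloom_length Bloom filter length in bits. Must be a positive
#'   multiple of 16 (filters are stored as 16-bit words / 4-hex-char groups).
#' @param hashes_per_bigram Named integer vector mapping each Bloom field to
#'   its number of hash functions per bigram.
#' @param max_chars Identifier values are truncated to this many characters
#'   after cleaning, before bigram extraction or token hashing.
#' @param bloom_fields Character vector of fields encoded as Bloom filters.
#' @param hash_fields Character vector of fields encoded as single keyed hash
#'   tokens.
#' @param blocking List of blocking passes, each created by [block_on()].
#'
#' @return An object of class `encoding_config`.
#' @seealso [block_on()], [encode_records()]
#' @examples
#' cfg <- encoding_config(key = "example-secret")
#' cfg$bloom_length
#' @export
encoding_config <- function(key,
                            bloom_length = 512L,
                            hashes_per_bigram = c(
                              given1 = 30L, given2 = 30L, given3 = 30L,
                              surname = 30L, address = 20L, suburb = 25L
                            ),
                            max_chars = 20L,
                            bloom_fields = c(
                              "given1", "given2", "given3",
                              "surname", "address", "suburb"
                            ),
                            hash_fields = c("sex", "dob", "postcode"),
                            blocking = default_blocking()) {
  if (missing(key) || is.null(key) || !nzchar(key)) {
    stop("`key` must be a non-empty secret string", call. = FALSE)
  }
  bloom_length <- as.integer(bloom_length)
  if (bloom_length <= 0L || bloom_length %% 16L != 0L) {
    stop("`bloom_length` must be a positive multiple of 16", call. = FALSE)
  }
  if (any(hashes_per_bigram < 1L)) {
    stop("every `hashes_per_bigram` count must be >= 1", call. = FALSE)
  }
  if (length(intersect(bloom_fields, hash_fields)) > 0L) {
    stop("a field cannot be in both `bloom_fields` and `hash_fields`",
      call. = FALSE
    )
  }
  missing_k <- setdiff(bloom_fields, names(hashes_per_bigram))
  if (length(missing_k) > 0L) {
    stop(
      "no `hashes_per_bigram` entry for field(s): ",
      paste(missing_k, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      key = key,
      bloom_length = bloom_length,
      hashes_per_bigram = vapply(hashes_per_bigram, as.integer, integer(1)),
      max_chars = as.integer(max_chars),
      bloom_fields = bloom_fields,
      hash_fields = hash_fields,
      blocking = blocking
    ),
    class = "encoding_config"
  )
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("<encoding_config>\n")
  cat("  bloom_length:", x$bloom_length, "bits\n")
  cat(
    "  bloom fields:",
    paste(sprintf("%s(k=%d)", x$bloom_fields, x$hashes_per_bigram[x$bloom_fields]),
      collapse = ", "
    ), "\n"
  )
  cat("  hash fields: ", paste(x$hash_fields, collapse = ", "), "\n")
  cat("  max_chars:   ", x$max_chars, "\n")
  cat(
    "  blocking:    ",
    paste(vapply(x$blocking, function(p) p$name, character(1)), collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' Define a blocking pass
#'
#' A blocking pass names the field fragments whose concatenation forms a
#' blocking key; only record pairs sharing a key in at least one pass are
#' compared. Keys are computed clear-side (before encoding) and shipped as
#' keyed hash tokens, because Bloom-encoded fields cannot be blocked on
#' directly. Components use a small fragment syntax:
#'
#' * `"surname"` — the whole cleaned field;
#' * `"surname[1:2]"` — characters 1-2 of the cleaned field;
#' * `"dob[year]"` — the year part of the date of birth.
#'
#' A record whose recipe has any missing component emits no key for that
#' pass.
#'
#' @param ... Component strings, concatenated in order.
#' @param name Optional pass label (defaults to the components joined by
#'   `+`); carried through to candidate-pair provenance.
#' @return A `blocking_pass` object.
#' @examples
#' block_on("surname[1:2]", "dob[year]")
#' @export
block_on <- function(..., name = NULL) {
  comps <- unlist(list(...), use.names = FALSE)
  if (length(comps) == 0L) stop("a blocking pass needs >= 1 component", call. = FALSE)
  parsed <- lapply(comps, parse_block_component)
  if (is.null(name)) name <- paste(comps, collapse = "+")
  structure(list(name = name, components = parsed), class = "blocking_pass")
}

parse_block_component <- function(spec) {
  m <- regmatches(spec, regexec("^([A-Za-z0-9_]+)(\\[(.+)\\])?$", spec))[[1]]
  if (length(m) == 0L) stop("cannot parse blocking component: ", spec, call. = FALSE)
  field <- m[2]
  part <- m[4]
  if (is.na(part) || part == "") {
    list(field = field, kind = "whole")
  } else if (part == "year") {
    list(field = field, kind = "year")
  } else if (grepl("^[0-9]+:[0-9]+$", part)) {
    rng <- as.integer(strsplit(part, ":")[[1]])
    list(field = field, kind = "substr", from = rng[1], to = rng[2])
  } else {
    stop("unknown fragment '", part, "' in blocking component: ", spec, call. = FALSE)
  }
}

#' Default blocking strategy
#'
#' Three passes that together give near-complete coverage of true pairs in
#' person-level data while keeping blocks small: full date of birth;
#' first two letters of surname plus year of birth; first two letters of the
#' first given name plus year of birth and sex. Operational blocking keys
#' are custodian-specific; these defaults are fully replaceable via
#' [encoding_config()].
#'
#' @return List of [block_on()] passes.
#' @export
default_blocking <- function() {
  list(
    block_on("dob", name = "dob"),
    block_on("surname[1:2]", "dob[year]", name = "sn2+yob"),
    block_on("given1[1:2]", "dob[year]", "sex", name = "gn2+yob+sex")
  )
}

#' Fellegi-Sunter match weights
#'
#' Per-field m-probabilities (chance that a true match agrees on the field)
#' and u-probabilities (chance that a random non-match agrees), from which
#' the log2 agreement and disagreement weights are derived:
#' `w_agree = log2(m/u)` and `w_disagree = log2((1-m)/(1-u))`. For
#' Bloom-encoded fields, Dice similarity between `partial_floor` and 1 is
#' mapped linearly between `w_disagree` and `w_agree`; below the floor the
#' comparison counts as full disagreement. Missing fields contribute 0.
#'
#' @param weights Data frame with columns `field`, `m`, `u` and optionally
#'   `partial_floor` (default 0.7, used for Bloom fields only).
#' @return A tibble of class `match_weights` with derived columns `w_agree`
#'   and `w_disagree`.
#' @examples
#' match_weights(data.frame(field = "surname", m = 0.95, u = 0.01))
#' @export
match_weights <- function(weights) {
  w <- tibble::as_tibble(weights)
  stopifnot(all(c("field", "m", "u") %in% names(w)))
  if (!"partial_floor" %in% names(w)) w$partial_floor <- 0.7
  if (any(!(w$u > 0 & w$u < w$m & w$m < 1))) {
    stop("match weights require 0 < u < m < 1 for every field", call. = FALSE)
  }
  w$w_agree <- log2(w$m / w$u)
  w$w_disagree <- log2((1 - w$m) / (1 - w$u))
  class(w) <- c("match_weights", class(w))
  w
}

#' Default match weights
#'
#' A plausible default m/u set for population-level morbidity/mortality
#' linkage; operational weight tables are developed per-collection and
#' these defaults are meant to be overridden. With these values a pair
#' agreeing on first name, surname, sex, date of birth, address, suburb and
#' postcode scores about 44, and a male-female twin pattern (everything but
#' first name and sex agreeing) about 28 — both above the default acceptance
#' threshold of 20, so twins are deliberately left to post-linkage quality
#' assurance, as in operational practice.
#'
#' @return A `match_weights` tibble covering the default field schema.
#' @export
default_weights <- function() {
  match_weights(tibble::tribble(
    ~field,     ~m,   ~u,
    "given1",   0.95, 0.010,
    "given2",   0.90, 0.010,
    "given3",   0.85, 0.020,
    "surname",  0.96, 0.010,
    "sex",      0.98, 0.500,
    "dob",      0.99, 0.0005,
    "address",  0.90, 0.002,
    "suburb",   0.93, 0.030,
    "postcode", 0.94, 0.020
  ))
}

#' Post-linkage quality-assurance parameters
#'
#' @param low_weight_band Numeric length-2: groups containing an internal
#'   pair scoring within `[low, high)` are flagged for review.
#' @param large_group Groups with more than this many members are flagged.
#' @param twin_name_ceiling Given-name Dice similarity below which a pair
#'   otherwise agreeing on surname, date of birth and full address, but
#'   disagreeing on sex, is treated as a male-female twin pattern.
#' @return A list of class `qa_params`.
#' @export
qa_params <- function(low_weight_band = c(20, 22),
                      large_group = 10L,
                      twin_name_ceiling = 0.8) {
  structure(
    list(
      low_weight_band = as.numeric(low_weight_band),
      large_group = as.integer(large_group),
      twin_name_ceiling = twin_name_ceiling
    ),
    class = "qa_params"
  )
}
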