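#' Encode cleaned strings into field-level Bloom filters
#'
#' Each distinct unpadded bigram of the (already cleaned) input is hashed
#' `k` times with HMAC-SHA-256 under the shared secret key — `k` set per
#' field in the configuration — and the resulting bit positions are set in a
#' filter of `bloom_length` bits. The field label is part of every HMAC
#' message, so identical values in different fields produce unrelated
#' filters. Empty input encodes to the all-zero filter (missing).
#'
#' @param values Character vector of cleaned strings (see
#'   [preprocess_field()]); encoding does not re-clean.
#' @param field Field label; must be one of `config$bloom_fields`.
#' @param config An [encoding_config()].
#' @return Character vector of hex-encoded filters
#'   (`bloom_length / 4` hex characters, most-significant bit first).
#' @examples
#' cfg <- encoding_config(key = "k")
#' substr(bloom_encode("smith", "surname", cfg), 1, 16)
#' @export
bloom_encode <- function(values, field, config) {
  stopifnot(inherits(config, "encoding_config"))
  if (!field %in% config$bloom_fields) {
    stop("`", field, "` is not a Bloom-encoded field", call. = FALSE)
  }
  values <- as.character(values)
  values[is.na(values)] <- ""
  uv <- unique(values)
  grams <- extract_bigrams(uv)
  pos_map <- bigram_bit_positions(unique(unlist(grams)), field, config)
  z <- zero_hex(config$bloom_length)
  uhex <- vapply(grams, function(g) {
    if (length(g) == 0L) {
      return(z)
    }
    positions_to_hex(unlist(pos_map[g], use.names = FALSE), config$bloom_length)
  }, character(1))
  uhex[match(values, uv)]
}

#' Encode exact-match fields as keyed hash tokens
#'
#' Fields compared for exact equality (sex, date of birth, postcode) are
#' encoded as the full HMAC-SHA-256 hex digest of `field|value` under the
#' shared key: token equality then holds exactly when the normalised clear
#' values are equal under the same key. Missing input yields `NA`.
#'
#' @inheritParams bloom_encode
#' @param values Character vector of normalised values (dates as `yyyymmdd`).
#' @return Character vector of 64-character hex tokens, `NA` for missing.
#' @export
hash_encode <- function(values, field, config) {
  stopifnot(inherits(config, "encoding_config"))
  if (!field %in% config$hash_fields) {
    stop("`", field, "` is not a token-encoded field", call. = FALSE)
  }
  values <- as.character(values)
  values[is.na(values)] <- ""
  out <- rep(NA_character_, length(values))
  nz <- which(nzchar(values))
  if (length(nz) > 0L) {
    uv <- unique(values[nz])
    uh <- hmac_hex(paste0(field, "|", uv), config$key)
    out[nz] <- uh[match(values[nz], uv)]
  }
  out
}

block_component_value <- function(comp, rec_clean) {
  f <- comp$field
  if (!f %in% names(rec_clean)) {
    stop("blocking recipe refers to unknown field `", f, "`", call. = FALSE)
  }
  v <- rec_clean[[f]]
  switch(comp$kind,
    whole = v,
    substr = {
      out <- substr(v, comp$from, comp$to)
      # a fragment shorter than requested counts as missing
      out[nchar(out) < (comp$to - comp$from + 1L)] <- ""
      out
    },
    year = substr(v, 1L, 4L)
  )
}

#' Derive hashed blocking keys from clear-text records
#'
#' Evaluates every configured blocking pass on the cleaned record fields and
#' hash-encodes each resulting key string as
#' `HMAC-SHA-256(key, block|pass|value)`. This runs clear-side, at the data
#' source, because Bloom-encoded fields cannot be blocked on; only the
#' hashed keys leave the custodian. A pass with any missing component emits
#' no key for that record.
#'
#' @param df Data frame of clear-text records (one row per record).
#' @param config An [encoding_config()]; `config$blocking` supplies the
#'   passes.
#' @return A character vector (one element per row) of
#'   `pass|token` entries joined by `";"`; `""` when no pass fires.
#' @export
derive_blocking_keys <- function(df, config) {
  stopifnot(inherits(config, "encoding_config"))
  clean <- preprocess_records(df, config)
  n <- nrow(df)
  per_pass <- lapply(config$blocking, function(pass) {
    frags <- lapply(pass$components, block_component_value, rec_clean = clean)
    ok <- Reduce(`&`, lapply(frags, nzchar))
    keyval <- do.call(paste0, frags)
    out <- rep(NA_character_, n)
    if (any(ok)) {
      uv <- unique(keyval[ok])
      uh <- hmac_hex(paste0("block|", pass$name, "|", uv), config$key)
      out[ok] <- paste0(pass$name, "|", uh[match(keyval[ok], uv)])
    }
    out
  })
  mat <- do.call(cbind, per_pass)
  apply(mat, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
}

#' Encode a clear-text dataset for privacy-preserving linkage
#'
#' The custodian-side encoder: cleans every identifier, Bloom-encodes the
#' name/address/suburb fields, token-encodes the exact-match fields, derives
#' hashed blocking keys, and returns a table that contains no clear-text
#' identifier material. Encoding is fully deterministic for a fixed key and
#' configuration.
#'
#' @param df Data frame with columns `record_id`, `dataset`, and every field
#'   named in the configuration. Missing values may be `NA` or `""`.
#' @param config An [encoding_config()].
#' @return A tibble with columns `record_id`, `dataset`, one hex Bloom
#'   column per Bloom field, one token column per hash field (`NA` =
#'   missing) and `block_keys`. The encoding report (record count and
#'   per-field missingness) is attached as attribute `"report"`; see
#'   [encoding_report()].
#' @examples
#' cfg <- encoding_config(key = "k")
#' df <- data.frame(
#'   record_id = "r1", dataset = "morbidity",
#'   given1 = "Mary", given2 = "", given3 = "", surname = "Smith",
#'   sex = "F", dob = as.Date("1950-03-02"),
#'   address = "12 John St", suburb = "Perth", postcode = "6000"
#' )
#' enc <- encode_records(df, cfg)
#' names(enc)
#' @export
encode_records <- function(df, config) {
  stopifnot(inherits(config, "encoding_config"))
  req <- c("record_id", "dataset", config$bloom_fields, config$hash_fields)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("input is missing required field(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$record_id)) {
    stop("`record_id` must be unique within a dataset", call. = FALSE)
  }
  clean <- preprocess_records(df, config)
  out <- tibble::tibble(
    record_id = as.character(df$record_id),
    dataset = as.character(df$dataset)
  )
  n_missing <- integer(0)
  for (f in config$bloom_fields) {
    out[[f]] <- bloom_encode(clean[[f]], f, config)
    n_missing[f] <- sum(!nzchar(clean[[f]]))
  }
  for (f in config$hash_fields) {
    out[[f]] <- hash_encode(clean[[f]], f, config)
    n_missing[f] <- sum(!nzchar(clean[[f]]))
  }
  out$block_keys <- derive_blocking_keys(df, config)
  report <- tibble::tibble(
    field = names(n_missing),
    n_missing = unname(n_missing),
    missing_rate = unname(n_missing) / max(nrow(df), 1L)
  )
  attr(out, "report") <- list(record_count = nrow(df), missingness = report)
  out
}

#' Retrieve the encoding report of an encoded dataset
#'
#' @param encoded A tibble returned by [encode_records()].
#' @return A list with `record_count` and a `missingness` tibble.
#' @export
encoding_report <- function(encoded) {
  rep <- attr(encoded, "report")
  if (is.null(rep)) stop("no encoding report attached", call. = FALSE)
  rep
}

#' Read and write encoded-record files
#'
#' The on-disk dialect is a plain CSV with header: `record_id`, `dataset`,
#' one hex column per Bloom field (`bloom_length / 4` hex characters,
#' most-significant bit first), one hex token column per hash field (empty =
#' missing), and `block_keys` (semicolon-joined `pass|token` entries). The
#' round trip through [write_encoded()] / [read_encoded()] is lossless.
#'
#' @param encoded Encoded tibble from [encode_records()].
#' @param path File path.
#' @return `read_encoded()` returns the encoded tibble;
#'   `write_encoded()` returns `path` invisibly.
#' @export
write_encoded <- function(encoded, path) {
  readr::write_csv(encoded, path, na = "")
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  for (col in setdiff(names(out), c("record_id", "dataset", "block_keys"))) {
    out[[col]][out[[col]] == ""] <- NA_character_
  }
  out
}
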