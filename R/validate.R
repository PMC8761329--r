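#' Profile an encoded dataset before linkage
#'
#' Pre-linkage validation works only with what the linkage unit can see:
#' counts, per-field missingness, frequency tables of encoded values, and
#' Bloom filter cardinality histograms. Identical clear values encode to
#' identical filters/tokens, so frequency structure (and anomalies such as
#' placeholder values) survives encoding.
#'
#' @param encoded Encoded tibble (from [encode_records()] or
#'   [read_encoded()]).
#' @param config The [encoding_config()] used for encoding.
#' @param companions Named character vector declaring, for selected fields,
#'   a companion field whose values are cross-tabulated against them
#'   (used by the placeholder association rule). Default: postcode against
#'   address.
#' @return A list of class `validation_report`: `record_count`, `fields`,
#'   `missingness`, per-field `frequencies` (value/token counts, descending),
#'   `cardinality` histograms for Bloom fields, and `cooccurrence` tibbles.
#' @export
profile_dataset <- function(encoded, config,
                            companions = c(address = "postcode")) {
  stopifnot(inherits(config, "encoding_config"))
  fields <- c(config$bloom_fields, config$hash_fields)
  miss <- setdiff(c("record_id", "dataset", fields), names(encoded))
  if (length(miss) > 0L) {
    stop("encoded data is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  z <- zero_hex(config$bloom_length)
  present <- function(f) {
    v <- encoded[[f]]
    if (f %in% config$bloom_fields) !is.na(v) & v != z else !is.na(v)
  }
  freqs <- lapply(fields, function(f) {
    v <- encoded[[f]][present(f)]
    if (length(v) == 0L) {
      return(tibble::tibble(value = character(0), n = integer(0)))
    }
    tb <- sort(table(v), decreasing = TRUE)
    tibble::tibble(value = names(tb), n = as.integer(tb))
  })
  names(freqs) <- fields
  card <- lapply(config$bloom_fields, function(f) {
    w <- hex_to_words(encoded[[f]], config$bloom_length)
    tb <- table(words_cardinality(w))
    tibble::tibble(cardinality = as.integer(names(tb)), n = as.integer(tb))
  })
  names(card) <- config$bloom_fields
  cooc <- lapply(names(companions), function(f) {
    g <- companions[[f]]
    keep <- present(f) & present(g)
    dplyr::count(
      tibble::tibble(value = encoded[[f]][keep], companion = encoded[[g]][keep]),
      .data$value, .data$companion,
      name = "n"
    )
  })
  names(cooc) <- names(companions)
  structure(
    list(
      record_count = nrow(encoded),
      fields = fields,
      missingness = {
        npres <- vapply(fields, function(f) sum(present(f)),
          integer(1),
          USE.NAMES = FALSE
        )
        tibble::tibble(
          field = fields,
          n_present = npres,
          n_missing = nrow(encoded) - npres
        )
      },
      frequencies = freqs,
      cardinality = card,
      cooccurrence = cooc,
      companions = companions
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$record_count, "records,",
    length(x$fields), "identifier fields\n"
  )
  print(x$missingness)
  invisible(x)
}

#' Check that two encoded datasets share the same encoding
#'
#' The existence of identical encoded values across the two files for a
#' field is taken as evidence that the same key and configuration were used
#' on both sides: real populations share names, dates of birth and
#' postcodes, so a correct joint encoding always produces overlap, while a
#' key mismatch makes overlap (HMAC collision) essentially impossible. A
#' field with no usable values on either side is `indeterminate`, not
#' inconsistent.
#'
#' @param report_a,report_b [profile_dataset()] reports for the two files.
#' @return A tibble with columns `field`, `overlap` (count of shared encoded
#'   values) and `verdict` (`"consistent"`, `"inconsistent"`,
#'   `"indeterminate"`).
#' @export
check_cross_encoding <- function(report_a, report_b) {
  stopifnot(
    inherits(report_a, "validation_report"),
    inherits(report_b, "validation_report")
  )
  if (!identical(report_a$fields, report_b$fields)) {
    stop("field lists differ between the two reports", call. = FALSE)
  }
  purrr::map_dfr(report_a$fields, function(f) {
    va <- report_a$frequencies[[f]]$value
    vb <- report_b$frequencies[[f]]$value
    ov <- length(intersect(va, vb))
    verdict <- if (length(va) == 0L || length(vb) == 0L) {
      "indeterminate"
    } else if (ov > 0L) "consistent" else "inconsistent"
    tibble::tibble(field = f, overlap = ov, verdict = verdict)
  })
}

#' Detect placeholder ("dummy") values in an encoded field
#'
#' Operational data often contains placeholder identifiers — addresses such
#' as "UNKNOWN" or "NO FIXED ADDRESS", postcodes such as "9999" — which are
#' shared by many unrelated people and must be blanked before linkage.
#' Because identical clear values give identical encodings, placeholders are
#' visible as anomalously frequent encoded values: a value is flagged when
#' its count exceeds `multiplier` times the median count of the field's top
#' 20 values (itself a robust estimate of ordinary repetition). Values of
#' the declared companion field (default postcode, against address) that
#' co-occur with a flagged value in at least `assoc` of their occurrences
#' are flagged as associated dummies.
#'
#' @param report A [profile_dataset()] report.
#' @param field Field to screen (default `"address"`).
#' @param multiplier Frequency multiplier over the top-20 median.
#' @param assoc Minimum co-occurrence proportion for the companion rule.
#' @return A tibble `field`, `value`, `n`, `reason`
#'   (`"frequency"` or `"association"`); zero rows when nothing is flagged.
#' @export
detect_placeholders <- function(report, field = "address",
                                multiplier = 10, assoc = 0.9) {
  stopifnot(inherits(report, "validation_report"))
  fr <- report$frequencies[[field]]
  if (is.null(fr)) stop("unknown field `", field, "`", call. = FALSE)
  if (nrow(fr) == 0L) {
    return(tibble::tibble(
      field = character(0), value = character(0),
      n = integer(0), reason = character(0)
    ))
  }
  med_top <- stats::median(utils::head(fr$n, 20L))
  flagged <- fr[fr$n > multiplier * med_top, , drop = FALSE]
  out <- tibble::tibble(
    field = rep(field, nrow(flagged)),
    value = flagged$value, n = flagged$n, reason = "frequency"
  )
  comp_field <- report$companions[[field]]
  if (nrow(flagged) > 0L && !is.null(comp_field)) {
    cooc <- report$cooccurrence[[field]]
    comp_fr <- report$frequencies[[comp_field]]
    with_flagged <- dplyr::filter(cooc, .data$value %in% flagged$value)
    tot <- stats::setNames(comp_fr$n, comp_fr$value)
    assoc_tbl <- dplyr::summarise(
      dplyr::group_by(with_flagged, .data$companion),
      n_with = sum(.data$n), .groups = "drop"
    )
    assoc_tbl$prop <- assoc_tbl$n_with / tot[assoc_tbl$companion]
    hits <- assoc_tbl[assoc_tbl$prop >= assoc, , drop = FALSE]
    if (nrow(hits) > 0L) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        field = comp_field,
        value = hits$companion,
        n = as.integer(tot[hits$companion]),
        reason = "association"
      ))
    }
  }
  out
}

#' Blank flagged placeholder values in an encoded dataset
#'
#' Flagged values are set to missing (all-zero filter for Bloom fields, `NA`
#' token for hash fields); records are kept, mirroring operational cleaning
#' where values — not people — are removed.
#'
#' @param encoded Encoded tibble.
#' @param flags Tibble from [detect_placeholders()] (or hand-built with
#'   columns `field`, `value`).
#' @param config The [encoding_config()].
#' @return The cleaned encoded tibble, with attribute `"removals"`: a tibble
#'   of per-field blanked-value counts.
#' @export
remove_placeholders <- function(encoded, flags, config) {
  stopifnot(inherits(config, "encoding_config"))
  removed <- tibble::tibble(field = character(0), n_removed = integer(0))
  if (!is.null(flags) && nrow(flags) > 0L) {
    for (f in unique(flags$field)) {
      vals <- flags$value[flags$field == f]
      hit <- !is.na(encoded[[f]]) & encoded[[f]] %in% vals
      encoded[[f]][hit] <- if (f %in% config$bloom_fields) {
        zero_hex(config$bloom_length)
      } else {
        NA_character_
      }
      removed <- dplyr::bind_rows(
        removed,
        tibble::tibble(field = f, n_removed = sum(hit))
      )
    }
  }
  attr(encoded, "removals") <- removed
  encoded
}
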