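#' Clean an identifier value before encoding
#'
#' Lower-cases, removes all whitespace and non-alphanumeric characters, and
#' truncates to the first `max_chars` characters. Both linkage parties must
#' apply identical cleaning or their encodings will not be comparable. An
#' empty result (including `NA` input) means the field is missing.
#'
#' @param x Character vector of raw values.
#' @param max_chars Truncation length applied after cleaning.
#' @return Character vector of cleaned values; `""` marks missing.
#' @examples
#' preprocess_field(c("O'Brien ", "van der Berg", NA))
#' @export
preprocess_field <- function(x, max_chars = 20L) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "", x)
  substr(x, 1L, max_chars)
}

#' Normalise a date of birth to its canonical digit string
#'
#' Dates are hashed as exact tokens, so token equality must coincide with
#' date equality: any parseable input is reduced to `yyyymmdd`. Date objects
#' and ISO-8601 strings are accepted; other strings fall through
#' [preprocess_field()] unchanged (digits kept in order).
#'
#' @param x Date vector or character vector.
#' @return Character vector of `yyyymmdd` strings; `""` marks missing.
#' @export
normalize_dob <- function(x) {
  if (inherits(x, "Date")) {
    out <- format(x, "%Y%m%d")
    out[is.na(out)] <- ""
    return(out)
  }
  x <- as.character(x)
  x[is.na(x)] <- ""
  gsub("[^0-9]", "", x)
}

#' Extract the set of unpadded bigrams from a cleaned string
#'
#' Returns the distinct consecutive two-character substrings, with no
#' boundary padding; strings of length 0 or 1 yield an empty set. Distinct
#' (set, not multiset) bigrams are used because repeated bigrams would set
#' identical filter bits under deterministic hashing.
#'
#' @param s Character vector of cleaned strings.
#' @return A list of character vectors (one bigram set per input string).
#' @examples
#' extract_bigrams("smith")
#' @export
extract_bigrams <- function(s) {
  lapply(as.character(s), function(v) {
    if (is.na(v) || nchar(v) < 2L) {
      return(character(0))
    }
    n <- nchar(v)
    unique(substring(v, 1:(n - 1L), 2:n))
  })
}

# Apply the cleaning appropriate to each field of a clear-text record table.
# dob is digit-normalised; everything else goes through preprocess_field().
preprocess_records <- function(df, config) {
  fields <- c(config$bloom_fields, config$hash_fields)
  out <- df
  for (f in fields) {
    if (!f %in% names(df)) {
      stop("input is missing required field `", f, "`", call. = FALSE)
    }
    out[[f]] <- if (f == "dob") {
      substr(normalize_dob(df[[f]]), 1L, config$max_chars)
    } else {
      preprocess_field(df[[f]], config$max_chars)
    }
  }
  out
}
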