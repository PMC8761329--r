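# Bloom filter bit-level machinery.
#
# Filters are stored at the interface as hex strings (4 hex chars per 16-bit
# word, most-significant bit first: bit b of the filter, 0-based, lives in
# word b %/% 16 at bit value 2^(15 - b %% 16)). Internally they are unpacked
# to integer matrices of 16-bit words so Dice can be vectorised over large
# pair sets with a popcount lookup table.

.bloomlink_env <- new.env(parent = emptyenv())

pop16 <- function() {
  if (is.null(.bloomlink_env$pop16)) {
    i <- 0:65535
    pc <- integer(65536)
    for (b in 0:15) pc <- pc + bitwAnd(bitwShiftR(i, b), 1L)
    .bloomlink_env$pop16 <- pc
  }
  .bloomlink_env$pop16
}

hmac_hex <- function(messages, key) {
  if (length(messages) == 0L) {
    return(character(0))
  }
  as.character(openssl::sha256(messages, key = key))
}

# Bit positions (0-based) for one field's bigrams: the i-th hash of bigram g
# is HMAC-SHA-256(key, field|g|i), taking the first 24 bits of the digest
# modulo the filter length. Returns a named list bigram -> integer positions.
bigram_bit_positions <- function(bigrams, field, config) {
  bigrams <- unique(bigrams)
  if (length(bigrams) == 0L) {
    return(list())
  }
  k <- config$hashes_per_bigram[[field]]
  msgs <- paste0(
    rep(field, length(bigrams) * k), "|",
    rep(bigrams, each = k), "|",
    rep(0:(k - 1L), times = length(bigrams))
  )
  hx <- hmac_hex(msgs, config$key)
  idx <- strtoi(substr(hx, 1L, 6L), 16L) %% config$bloom_length
  split(idx, rep(bigrams, each = k))[bigrams]
}

positions_to_hex <- function(positions, bloom_length) {
  nw <- bloom_length %/% 16L
  words <- integer(nw)
  p <- unique(positions)
  if (length(p) > 0L) {
    wi <- p %/% 16L + 1L
    bv <- bitwShiftL(1L, 15L - p %% 16L)
    agg <- rowsum(bv, wi)
    words[as.integer(rownames(agg))] <- agg[, 1L]
  }
  paste(sprintf("%04x", words), collapse = "")
}

zero_hex <- function(bloom_length) {
  strrep("0", bloom_length %/% 4L)
}

# Unpack a vector of hex filters into an n x (l/16) integer matrix of words.
hex_to_words <- function(hex, bloom_length) {
  nw <- bloom_length %/% 16L
  n <- length(hex)
  out <- matrix(0L, nrow = n, ncol = nw)
  if (n == 0L) {
    return(out)
  }
  if (any(nchar(hex) != nw * 4L, na.rm = TRUE)) {
    stop("Bloom filter hex length does not match bloom_length", call. = FALSE)
  }
  for (w in seq_len(nw)) {
    out[, w] <- strtoi(substr(hex, 4L * w - 3L, 4L * w), 16L)
  }
  out[is.na(out)] <- 0L
  out
}

words_cardinality <- function(words) {
  pc <- pop16()
  rowSums(matrix(pc[words + 1L], nrow = nrow(words)))
}

# Dice over row-aligned word matrices; all-zero filters are missing -> NA.
dice_words <- function(wa, wb) {
  pc <- pop16()
  inter <- rowSums(matrix(pc[bitwAnd(wa, wb) + 1L], nrow = nrow(wa)))
  ca <- words_cardinality(wa)
  cb <- words_cardinality(wb)
  out <- 2 * inter / (ca + cb)
  out[ca == 0L | cb == 0L] <- NA_real_
  out
}

#' Sorensen-Dice similarity of two Bloom filters
#'
#' `dice(a, b) = 2|a & b| / (|a| + |b|)` where `|x|` counts set bits.
#' Vectorised over pairs of hex-encoded filters. An all-zero filter encodes
#' a missing field, so any comparison involving one returns `NA`.
#'
#' Note that for *dissimilar* inputs the Bloom-level coefficient
#' overestimates the underlying bigram-set Dice: with dense filters (e.g.
#' 30 hashes per bigram into 512 bits) unrelated strings share bits by
#' collision alone, giving a floor of roughly 0.25 rather than 0. Near
#' agreement — the region that decides matches — the approximation is tight.
#'
#' @param a,b Character vectors of hex-encoded filters of equal bit length.
#' @param bloom_length Filter length in bits; defaults to 4 bits per hex
#'   character of `a`.
#' @return Numeric vector of similarities in `[0, 1]`, `NA` where either
#'   filter is empty.
#' @examples
#' cfg <- encoding_config(key = "k")
#' f <- bloom_encode("smith", "surname", cfg)
#' dice(f, f)
#' @export
dice <- function(a, b, bloom_length = nchar(a[1]) * 4L) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) == 0L) {
    return(numeric(0))
  }
  if (any(nchar(a) != nchar(b))) {
    stop("Bloom filter lengths differ between `a` and `b`", call. = FALSE)
  }
  dice_words(
    hex_to_words(a, bloom_length),
    hex_to_words(b, bloom_length)
  )
}

#' Dice similarity of two bigram sets (clear-text)
#'
#' The clear-text analogue of [dice()]: `2|A n B| / (|A| + |B|)` over the
#' distinct unpadded bigram sets of two cleaned strings. Used by the
#' clear-text baseline linker and as the independent oracle for the
#' Bloom-level coefficient.
#'
#' @param a,b Character vectors of cleaned strings.
#' @return Numeric similarity vector; `NA` where either bigram set is empty.
#' @export
bigram_dice <- function(a, b) {
  ba <- extract_bigrams(a)
  bb <- extract_bigrams(b)
  mapply(function(x, y) {
    if (length(x) == 0L || length(y) == 0L) {
      return(NA_real_)
    }
    2 * length(intersect(x, y)) / (length(x) + length(y))
  }, ba, bb)
}
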