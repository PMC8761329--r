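# Shared fixtures. Everything is built in code; nothing is read from disk.

test_config <- function(key = "testkey", ...) {
  encoding_config(key = key, ...)
}

# Independent hex builder for hand-constructed Bloom filters: bit b (0-based,
# MSB-first) lives in hex nibble b %/% 4 with value 2^(3 - b %% 4).
hex_from_bits <- function(bits, bloom_length = 512L) {
  v <- integer(bloom_length %/% 4L)
  for (b in bits) {
    i <- b %/% 4L + 1L
    v[i] <- bitwOr(v[i], bitwShiftL(1L, 3L - b %% 4L))
  }
  paste(sprintf("%x", v), collapse = "")
}

# A minimal clear-text record row with overridable fields.
person_row <- function(record_id, dataset = "morbidity",
                       given1 = "MARY", given2 = "", given3 = "",
                       surname = "SMITH", sex = "F",
                       dob = as.Date("1950-03-02"),
                       address = "12 JOHN ST", suburb = "PERTH",
                       postcode = "6000") {
  tibble::tibble(
    record_id = record_id, dataset = dataset,
    given1 = given1, given2 = given2, given3 = given3,
    surname = surname, sex = sex, dob = dob,
    address = address, suburb = suburb, postcode = postcode
  )
}

# One random typo (substitution / deletion / transposition), written
# independently of the generator's internal operator.
typo_once <- function(s) {
  n <- nchar(s)
  if (n < 2L) {
    return(s)
  }
  op <- sample(3L, 1L)
  i <- sample(n, 1L)
  if (op == 1L) {
    paste0(substr(s, 1, i - 1), sample(LETTERS, 1), substr(s, i + 1, n))
  } else if (op == 2L) {
    paste0(substr(s, 1, i - 1), substr(s, i + 1, n))
  } else {
    if (i == n) i <- n - 1L
    paste0(
      substr(s, 1, i - 1), substr(s, i + 1, i + 1),
      substr(s, i, i), substr(s, i + 2, n)
    )
  }
}

quiet_synth <- function(...) synthesize_linkage_data(synth_config(...))
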