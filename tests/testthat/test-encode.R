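# Frozen oracle values computed with an independent HMAC-SHA-256
# implementation (Python hmac/hashlib), following the documented scheme:
# i-th index of bigram g = first 24 bits of HMAC(key, field|g|i) mod 512.
SMITH_SURNAME_TESTKEY_HEX <- paste0(
  "009080060040109520944001402026c20040510010004041822288a4c0006124",
  "470401804000ce1405080744420409041290002104c4002822040808a00d9800"
)
DOB_19500302_TESTKEY_TOKEN <-
  "387dc85be4ab0575a96419be1d8141058f35f71a705b2d969da72059b46cef4f"

test_that("Bloom encoding reproduces the independent HMAC oracle", {
  cfg <- test_config()
  h <- bloom_encode("smith", "surname", cfg)
  expect_equal(h, SMITH_SURNAME_TESTKEY_HEX)
  # cardinality bound: <= k x |bigrams|, and at least one bit set
  card <- sum(strtoi(strsplit(h, "")[[1]], 16L) |>
    sapply(function(v) sum(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)))
  expect_lte(card, 30 * 4)
  expect_gte(card, 1)
})

test_that("empty input encodes to the all-zero filter, deterministically", {
  cfg <- test_config()
  expect_equal(bloom_encode("", "given1", cfg), strrep("0", 128))
  expect_equal(bloom_encode(NA, "given1", cfg), strrep("0", 128))
  expect_identical(
    bloom_encode(c("smith", "jones"), "surname", cfg),
    bloom_encode(c("smith", "jones"), "surname", cfg)
  )
  expect_error(bloom_encode("smith", "sex", cfg), "not a Bloom-encoded")
})

test_that("different keys never produce colliding filters", {
  cfg1 <- test_config(key = "key-one")
  cfg2 <- test_config(key = "key-two")
  set.seed(42)
  values <- replicate(100, paste(sample(letters, 7, replace = TRUE), collapse = ""))
  f1 <- bloom_encode(values, "surname", cfg1)
  f2 <- bloom_encode(values, "surname", cfg2)
  expect_true(all(f1 != f2))
})

test_that("filter cardinality respects the k x bigram-count bound", {
  cfg <- test_config()
  set.seed(7)
  values <- replicate(50, paste(
    sample(letters, sample(2:15, 1), replace = TRUE),
    collapse = ""
  ))
  hex <- bloom_encode(values, "suburb", cfg) # k = 25
  nb <- lengths(extract_bigrams(values))
  card <- vapply(hex, function(h) {
    sum(vapply(
      strtoi(strsplit(h, "")[[1]], 16L),
      function(v) sum(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), numeric(1)
    ))
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(card <= 25 * nb))
  expect_true(all(card[nb > 0] >= 1))
})

test_that("hash tokens are deterministic, field-separated and missing-aware", {
  cfg <- test_config()
  expect_equal(hash_encode("19500302", "dob", cfg), DOB_19500302_TESTKEY_TOKEN)
  expect_identical(
    hash_encode("19500302", "dob", cfg),
    hash_encode("19500302", "dob", cfg)
  )
  expect_true(is.na(hash_encode("", "postcode", cfg)))
  # the field label is part of the HMAC message: same value, different field
  expect_false(identical(
    hash_encode("6000", "postcode", cfg),
    hash_encode("6000", "sex", cfg)
  ))
  # token equality follows value equality under one key, not across keys
  cfg2 <- test_config(key = "other")
  expect_false(identical(
    hash_encode("6000", "postcode", cfg),
    hash_encode("6000", "postcode", cfg2)
  ))
})

test_that("dataset encoding reports missingness and round-trips losslessly", {
  cfg <- test_config()
  df <- dplyr::bind_rows(
    person_row("r1"),
    person_row("r2", given1 = "", postcode = ""),
    person_row("r3", surname = "O'Brien")
  )
  enc <- encode_records(df, cfg)
  expect_equal(nrow(enc), 3L)
  rep <- encoding_report(enc)
  expect_equal(rep$record_count, 3L)
  miss <- setNames(rep$missingness$n_missing, rep$missingness$field)
  expect_equal(miss[["given1"]], 1L)
  expect_equal(miss[["postcode"]], 1L)
  expect_equal(miss[["surname"]], 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_encoded(enc, path)
  back <- read_encoded(path)
  expect_equal(back, enc, ignore_attr = TRUE)
  # byte-identical re-encoding
  enc2 <- encode_records(df, cfg)
  expect_identical(as.data.frame(enc), as.data.frame(enc2))
})

test_that("zero records encode to zero records", {
  cfg <- test_config()
  enc <- encode_records(person_row(character(0)), cfg)
  expect_equal(nrow(enc), 0L)
  expect_equal(encoding_report(enc)$record_count, 0L)
})

test_that("schema mismatches are reported by field name", {
  cfg <- test_config()
  df <- person_row("r1")
  df$surname <- NULL
  expect_error(encode_records(df, cfg), "surname")
  expect_error(
    encode_records(dplyr::bind_rows(person_row("r1"), person_row("r1")), cfg),
    "unique"
  )
})

test_that("encoded output leaks no clear-text identifier substrings", {
  synth <- quiet_synth(n_persons = 40, seed = 11)
  cfg <- test_config()
  enc <- encode_records(synth$morbidity, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_encoded(enc, path)
  blob <- tolower(paste(readLines(path), collapse = "\n"))
  clear <- unique(unlist(synth$morbidity[c(
    "given1", "surname", "address", "suburb"
  )]))
  clear <- tolower(gsub("[^A-Za-z0-9]", "", clear))
  clear <- clear[nchar(clear) >= 4]
  expect_true(length(clear) > 10)
  expect_false(any(vapply(clear, grepl, logical(1), x = blob, fixed = TRUE)))
})
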