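# A reduced five-field schema keeps the closed-form arithmetic legible.
five_field_config <- function() {
  test_config(
    bloom_fields = c("given1", "surname"),
    hash_fields = c("sex", "dob", "postcode"),
    hashes_per_bigram = c(given1 = 30L, surname = 30L),
    blocking = list(block_on("dob"))
  )
}

five_field_weights <- function(m = 0.9, u = 0.1) {
  match_weights(data.frame(
    field = c("given1", "surname", "sex", "dob", "postcode"),
    m = m, u = u
  ))
}

five_field_pair <- function(row_a, row_b) {
  cfg <- five_field_config()
  enc <- encode_records(dplyr::bind_rows(row_a, row_b), cfg)
  cands <- tibble::tibble(
    id_a = row_a$record_id, id_b = row_b$record_id,
    block_pass = "manual"
  )
  compare_pairs(cands, enc, five_field_weights(), cfg)
}

test_that("fully agreeing and disagreeing pairs hit the closed forms", {
  a <- person_row("r1")
  b <- person_row("r2")
  scored <- five_field_pair(a, b)
  expect_equal(scored$score, 5 * log2(0.9 / 0.1), tolerance = 1e-12)

  c <- person_row("r3",
    given1 = "Zebediah", surname = "Quokka", sex = "M",
    dob = as.Date("1931-07-09"), postcode = "6999"
  )
  scored2 <- five_field_pair(a, c)
  expect_equal(scored2$score, 5 * log2((1 - 0.9) / (1 - 0.1)), tolerance = 1e-12)
})

test_that("missing fields contribute exactly zero", {
  a <- person_row("r1")
  allmiss <- person_row("r2",
    given1 = "", surname = "", sex = "",
    dob = as.Date(NA), postcode = ""
  )
  scored <- five_field_pair(a, allmiss)
  expect_equal(scored$score, 0)
  one_miss <- person_row("r3", postcode = "")
  scored2 <- five_field_pair(a, one_miss)
  expect_equal(scored2$score, 4 * log2(9), tolerance = 1e-12)
})

test_that("Bloom similarity at the partial floor counts as full disagreement", {
  cfg <- test_config(
    bloom_fields = "surname", hash_fields = character(0),
    hashes_per_bigram = c(surname = 30L)
  )
  w <- match_weights(data.frame(field = "surname", m = 0.9, u = 0.1))
  # dice = 2*7/(10+10) = 0.7 exactly: a = bits 0..9, b = bits 3..12
  enc <- tibble::tibble(
    record_id = c("a", "b", "c"),
    dataset = "x",
    surname = c(
      hex_from_bits(0:9), hex_from_bits(3:12),
      hex_from_bits(c(0:8, 20)) # dice vs a: 18/19, inside the partial band
    )
  )
  cands <- tibble::tibble(id_a = c("a", "a"), id_b = c("b", "c"), block_pass = "m")
  scored <- compare_pairs(cands, enc, w, cfg)
  expect_equal(scored$sim_surname[1], 0.7)
  expect_equal(scored$score[1], w$w_disagree)
  # interpolation: w_disagree + (s - floor)/(1 - floor) * (w_agree - w_disagree)
  s <- scored$sim_surname[2]
  expect_equal(
    scored$score[2],
    w$w_disagree + (s - 0.7) / 0.3 * (w$w_agree - w$w_disagree)
  )
  expect_gt(scored$score[2], w$w_disagree)
  expect_lt(scored$score[2], w$w_agree)
})

test_that("pair comparison is symmetric in its record arguments", {
  a <- person_row("r1")
  b <- person_row("r2", given1 = "Maria", postcode = "6001")
  expect_equal(
    five_field_pair(a, b)$score,
    five_field_pair(b, a)$score
  )
})

test_that("classification is inclusive at the threshold and monotone", {
  scored <- tibble::tibble(
    id_a = c("a", "b", "c"), id_b = c("x", "y", "z"),
    score = c(20.0, 19.99, 25)
  )
  cls <- classify_pairs(scored, threshold = 20)
  expect_equal(cls$accepted, c(TRUE, FALSE, TRUE))
  # raising the threshold never adds accepted pairs
  accepted_at <- function(t) which(classify_pairs(scored, t)$accepted)
  for (t in seq(0, 30, by = 2.5)) {
    expect_true(all(accepted_at(t + 1) %in% accepted_at(t)))
  }
})

test_that("a field present in the data but absent from weights errors", {
  cfg <- five_field_config()
  enc <- encode_records(person_row("r1"), cfg)
  w <- match_weights(data.frame(field = c("given1", "surname"), m = 0.9, u = 0.1))
  cands <- tibble::tibble(id_a = "r1", id_b = "r1", block_pass = "m")
  expect_error(compare_pairs(cands, enc, w, cfg), "no match weights")
})

test_that("score-band sampling is seeded, bounded and pattern-only", {
  synth <- quiet_synth(n_persons = 50, seed = 9)
  cfg <- test_config()
  scored <- link_encoded(
    encode_records(synth$morbidity, cfg),
    encode_records(synth$mortality, cfg),
    default_weights(), cfg
  )
  band <- sample_score_band(scored, 20, 40, n = 5, seed = 99)
  expect_lte(nrow(band), 5L)
  expect_true(all(band$score >= 20 & band$score < 40))
  expect_identical(band, sample_score_band(scored, 20, 40, n = 5, seed = 99))
  # empty band and n larger than band
  expect_equal(nrow(sample_score_band(scored, 1e6, 2e6, n = 5)), 0L)
  whole <- dplyr::filter(scored, score >= 20, score < 40)
  expect_equal(
    nrow(sample_score_band(scored, 20, 40, n = nrow(whole) + 10)),
    nrow(whole)
  )
})
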