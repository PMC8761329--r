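zero_missing <- function() {
  z <- c(
    given1 = 0, given2 = 0, given3 = 0, surname = 0, sex = 0,
    dob = 0, address = 0, suburb = 0, postcode = 0
  )
  list(morbidity = z, mortality = z)
}

clean_config <- function(...) {
  args <- utils::modifyList(
    list(
      typo_rate = 0, diminutive_rate = 0, address_variant_rate = 0,
      facility_rate = 0, name_swap_rate = 0, twin_fraction = 0,
      placeholder_rate = 0, missingness = zero_missing()
    ),
    list(...)
  )
  do.call(synth_config, args)
}

test_that("generation is deterministic under a fixed seed", {
  a <- synthesize_linkage_data(synth_config(n_persons = 120, seed = 5))
  b <- synthesize_linkage_data(synth_config(n_persons = 120, seed = 5))
  expect_identical(a$morbidity, b$morbidity)
  expect_identical(a$mortality, b$mortality)
  expect_identical(a$truth, b$truth)
  expect_identical(a$corruptions, b$corruptions)
  c <- synthesize_linkage_data(synth_config(n_persons = 120, seed = 6))
  expect_false(identical(a$morbidity, c$morbidity))
})

test_that("zero corruption and missingness copy persons exactly", {
  synth <- synthesize_linkage_data(clean_config(n_persons = 80, seed = 2))
  expect_equal(nrow(corruption_report(synth)), 0L)
  pop <- synth$population
  person_of <- stats::setNames(synth$truth$person_id, synth$truth$record_id)
  for (ds in list(synth$morbidity, synth$mortality)) {
    idx <- match(person_of[ds$record_id], pop$person_id)
    for (f in c("given1", "surname", "sex", "address", "suburb", "postcode")) {
      expect_identical(ds[[f]], pop[[f]][idx])
    }
    expect_identical(ds$dob, pop$dob[idx])
  }
  # every person has >= 1 morbidity record; mortality has <= 1 per person
  expect_setequal(
    unique(person_of[synth$morbidity$record_id]),
    pop$person_id
  )
  expect_equal(
    anyDuplicated(person_of[synth$mortality$record_id]), 0L
  )
  # every record has exactly one person in the truth map
  expect_setequal(
    synth$truth$record_id,
    c(synth$morbidity$record_id, synth$mortality$record_id)
  )
})

test_that("missingness converges to the configured per-field rates", {
  synth <- synthesize_linkage_data(synth_config(n_persons = 1200, seed = 8))
  rates <- default_missingness()$morbidity
  morb <- synth$morbidity
  n <- nrow(morb)
  for (f in c("given1", "given2", "given3")) {
    obs <- mean(morb[[f]] == "")
    se <- sqrt(rates[[f]] * (1 - rates[[f]]) / n)
    expect_lt(abs(obs - rates[[f]]), 4 * se + 1e-9)
  }
  expect_equal(mean(is.na(morb$dob)), 0)
})

test_that("twin pairs carry the detectable twin signature", {
  synth <- synthesize_linkage_data(clean_config(
    n_persons = 200, seed = 12, twin_fraction = 0.1
  ))
  pop <- synth$population
  twins <- pop[!is.na(pop$twin_of), ]
  expect_gt(nrow(twins), 0L)
  sib <- pop[match(twins$twin_of, pop$person_id), ]
  expect_identical(twins$surname, sib$surname)
  expect_identical(twins$dob, sib$dob)
  expect_identical(twins$address, sib$address)
  expect_false(any(twins$sex == sib$sex))
  expect_false(any(twins$given1 == sib$given1))

  # cross-module: an encoded record pair of two twin siblings fires the
  # twin-pattern rule
  cfg <- test_config()
  pair <- dplyr::bind_rows(
    dplyr::mutate(twins[1, ], record_id = "t1", dataset = "morbidity",
      given2 = "", given3 = ""),
    dplyr::mutate(sib[1, ], record_id = "t2", dataset = "morbidity",
      given2 = "", given3 = "")
  )
  enc <- encode_records(pair[, c(
    "record_id", "dataset", "given1", "given2", "given3", "surname",
    "sex", "dob", "address", "suburb", "postcode"
  )], cfg)
  scored <- compare_pairs(
    tibble::tibble(id_a = "t1", id_b = "t2", block_pass = "m"),
    enc, default_weights(), cfg
  )
  expect_true(detect_twin_pattern(scored))
})

test_that("no twins requested means no twin structure beyond chance", {
  synth <- synthesize_linkage_data(clean_config(n_persons = 300, seed = 4))
  expect_true(all(is.na(synth$population$twin_of)))
})

test_that("corruption provenance counts follow the configured rates", {
  synth <- synthesize_linkage_data(synth_config(
    n_persons = 800, seed = 10,
    diminutive_rate = 0.1, typo_rate = 0,
    address_variant_rate = 0, facility_rate = 0,
    name_swap_rate = 0, placeholder_rate = 0, twin_fraction = 0,
    missingness = zero_missing()
  ))
  rep <- corruption_report(synth)
  expect_true(all(rep$type == "diminutive"))
  # eligible records: given1 has a diminutive form
  n_rec <- nrow(synth$morbidity) + nrow(synth$mortality)
  p_eligible <- nrow(rep) / n_rec
  # diminutive-capable names are roughly 46/139 of the pool; applied at 0.1
  expect_gt(p_eligible, 0.01)
  expect_lt(p_eligible, 0.08)
  # diminutive substitution recorded with its replacement value
  expect_true(all(nzchar(rep$detail)))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(typo_rate = 1.5), "rates")
  expect_error(synth_config(morbidity_mean = 0.5), "morbidity_mean")
})
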