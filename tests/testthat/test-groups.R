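pairs_tbl <- function(...) {
  v <- c(...)
  if (is.null(v)) {
    return(tibble::tibble(id_a = character(0), id_b = character(0)))
  }
  m <- matrix(v, ncol = 2, byrow = TRUE)
  tibble::tibble(id_a = m[, 1], id_b = m[, 2])
}

test_that("groups are the transitive closure of accepted pairs", {
  g <- build_groups(pairs_tbl("a", "b", "b", "c"), c("a", "b", "c", "d"))
  expect_equal(g$group_id[g$record_id %in% c("a", "b", "c")], rep("a", 3))
  expect_equal(g$group_id[g$record_id == "d"], "d") # singleton included
  g0 <- build_groups(pairs_tbl()[0, ], c("x", "y"))
  expect_equal(g0$group_id, c("x", "y"))
})

test_that("grouping matches brute-force traversal and ignores pair order", {
  set.seed(14)
  ids <- sprintf("n%04d", 1:300)
  pr <- tibble::tibble(
    id_a = sample(ids, 250, replace = TRUE),
    id_b = sample(ids, 250, replace = TRUE)
  )
  pr <- pr[pr$id_a != pr$id_b, ]
  g <- build_groups(pr, ids)

  # oracle: repeated label propagation to a fixed point
  lab <- stats::setNames(ids, ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pr))) {
      a <- pr$id_a[r]
      b <- pr$id_b[r]
      m <- min(lab[[a]], lab[[b]])
      if (lab[[a]] != m || lab[[b]] != m) {
        lab[lab %in% c(lab[[a]], lab[[b]])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(stats::setNames(g$group_id, g$record_id), lab[g$record_id])

  # pair order invariance
  g2 <- build_groups(pr[sample(nrow(pr)), c("id_a", "id_b")], ids)
  expect_equal(g, g2)
})

test_that("unknown or self-referencing pairs are input errors", {
  expect_error(build_groups(pairs_tbl("a", "zz"), c("a", "b")), "unknown")
  expect_error(build_groups(pairs_tbl("a", "a"), c("a", "b")), "itself")
})

test_that("group flags follow the review rules", {
  ids <- tibble::tibble(
    record_id = c("m1", "m2", "d1", "d2", sprintf("x%02d", 1:12)),
    dataset = c("morbidity", "morbidity", "mortality", "mortality", rep("morbidity", 12))
  )
  pr <- pairs_tbl(
    "m1", "d1", # group 1: one death, low-weight internal pair
    "m2", "d2", "d1", "d2" # joins both deaths into group 1
  )
  pr <- dplyr::bind_rows(pr, tibble::tibble(
    id_a = sprintf("x%02d", 1:11), id_b = sprintf("x%02d", 2:12)
  ))
  pr$score <- c(21, 30, 30, rep(35, 11))
  g <- build_groups(pr[, 1:2], ids)
  fl <- flag_groups(g, pr, qa_params(
    low_weight_band = c(20, 22),
    large_group = 10L
  ))
  big <- fl[fl$group_id == "x01", ]
  expect_true(big$large_group)
  expect_false(big$multiple_deaths)
  dual <- fl[fl$group_id == "d1", ]
  expect_true(dual$multiple_deaths)
  expect_true(dual$low_weight_pair) # the 21-scoring m1-d1 pair
  expect_equal(dual$n_mortality, 2L)
})

test_that("the twin signature requires full agreement except name and sex", {
  base <- tibble::tibble(
    sim_given1 = 0.2, sim_given2 = NA_real_, sim_given3 = NA_real_,
    sim_surname = 1, sim_dob = 1, sim_address = 1, sim_suburb = 1,
    sim_postcode = 1, sim_sex = 0
  )
  expect_true(detect_twin_pattern(base))
  identical_rec <- dplyr::mutate(base, sim_given1 = 1, sim_sex = 1)
  expect_false(detect_twin_pattern(identical_rec)) # sex agrees
  typo_rec <- dplyr::mutate(base, sim_given1 = 0.7, sim_sex = 1)
  expect_false(detect_twin_pattern(typo_rec)) # same person, name typo
  addr_off <- dplyr::mutate(base, sim_address = 0.9)
  expect_false(detect_twin_pattern(addr_off)) # address must fully agree
  similar_name <- dplyr::mutate(base, sim_given1 = 0.85)
  expect_false(detect_twin_pattern(similar_name)) # above the name ceiling
  name_missing <- dplyr::mutate(base, sim_given1 = NA_real_)
  expect_false(detect_twin_pattern(name_missing))
})

test_that("splitting removes bridges, refines the partition, keeps all ids", {
  ids <- c("a", "b", "c", "d", "e", "f")
  pr <- pairs_tbl("a", "b", "a", "c", "c", "d", "d", "e", "d", "f")
  g <- build_groups(pr, ids)
  expect_equal(length(unique(g$group_id)), 1L)
  # remove the single bridge c-d of the dumbbell
  g2 <- split_group(g, pr, pairs_tbl("c", "d"))
  expect_equal(length(unique(g2$group_id)), 2L)
  expect_setequal(g2$record_id[g2$group_id == "a"], c("a", "b", "c"))
  expect_setequal(g2$record_id[g2$group_id == "d"], c("d", "e", "f"))
  # refinement: every post-split group is inside one pre-split group
  joined <- dplyr::inner_join(g, g2, by = "record_id", suffix = c("_pre", "_post"))
  expect_true(all(tapply(
    joined$group_id_pre, joined$group_id_post,
    function(v) length(unique(v)) == 1L
  )))
  # identity and error cases
  expect_equal(split_group(g, pr, pr[0, ]), g, ignore_attr = TRUE)
  expect_error(split_group(g, pr, pairs_tbl("a", "f")), "not internal")
  expect_setequal(g2$record_id, ids)
})

test_that("quality assurance splits twins and separates death records", {
  synth <- quiet_synth(
    n_persons = 400, seed = 31,
    twin_fraction = 0.06, mortality_fraction = 0.3,
    typo_rate = 0, diminutive_rate = 0, address_variant_rate = 0,
    facility_rate = 0, name_swap_rate = 0, placeholder_rate = 0,
    missingness = list(
      morbidity = c(given1 = 0, given2 = 0, given3 = 0, surname = 0, sex = 0,
        dob = 0, address = 0, suburb = 0, postcode = 0),
      mortality = c(given1 = 0, given2 = 0, given3 = 0, surname = 0, sex = 0,
        dob = 0, address = 0, suburb = 0, postcode = 0)
    )
  )
  cfg <- test_config()
  enc_a <- encode_records(synth$morbidity, cfg)
  enc_b <- encode_records(synth$mortality, cfg)
  scored <- link_encoded(enc_a, enc_b, default_weights(), cfg)
  pool <- dplyr::bind_rows(enc_a, enc_b)
  pre <- build_groups(
    scored[scored$accepted, c("id_a", "id_b")],
    pool[, c("record_id", "dataset")]
  )
  post <- apply_group_qa(pre, scored, qa_params())

  # twins linked before QA are separated after it
  person <- stats::setNames(synth$truth$person_id, synth$truth$record_id)
  twin_of <- stats::setNames(synth$population$twin_of, synth$population$person_id)
  acc <- scored[scored$accepted, ]
  cross_twin <- !is.na(twin_of[person[acc$id_a]]) &
    twin_of[person[acc$id_a]] == person[acc$id_b]
  expect_gt(sum(cross_twin), 0L) # the hazard is present before QA
  grp <- stats::setNames(post$group_id, post$record_id)
  expect_true(all(grp[acc$id_a[cross_twin]] != grp[acc$id_b[cross_twin]]))

  # no group retains two or more death records
  fl <- flag_groups(post, acc, qa_params())
  expect_true(all(!fl$multiple_deaths))

  # QA only refines: each post group sits inside one pre group
  joined <- dplyr::inner_join(pre, post,
    by = "record_id", suffix = c("_pre", "_post")
  )
  expect_true(all(tapply(
    joined$group_id_pre, joined$group_id_post,
    function(v) length(unique(v)) == 1L
  )))
  expect_setequal(post$record_id, pre$record_id)
})
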