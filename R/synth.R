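#' Configuration for the synthetic morbidity/mortality generator
#'
#' Defines a synthetic population and two linked extracts shaped like a
#' hospital morbidity collection (many records per person) and a death
#' registration file (at most one record per person), with known person
#' truth. Per-field missingness defaults reproduce the profile of real
#' administrative extracts of this kind (second given names missing in
#' half the hospital records, third given names almost always missing,
#' near-complete surname/sex/date of birth); corruption defaults plant the
#' error modes that drive linkage discrepancies in practice: typos,
#' diminutive first names, address keyword variants (UNIT/LOT/FLAT),
#' facility-name address prefixes, swapped first/last names, male-female
#' twins, and placeholder addresses with associated dummy postcodes.
#'
#' @param n_persons Number of persons in the population.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @param morbidity_mean Mean of the zero-truncated geometric number of
#'   morbidity records per person.
#' @param mortality_fraction Fraction of persons with a death record.
#' @param missingness List with elements `morbidity` and `mortality`, each
#'   a named per-field missing-value probability vector.
#' @param typo_rate Per-record, per-field probability of one random
#'   character error (substitution, transposition or deletion) in given1,
#'   surname and address.
#' @param diminutive_rate Probability that a record carries the diminutive
#'   form of its first name (when one exists for that name).
#' @param address_variant_rate Probability of a UNIT/LOT/FLAT keyword
#'   insertion (or removal when present) in the address.
#' @param facility_rate Probability that the address is prefixed with a
#'   facility name (aged-care home, hostel).
#' @param name_swap_rate Probability that first name and surname are
#'   recorded swapped.
#' @param twin_fraction Fraction of persons belonging to a planted
#'   male-female twin pair (shared surname, date of birth and address;
#'   different first name and sex).
#' @param placeholder_rate Probability that a record's address is replaced
#'   by a placeholder value with its associated dummy postcode.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_persons = 2000L,
                         seed = 1L,
                         morbidity_mean = 4,
                         mortality_fraction = 0.1,
                         missingness = default_missingness(),
                         typo_rate = 0.02,
                         diminutive_rate = 0.05,
                         address_variant_rate = 0.10,
                         facility_rate = 0.02,
                         name_swap_rate = 0.005,
                         twin_fraction = 0.005,
                         placeholder_rate = 0.02) {
  rates <- c(
    mortality_fraction, typo_rate, diminutive_rate, address_variant_rate,
    facility_rate, name_swap_rate, twin_fraction, placeholder_rate,
    unlist(missingness)
  )
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (morbidity_mean < 1) stop("`morbidity_mean` must be >= 1", call. = FALSE)
  structure(
    list(
      n_persons = as.integer(n_persons), seed = as.integer(seed),
      morbidity_mean = morbidity_mean,
      mortality_fraction = mortality_fraction,
      missingness = missingness,
      typo_rate = typo_rate, diminutive_rate = diminutive_rate,
      address_variant_rate = address_variant_rate,
      facility_rate = facility_rate, name_swap_rate = name_swap_rate,
      twin_fraction = twin_fraction, placeholder_rate = placeholder_rate
    ),
    class = "synth_config"
  )
}

#' Default per-field missingness profile
#'
#' Morbidity and mortality missing-value rates typical of administrative
#' hospital and death-registration extracts: first given name nearly
#' complete, second given name missing in 50.6% / 23.2% of records,
#' third given name missing in 99.0% / 93.5%, surname and sex complete,
#' and small rates on the mortality address fields.
#'
#' @return List with named rate vectors `morbidity` and `mortality`.
#' @export
default_missingness <- function() {
  list(
    morbidity = c(
      given1 = 0.019, given2 = 0.506, given3 = 0.990, surname = 0,
      sex = 0, dob = 0, address = 0, suburb = 0, postcode = 0
    ),
    mortality = c(
      given1 = 0.001, given2 = 0.232, given3 = 0.935, surname = 0,
      sex = 0, dob = 0.001, address = 0.003, suburb = 0.005,
      postcode = 0.013
    )
  )
}

sample_given <- function(n, sex) {
  out <- character(n)
  f <- sex == "F"
  out[f] <- sample(.given_female, sum(f), replace = TRUE)
  out[!f] <- sample(.given_male, sum(!f), replace = TRUE)
  out
}

#' Generate a synthetic person population
#'
#' Persons carry a sex, up to three given names (first names drawn from
#' sex-specific pools containing diminutive-linked canonical forms),
#' surname, date of birth (1920-2009), and an address / suburb / postcode
#' triple with consistent suburb-postcode pairing. Planted twin pairs share
#' surname, date of birth and the full address triple, differ in first
#' name, and have opposite sex.
#'
#' @param config A [synth_config()].
#' @return A tibble of persons with a `twin_of` column (`NA` when the
#'   person has no planted twin).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_persons
  withr::with_seed(config$seed, {
    sex <- sample(c("F", "M"), n, replace = TRUE)
    sub_idx <- sample(nrow(.suburbs), n, replace = TRUE)
    persons <- tibble::tibble(
      person_id = sprintf("P%06d", seq_len(n)),
      sex = sex,
      given1 = sample_given(n, sex),
      given2 = sample_given(n, sex),
      given3 = sample_given(n, sex),
      surname = sample(.surnames, n, replace = TRUE),
      dob = sample(
        seq(as.Date("1920-01-01"), as.Date("2009-12-31"), by = "day"),
        n,
        replace = TRUE
      ),
      address = paste(
        sample(1:300, n, replace = TRUE),
        sample(.streets, n, replace = TRUE),
        sample(.street_types, n, replace = TRUE)
      ),
      suburb = .suburbs$suburb[sub_idx],
      postcode = .suburbs$postcode[sub_idx],
      twin_of = NA_character_
    )
    n_pairs <- floor(config$twin_fraction * n / 2)
    if (n_pairs > 0L) {
      idx <- sample(n, 2L * n_pairs)
      a <- idx[seq_len(n_pairs)]
      b <- idx[n_pairs + seq_len(n_pairs)]
      for (col in c("surname", "dob", "address", "suburb", "postcode")) {
        persons[[col]][b] <- persons[[col]][a]
      }
      persons$sex[b] <- ifelse(persons$sex[a] == "F", "M", "F")
      persons$given1[b] <- sample_given(n_pairs, persons$sex[b])
      # twins must actually differ in first name
      clash <- persons$given1[b] == persons$given1[a]
      while (any(clash)) {
        persons$given1[b][clash] <- sample_given(sum(clash), persons$sex[b][clash])
        clash <- persons$given1[b] == persons$given1[a]
      }
      persons$twin_of[a] <- persons$person_id[b]
      persons$twin_of[b] <- persons$person_id[a]
    }
    persons
  })
}

typo_one <- function(s) {
  nc <- nchar(s)
  if (nc == 0L) {
    return(s)
  }
  op <- if (nc >= 2L) sample(c("sub", "del", "tr"), 1L) else "sub"
  i <- sample(nc, 1L)
  if (op == "sub") {
    ch <- sample(LETTERS, 1L)
    paste0(substr(s, 1L, i - 1L), ch, substr(s, i + 1L, nc))
  } else if (op == "del") {
    paste0(substr(s, 1L, i - 1L), substr(s, i + 1L, nc))
  } else {
    if (i == nc) i <- nc - 1L
    paste0(
      substr(s, 1L, i - 1L), substr(s, i + 1L, i + 1L),
      substr(s, i, i), substr(s, i + 2L, nc)
    )
  }
}

corrupt_records <- function(rec, config, log_env) {
  n <- nrow(rec)
  note <- function(rows, field, type, detail = NA_character_) {
    if (length(rows) == 0L) {
      return(invisible())
    }
    log_env$log[[length(log_env$log) + 1L]] <- tibble::tibble(
      record_id = rec$record_id[rows],
      person_id = rec$person_id[rows],
      field = field, type = type,
      detail = if (length(detail) == 1L) rep(detail, length(rows)) else detail
    )
  }
  # placeholder address + paired dummy postcode (suppresses other address edits)
  ph <- which(stats::runif(n) < config$placeholder_rate)
  if (length(ph) > 0L) {
    k <- sample(length(.placeholder_addresses), length(ph), replace = TRUE)
    rec$address[ph] <- .placeholder_addresses[k]
    rec$postcode[ph] <- .placeholder_postcodes[k]
    note(ph, "address", "placeholder", .placeholder_addresses[k])
  }
  not_ph <- setdiff(seq_len(n), ph)
  fac <- not_ph[stats::runif(length(not_ph)) < config$facility_rate]
  if (length(fac) > 0L) {
    fn <- sample(.facilities, length(fac), replace = TRUE)
    rec$address[fac] <- paste(fn, rec$address[fac])
    note(fac, "address", "facility_prefix", fn)
  }
  av <- not_ph[stats::runif(length(not_ph)) < config$address_variant_rate]
  if (length(av) > 0L) {
    has_kw <- grepl("^(UNIT|LOT|FLAT) ", rec$address[av])
    rec$address[av][has_kw] <- sub("^(UNIT|LOT|FLAT) [0-9]+ ", "", rec$address[av][has_kw])
    kw <- sample(c("UNIT", "LOT", "FLAT"), sum(!has_kw), replace = TRUE)
    rec$address[av][!has_kw] <- paste(
      kw, sample(1:9, sum(!has_kw), replace = TRUE), rec$address[av][!has_kw]
    )
    note(av, "address", "keyword_variant")
  }
  dim_ok <- which(rec$given1 %in% names(.diminutives))
  dm <- dim_ok[stats::runif(length(dim_ok)) < config$diminutive_rate]
  if (length(dm) > 0L) {
    note(dm, "given1", "diminutive", unname(.diminutives[rec$given1[dm]]))
    rec$given1[dm] <- unname(.diminutives[rec$given1[dm]])
  }
  for (f in c("given1", "surname", "address")) {
    ty <- which(stats::runif(n) < config$typo_rate & nzchar(rec[[f]]))
    if (length(ty) > 0L) {
      rec[[f]][ty] <- vapply(rec[[f]][ty], typo_one, character(1), USE.NAMES = FALSE)
      note(ty, f, "typo")
    }
  }
  sw <- which(stats::runif(n) < config$name_swap_rate)
  if (length(sw) > 0L) {
    tmp <- rec$given1[sw]
    rec$given1[sw] <- rec$surname[sw]
    rec$surname[sw] <- tmp
    note(sw, "given1", "name_swap")
  }
  rec
}

apply_missingness <- function(rec, rates) {
  n <- nrow(rec)
  for (f in names(rates)) {
    if (rates[[f]] <= 0) next
    hit <- stats::runif(n) < rates[[f]]
    if (f == "dob") {
      rec$dob[hit] <- as.Date(NA)
    } else {
      rec[[f]][hit] <- ""
    }
  }
  rec
}

#' Generate linked morbidity and mortality extracts from a population
#'
#' Each person receives a zero-truncated-geometric number of morbidity
#' records (independent per-record corruption) and, with probability
#' `mortality_fraction`, one mortality record. Corruption is applied per
#' record, then per-field missingness at the dataset-specific rates. With
#' all corruption and missingness rates at zero, every record is an exact
#' copy of its person.
#'
#' @param population Tibble from [generate_population()].
#' @param config The same [synth_config()].
#' @return A list of class `synth_linkage_data` with tibbles `morbidity`,
#'   `mortality`, `truth` (`record_id`, `dataset`, `person_id`),
#'   `corruptions` (machine-readable provenance of every applied
#'   corruption), plus the `population` and `config`.
#' @export
generate_datasets <- function(population, config) {
  stopifnot(inherits(config, "synth_config"))
  person_cols <- c(
    "given1", "given2", "given3", "surname", "sex", "dob",
    "address", "suburb", "postcode"
  )
  withr::with_seed(config$seed + 1L, {
    n_rec <- 1L + stats::rgeom(nrow(population), prob = 1 / config$morbidity_mean)
    morb <- population[rep(seq_len(nrow(population)), n_rec), c("person_id", person_cols)]
    morb <- tibble::add_column(morb,
      record_id = sprintf("HM%06d", seq_len(nrow(morb))),
      dataset = "morbidity", .before = 1L
    )
    dead <- stats::runif(nrow(population)) < config$mortality_fraction
    mort <- population[dead, c("person_id", person_cols)]
    mort <- tibble::add_column(mort,
      record_id = sprintf("DR%06d", seq_len(nrow(mort))),
      dataset = "mortality", .before = 1L
    )
    log_env <- new.env(parent = emptyenv())
    log_env$log <- list()
    morb <- corrupt_records(morb, config, log_env)
    mort <- corrupt_records(mort, config, log_env)
    morb <- apply_missingness(morb, config$missingness$morbidity)
    mort <- apply_missingness(mort, config$missingness$mortality)
    corruptions <- if (length(log_env$log) > 0L) {
      dplyr::bind_rows(log_env$log)
    } else {
      tibble::tibble(
        record_id = character(0), person_id = character(0),
        field = character(0), type = character(0), detail = character(0)
      )
    }
    truth <- dplyr::bind_rows(
      morb[, c("record_id", "dataset", "person_id")],
      mort[, c("record_id", "dataset", "person_id")]
    )
    structure(
      list(
        morbidity = morb[, c("record_id", "dataset", person_cols)],
        mortality = mort[, c("record_id", "dataset", person_cols)],
        truth = truth,
        corruptions = corruptions,
        population = population,
        config = config
      ),
      class = "synth_linkage_data"
    )
  })
}

#' Generate a complete synthetic linkage study in one call
#'
#' @param config A [synth_config()].
#' @return See [generate_datasets()].
#' @examples
#' synth <- synthesize_linkage_data(synth_config(n_persons = 100, seed = 3))
#' nrow(synth$morbidity)
#' @export
synthesize_linkage_data <- function(config = synth_config()) {
  generate_datasets(generate_population(config), config)
}

#' Per-record provenance of applied corruptions
#'
#' @param synth A `synth_linkage_data` object.
#' @return Tibble `record_id`, `person_id`, `field`, `type`, `detail`; one
#'   row per corruption applied (empty for a zero-corruption run).
#' @export
corruption_report <- function(synth) {
  stopifnot(inherits(synth, "synth_linkage_data"))
  synth$corruptions
}

#' @export
print.synth_linkage_data <- function(x, ...) {
  cat(
    "<synth_linkage_data>", nrow(x$population), "persons,",
    nrow(x$morbidity), "morbidity records,",
    nrow(x$mortality), "mortality records,",
    nrow(x$corruptions), "corruptions\n"
  )
  invisible(x)
}
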