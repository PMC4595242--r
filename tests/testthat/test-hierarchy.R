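test_that("stratum boundaries follow the strict-< convention", {
  expect_equal(stratum_of(2, 30), "lt3_lt32")
  expect_equal(stratum_of(3, 32), "ge3_ge32")
  expect_equal(stratum_of(10, 36), "ge3_ge32")
  expect_equal(stratum_of(2, 31.9), "lt3_lt32")
  expect_equal(stratum_of(0, 32.0), "lt3_ge32")
  expect_error(stratum_of(-1, 30), "non-negative")
  expect_error(stratum_of(29, 30), "exceeds 28")
  expect_error(stratum_of(5, 0), "positive")
})

test_that("missing gestation follows the configured policy", {
  expect_error(stratum_of(5, NA), "Missing gestation")
  expect_equal(stratum_of(5, NA, missing_gestation = "assume_ge32"),
               "ge3_ge32")
  expect_equal(stratum_of(5, NA, missing_gestation = "assume_lt32"),
               "ge3_lt32")
})

test_that("first eligible cause in the stratum order wins", {
  # early preterm death meeting only the prematurity definition
  out <- assign_primary_cause(
    1, 30,
    c(congenital_anomalies = FALSE, injuries = FALSE, birth_asphyxia = FALSE,
      prematurity_complications = TRUE)
  )
  expect_equal(out, "prematurity_complications")
  # asphyxia's age condition (< 7 days) defers to tetanus at day 10
  expect_equal(
    assign_primary_cause(10, 36, c(birth_asphyxia = TRUE, tetanus = TRUE)),
    "tetanus"
  )
  # same flags before day 7: asphyxia outranks tetanus
  expect_equal(
    assign_primary_cause(5, 36, c(birth_asphyxia = TRUE, tetanus = TRUE)),
    "birth_asphyxia"
  )
  # nothing eligible -> unexplained
  expect_equal(
    assign_primary_cause(5, 36, c(birth_asphyxia = FALSE)),
    "unexplained"
  )
})

test_that("serious-infection slot resolves to highest-priority member", {
  expect_equal(
    assign_primary_cause(4, 36, c(pneumonia = TRUE, diarrhea = TRUE)),
    "pneumonia"
  )
  expect_equal(
    assign_primary_cause(4, 36, c(sepsis = TRUE, pneumonia = TRUE)),
    "sepsis"
  )
  # no infection slot in the <3 days & <32 weeks stratum
  expect_equal(
    assign_primary_cause(1, 30, c(sepsis = TRUE, prematurity_complications = TRUE)),
    "prematurity_complications"
  )
})

test_that("asphyxia collapses into prematurity below 34 weeks when enabled", {
  expect_equal(
    assign_primary_cause(1, 33, c(birth_asphyxia = TRUE), collapse_lt34 = TRUE),
    "prematurity_complications"
  )
  expect_equal(
    assign_primary_cause(1, 33, c(birth_asphyxia = TRUE), collapse_lt34 = FALSE),
    "birth_asphyxia"
  )
  expect_equal(
    assign_primary_cause(1, 35, c(birth_asphyxia = TRUE), collapse_lt34 = TRUE),
    "birth_asphyxia"
  )
  # collapse threshold is configurable
  expect_equal(
    assign_primary_cause(1, 35, c(birth_asphyxia = TRUE), collapse_lt34 = TRUE,
                         collapse_threshold_weeks = 36),
    "prematurity_complications"
  )
})

test_that("unknown eligibility flags are rejected by name", {
  cases <- tibble::tibble(
    case_id = "x", age_at_death_days = 1, gestation_weeks = 30,
    elig_asphixia = TRUE
  )
  expect_error(assign_causes(cases), "asphixia")
  expect_error(
    assign_primary_cause(1, 30, c(unexplained = TRUE)), "unexplained"
  )
})

test_that("assignment is deterministic and order-dominant", {
  set.seed(11)
  causes <- assignable_causes()
  for (rep in 1:50) {
    age <- sample(0:28, 1)
    gest <- runif(1, 25, 42)
    flags <- setNames(runif(10) < 0.3, causes)
    a1 <- assign_primary_cause(age, gest, flags)
    a2 <- assign_primary_cause(age, gest, flags)
    expect_identical(a1, a2)
    if (a1 != "unexplained") {
      # forcing on any flag ranked above the winner must not yield a
      # lower-ranked cause
      s <- stratum_of(age, gest)
      plan <- hierarchy_table()
      ord <- expanded <- NULL
      expanded <- local({
        tab <- plan[plan$stratum == s, ]
        unlist(lapply(tab$slot, function(x)
          if (x == "severe_infection") severe_infection_causes() else x))
      })
      pos <- match(a1, expanded)
      if (pos > 1) {
        for (earlier in expanded[seq_len(pos - 1)]) {
          flags2 <- flags
          flags2[earlier] <- TRUE
          a3 <- assign_primary_cause(age, gest, flags2)
          expect_lte(match(a3, expanded), pos)
        }
      }
    }
  }
})

test_that("collapse monotonicity: no asphyxia label below 34 weeks with collapse on", {
  set.seed(22)
  n <- 300
  cases <- tibble::tibble(
    case_id = as.character(seq_len(n)),
    age_at_death_days = sample(0:28, n, replace = TRUE),
    gestation_weeks = runif(n, 25, 33.9),
    elig_birth_asphyxia = runif(n) < 0.7,
    elig_sepsis = runif(n) < 0.3,
    elig_prematurity_complications = runif(n) < 0.3
  )
  out <- assign_causes(cases, collapse_lt34 = TRUE)
  expect_false(any(out$assigned_cause == "birth_asphyxia"))
})

test_that("vectorised assignment equals the brute-force oracle on random cases", {
  set.seed(33)
  n <- 500
  causes <- assignable_causes()
  flag_mat <- matrix(runif(n * 10) < 0.25, n, 10, dimnames = list(NULL, causes))
  cases <- tibble::tibble(
    case_id = as.character(seq_len(n)),
    age_at_death_days = sample(0:28, n, replace = TRUE),
    gestation_weeks = round(runif(n, 24, 42), 1)
  )
  for (cc in causes) cases[[paste0("elig_", cc)]] <- flag_mat[, cc]
  for (collapse in c(FALSE, TRUE)) {
    got <- assign_causes(cases, collapse_lt34 = collapse)$assigned_cause
    want <- vapply(seq_len(n), function(i) {
      oracle_assign(cases$age_at_death_days[i], cases$gestation_weeks[i],
                    as.list(flag_mat[i, ]), collapse = collapse)
    }, character(1))
    expect_identical(got, want)
  }
})
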