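# Independent brute-force oracle for the cause-assignment hierarchy: the
# four ordered candidate lists are written out longhand (member causes of
# the serious-infection slot unrolled in sepsis > meningitis > pneumonia >
# diarrhea order) and scanned one case at a time with plain if/else logic.

oracle_orders <- list(
  lt3_lt32 = list(
    list("congenital_anomalies", Inf), list("injuries", Inf),
    list("birth_asphyxia", Inf), list("prematurity_complications", Inf)
  ),
  ge3_lt32 = list(
    list("congenital_anomalies", Inf), list("injuries", Inf),
    list("birth_asphyxia", 7), list("tetanus", Inf),
    list("sepsis", Inf), list("meningitis", Inf), list("pneumonia", Inf),
    list("diarrhea", Inf), list("prematurity_complications", Inf)
  ),
  lt3_ge32 = list(
    list("congenital_anomalies", Inf), list("injuries", Inf),
    list("birth_asphyxia", Inf),
    list("sepsis", Inf), list("meningitis", Inf), list("pneumonia", Inf),
    list("diarrhea", Inf), list("prematurity_complications", Inf),
    list("other_specific", Inf)
  ),
  ge3_ge32 = list(
    list("congenital_anomalies", Inf), list("injuries", Inf),
    list("birth_asphyxia", 7), list("tetanus", Inf),
    list("sepsis", Inf), list("meningitis", Inf), list("pneumonia", Inf),
    list("diarrhea", Inf), list("prematurity_complications", Inf),
    list("other_specific", Inf)
  )
)

oracle_assign <- function(age, gestation, flags, collapse = FALSE) {
  band_age <- if (age < 3) "lt3" else "ge3"
  band_gest <- if (gestation < 32) "lt32" else "ge32"
  order <- oracle_orders[[paste(band_age, band_gest, sep = "_")]]
  result <- "unexplained"
  for (entry in order) {
    cause <- entry[[1]]
    if (isTRUE(flags[[cause]]) && age < entry[[2]]) {
      result <- cause
      break
    }
  }
  if (collapse && result == "birth_asphyxia" && gestation < 34) {
    result <- "prematurity_complications"
  }
  result
}

# turn a named flag list into a one-row case table for assign_causes()
flags_to_case <- function(id, age, gestation, flags) {
  row <- tibble::tibble(
    case_id = id, age_at_death_days = age, gestation_weeks = gestation
  )
  for (cause in names(flags)) {
    row[[paste0("elig_", cause)]] <- isTRUE(flags[[cause]])
  }
  row
}

# printed per-cause accuracy table of the validation study, used as a fixed
# input fixture: 2x2 counts plus the published point estimates and 95% CI
# bounds (percent, one decimal)
table5_fixture <- function() {
  tibble::tribble(
    ~cause, ~tp, ~fp, ~tn, ~fn,
    ~sens, ~sens_lo, ~sens_hi, ~spec, ~spec_lo, ~spec_hi,
    ~ppv, ~ppv_lo, ~ppv_hi, ~npv, ~npv_lo, ~npv_hi,
    "congenital_anomalies", 8, 5, 607, 6,
    57.1, 32.6, 78.6, 99.2, 98.1, 99.6, 61.5, 35.5, 82.3, 99.0, 97.9, 99.5,
    "prematurity_complications", 209, 20, 382, 15,
    93.3, 89.2, 95.9, 95.0, 92.4, 96.7, 91.3, 86.9, 94.3, 96.2, 93.8, 97.7,
    "birth_asphyxia", 147, 41, 409, 29,
    83.5, 77.3, 88.3, 90.9, 87.8, 93.2, 78.2, 71.8, 83.5, 93.4, 90.6, 95.3,
    "tetanus", 6, 3, 614, 3,
    66.7, 35.4, 87.9, 99.5, 98.6, 99.8, 66.7, 35.4, 87.9, 99.5, 98.6, 99.8,
    "severe_infection", 138, 27, 424, 37,
    78.9, 72.2, 84.3, 94.0, 91.4, 95.9, 83.6, 77.2, 88.5, 92.0, 89.1, 94.1
  )
}

# random reviewer table with known composition, for partition properties
random_reviews <- function(n, p_agree, p_arb_match) {
  causes <- assignable_causes()
  ids <- sprintf("c%04d", seq_len(n))
  r1 <- sample(causes, n, replace = TRUE)
  agree <- runif(n) < p_agree
  r2 <- ifelse(agree, r1, vapply(r1, function(a)
    sample(setdiff(causes, a), 1), character(1)))
  arb <- rep(NA_character_, n)
  disc <- which(!agree)
  for (i in disc) {
    arb[i] <- if (runif(1) < p_arb_match) {
      sample(c(r1[i], r2[i]), 1)
    } else {
      sample(setdiff(causes, c(r1[i], r2[i])), 1)
    }
  }
  prim <- tibble::tibble(
    case_id = rep(ids, 2),
    reviewer_id = rep(c("A", "B"), each = n),
    round = "primary",
    cause = c(r1, r2)
  )
  arbr <- tibble::tibble(
    case_id = ids[!is.na(arb)], reviewer_id = "C", round = "arbiter",
    cause = arb[!is.na(arb)]
  )
  dplyr::bind_rows(prim, arbr)
}
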