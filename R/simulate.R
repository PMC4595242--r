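# Synthetic cohort generator. Emulates the data-generating structure the
# validation pipeline assumes: true causes drawn from a CSMF profile,
# adjudicated VA labels drawn from a per-cause misclassification (confusion)
# structure, reviewer tables whose consensus / arbiter-resolved / all-differ
# proportions match configured rates, covariates matching the study cohort,
# and eligibility flags constructed so the assignment hierarchy reproduces
# each case's intended cause exactly.

# Categories a true (reference) cause can take: every assignable cause plus
# "unexplained" (a real death whose records meet no case definition).
sim_categories <- function() c(assignable_causes(), "unexplained")

#' Build and validate a simulation configuration
#'
#' Assembles the parameter set for [simulate_cohort()]. The `confusion`
#' matrix describes the *final adjudicated* VA label: row `i`, column `j`
#' is the probability that a death whose true (reference) cause is `i`
#' receives adjudicated VA label `j`. Its last column, `unclassifiable`,
#' must equal `(1 - reviewer_agreement["va"]) * (1 - arbiter_match["va"])`
#' in every row, because a VA case ends unclassifiable exactly when its two
#' reviewers disagree and the arbiter sides with neither.
#'
#' @param n_cases Number of deaths to simulate.
#' @param csmf Named probability vector over the true-cause categories
#'   (assignable causes plus `unexplained`); must sum to 1.
#' @param confusion Row-stochastic matrix, rows named by the true-cause
#'   categories, columns by the same categories plus `unclassifiable`.
#' @param reviewer_agreement Named vector `c(reference = , va = )`:
#'   probability the two primary reviewers agree on a case.
#' @param arbiter_match Named vector `c(reference = , va = )`: probability
#'   the arbiter sides with one of the two discrepant reviewers.
#' @param covariates List of covariate-distribution parameters: `age_mean`,
#'   `age_sd` (truncated normal on 0-28 completed days),
#'   `gestation_preterm_mean/sd` (weeks, used for prematurity cases),
#'   `gestation_other_mean/sd`, `p_male`, `birth_weight_mean/sd` (grams).
#' @param p_extra_flag Probability that an eligibility flag of a cause
#'   ranked *below* the intended cause in the case's stratum is also set
#'   (extra flags never change the assigned cause).
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `vaval_config`.
#' @seealso [default_study_config()]
#' @export
sim_config <- function(n_cases, csmf, confusion, reviewer_agreement,
                       arbiter_match, covariates = list(), p_extra_flag = 0.15,
                       seed = NULL) {
  cats <- sim_categories()
  if (length(n_cases) != 1 || n_cases < 1) abort("`n_cases` must be a positive count.")

  if (is.null(names(csmf)) || !setequal(names(csmf), cats)) {
    abort("`csmf` must be named over all assignable causes plus 'unexplained'.")
  }
  csmf <- csmf[cats]
  check_probability(csmf, "csmf")
  if (abs(sum(csmf) - 1) > 1e-8) abort("`csmf` must sum to 1.")

  if (!is.matrix(confusion) ||
      !setequal(rownames(confusion), cats) ||
      !setequal(colnames(confusion), c(cats, "unclassifiable"))) {
    abort(paste0(
      "`confusion` must have rows named by the true-cause categories and ",
      "columns by the same categories plus 'unclassifiable'."
    ))
  }
  confusion <- confusion[cats, c(cats, "unclassifiable")]
  check_probability(as.numeric(confusion), "confusion")
  if (any(abs(rowSums(confusion) - 1) > 1e-8)) {
    abort("Every `confusion` row must sum to 1.")
  }

  for (nm in c("reviewer_agreement", "arbiter_match")) {
    v <- get(nm)
    if (is.null(names(v)) || !setequal(names(v), c("reference", "va"))) {
      abort(sprintf("`%s` must be named c(reference = , va = ).", nm))
    }
    check_probability(v, nm)
  }
  reviewer_agreement <- reviewer_agreement[c("reference", "va")]
  arbiter_match <- arbiter_match[c("reference", "va")]

  p_unclass_va <- unname((1 - reviewer_agreement["va"]) * (1 - arbiter_match["va"]))
  if (any(abs(confusion[, "unclassifiable"] - p_unclass_va) > 1e-8)) {
    abort(paste0(
      "`confusion` column 'unclassifiable' must equal (1 - reviewer_agreement['va']) ",
      "* (1 - arbiter_match['va']) in every row for the adjudication ",
      "accounting to be consistent."
    ))
  }

  cov_defaults <- list(
    age_mean = 5.9, age_sd = 6.7,
    gestation_preterm_mean = 30.5, gestation_preterm_sd = 2.5,
    gestation_other_mean = 35.3, gestation_other_sd = 3.5,
    p_male = 0.596,
    birth_weight_mean = 2400, birth_weight_sd = 900
  )
  unknown <- setdiff(names(covariates), names(cov_defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown covariate parameter(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  covariates <- utils::modifyList(cov_defaults, covariates)
  check_probability(covariates$p_male, "covariates$p_male")
  check_probability(p_extra_flag, "p_extra_flag")

  structure(
    list(
      n_cases = as.integer(n_cases), csmf = csmf, confusion = confusion,
      reviewer_agreement = reviewer_agreement, arbiter_match = arbiter_match,
      covariates = covariates, p_extra_flag = p_extra_flag, seed = seed
    ),
    class = "vaval_config"
  )
}

#' Default configuration emulating the validation study
#'
#' Returns a [sim_config()] whose parameters reproduce the published study
#' conditions: the clinical CSMF profile over 626 deaths, confusion
#' diagonals equal to the per-cause VA sensitivities (e.g. 209/224 for
#' prematurity complications, 147/176 for birth asphyxia; the four
#' severe-infection members share the composite sensitivity 138/175),
#' reviewer consensus rates of 494/626 (hospital record) and 461/626 (VA),
#' and arbiter-match rates of 127/132 and 146/165. Off-diagonal
#' misclassification mass is spread over the other causes in proportion to
#' their CSMF. Causes without a published accuracy row (unexplained, other
#' specific, injuries) get a diagonal of 0.5.
#'
#' @param n_cases Cohort size; default 626.
#' @param seed Optional integer seed stored in the config.
#' @return A `vaval_config` object.
#' @export
default_study_config <- function(n_cases = 626, seed = NULL) {
  counts <- c(
    congenital_anomalies = 14, injuries = 0, birth_asphyxia = 176,
    tetanus = 9, sepsis = 162, meningitis = 1, pneumonia = 11, diarrhea = 1,
    prematurity_complications = 224, other_specific = 11, unexplained = 17
  )
  csmf <- counts[sim_categories()] / sum(counts)

  agreement <- c(reference = 494 / 626, va = 461 / 626)
  arb_match <- c(reference = 127 / 132, va = 146 / 165)
  p_unclass <- unname((1 - agreement["va"]) * (1 - arb_match["va"]))  # 19/626

  diag_sens <- c(
    congenital_anomalies = 8 / 14,
    injuries = 0.5,
    birth_asphyxia = 147 / 176,
    tetanus = 6 / 9,
    sepsis = 138 / 175, meningitis = 138 / 175,
    pneumonia = 138 / 175, diarrhea = 138 / 175,
    prematurity_complications = 209 / 224,
    other_specific = 0.5,
    unexplained = 0.5
  )[sim_categories()]

  cats <- sim_categories()
  confusion <- matrix(
    0, length(cats), length(cats) + 1,
    dimnames = list(cats, c(cats, "unclassifiable"))
  )
  for (i in cats) {
    confusion[i, i] <- diag_sens[i]
    confusion[i, "unclassifiable"] <- p_unclass
    rest <- 1 - diag_sens[i] - p_unclass
    w <- csmf[setdiff(cats, i)]
    if (sum(w) > 0) {
      confusion[i, setdiff(cats, i)] <- rest * w / sum(w)
    } else {
      confusion[i, setdiff(cats, i)] <- rest / (length(cats) - 1)
    }
  }

  sim_config(
    n_cases = n_cases, csmf = csmf, confusion = confusion,
    reviewer_agreement = agreement, arbiter_match = arb_match, seed = seed
  )
}

#' @export
print.vaval_config <- function(x, ...) {
  cat(sprintf("Synthetic VA cohort configuration: %d cases\n", x$n_cases))
  cat("CSMF:\n")
  print(round(x$csmf, 4))
  cat(sprintf(
    "Reviewer agreement: reference %.3f, va %.3f; arbiter match: %.3f / %.3f\n",
    x$reviewer_agreement["reference"], x$reviewer_agreement["va"],
    x$arbiter_match["reference"], x$arbiter_match["va"]
  ))
  invisible(x)
}

# truncated-normal sampler by rejection (keeps no boundary atoms);
# lo/hi may be vectors of length n
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo[need] & x < hi[need]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# covariates drawn with the per-cause constraints that keep each intended
# cause inside a hierarchy stratum that can produce it:
#   asphyxia: age < 7 (the hierarchy's age condition in the >=3d strata)
#   tetanus: age >= 3 (tetanus only appears in the >=3d strata)
#   other_specific: gestation >= 32 (only in the >=32w strata)
#   infection members with age < 3: gestation >= 32 (no infection slot in
#     the <3d & <32w stratum)
#   prematurity: gestation < 33 (clinical definition of the prematurity row)
draw_covariates <- function(true_cause, cov) {
  n <- length(true_cause)
  age_lo <- ifelse(true_cause == "tetanus", 3, 0)
  age_hi <- ifelse(true_cause == "birth_asphyxia", 6, 28)
  age <- floor(rtrunc_norm(n, cov$age_mean, cov$age_sd, age_lo, age_hi + 1))

  preterm <- true_cause == "prematurity_complications"
  need_ge32 <- true_cause == "other_specific" |
    (true_cause %in% severe_infection_causes() & age < 3)
  gest <- numeric(n)
  gest[preterm] <- rtrunc_norm(sum(preterm), cov$gestation_preterm_mean,
                               cov$gestation_preterm_sd, 24, 32.9)
  gest[!preterm & need_ge32] <- rtrunc_norm(
    sum(!preterm & need_ge32), cov$gestation_other_mean,
    cov$gestation_other_sd, 32, 43
  )
  other <- !preterm & !need_ge32
  gest[other] <- rtrunc_norm(sum(other), cov$gestation_other_mean,
                             cov$gestation_other_sd, 24, 43)

  tibble(
    age_at_death_days = as.integer(age),
    gestation_weeks = round(gest, 1),
    sex = ifelse(runif(n) < cov$p_male, "male", "female"),
    birth_weight_g = round(rtrunc_norm(n, cov$birth_weight_mean,
                                       cov$birth_weight_sd, 500, 5500))
  )
}

# eligibility-flag matrix: the intended cause's flag is set, every
# higher-priority flag in the case's stratum is clear, and lower-priority
# flags are set with probability p_extra (they never alter the first match).
build_eligibility <- function(true_cause, stratum, p_extra) {
  n <- length(true_cause)
  elig <- matrix(FALSE, n, length(assignable_causes()),
                 dimnames = list(NULL, assignable_causes()))
  plan <- expanded_hierarchy()
  for (s in unique(stratum)) {
    ord <- plan$cause[plan$stratum == s]
    in_s <- which(stratum == s)
    for (cc in unique(true_cause[in_s])) {
      rows <- in_s[true_cause[in_s] == cc]
      if (cc == "unexplained") next
      pos <- match(cc, ord)
      if (is.na(pos)) {
        abort(sprintf("Internal error: cause %s not reachable in stratum %s.", cc, s))
      }
      elig[rows, cc] <- TRUE
      lower <- ord[seq_along(ord) > pos]
      if (length(lower) > 0 && p_extra > 0) {
        extra <- matrix(runif(length(rows) * length(lower)) < p_extra,
                        nrow = length(rows))
        elig[rows, lower] <- elig[rows, lower] | extra
      }
    }
  }
  elig
}

# sample one label per row of a probability matrix, grouped by row name
sample_by_row <- function(keys, prob_matrix) {
  out <- character(length(keys))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    out[idx] <- sample(colnames(prob_matrix), length(idx), replace = TRUE,
                       prob = prob_matrix[k, ])
  }
  out
}

# build the long reviewer table realising the given finals and resolution
# paths; reviewer calls are assignable-or-unexplained, never unclassifiable.
build_reviews <- function(case_id, final, path, reviewer_prefix, csmf) {
  cats <- names(csmf)
  n <- length(final)
  r1 <- character(n); r2 <- character(n)
  arb <- rep(NA_character_, n)

  cons <- path == "consensus"
  r1[cons] <- final[cons]
  r2[cons] <- final[cons]

  arbr <- path == "arbiter"
  if (any(arbr)) {
    # the dissenting reviewer calls some other cause, weighted by the CSMF
    dissent <- vapply(final[arbr], function(f) {
      w <- csmf[setdiff(cats, f)]
      if (sum(w) == 0) w <- rep(1, length(w))
      sample(setdiff(cats, f), 1, prob = w)
    }, character(1))
    keep_first <- runif(sum(arbr)) < 0.5
    r1[arbr] <- ifelse(keep_first, final[arbr], dissent)
    r2[arbr] <- ifelse(keep_first, dissent, final[arbr])
    arb[arbr] <- final[arbr]
  }

  alld <- path == "all_differ"
  if (any(alld)) {
    trio <- t(vapply(which(alld), function(i) {
      w <- csmf
      if (sum(w) == 0) w <- rep(1, length(w))
      sample(cats, 3, prob = w)
    }, character(3)))
    r1[alld] <- trio[, 1]
    r2[alld] <- trio[, 2]
    arb[alld] <- trio[, 3]
  }

  primary <- tibble(
    case_id = rep(case_id, 2),
    reviewer_id = rep(paste0(reviewer_prefix, 1:2), each = n),
    round = "primary",
    cause = c(r1, r2)
  )
  arbiter <- tibble(
    case_id = case_id[!is.na(arb)],
    reviewer_id = paste0(reviewer_prefix, 3),
    round = "arbiter",
    cause = arb[!is.na(arb)]
  )
  dplyr::arrange(dplyr::bind_rows(primary, arbiter), .data$case_id,
                 .data$round, .data$reviewer_id)
}

#' Simulate a paired reference/VA validation cohort
#'
#' Generates, for `config$n_cases` deaths: a case-record table with
#' covariates and eligibility flags (from which [assign_causes()] exactly
#' reproduces each true cause), reference and VA reviewer tables whose
#' adjudication reproduces the configured consensus / arbiter / all-differ
#' rates, and the underlying truth table. The final adjudicated VA label of
#' a classifiable case is drawn from the configured confusion row of its
#' true cause, so the full pipeline recovers the configured confusion
#' diagonals as per-cause sensitivities.
#'
#' @param config A `vaval_config` from [sim_config()] or
#'   [default_study_config()].
#' @param seed Integer seed (required here or in `config$seed`); the
#'   simulation is fully reproducible given the seed.
#' @return An object of class `vaval_cohort`: a list of tibbles `cases`,
#'   `reference_reviews`, `va_reviews`, `truth` (columns `case_id`,
#'   `true_cause`, `reference_final`, `va_final`).
#' @examples
#' cohort <- simulate_cohort(default_study_config(n_cases = 100), seed = 1)
#' names(cohort)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "vaval_config")) {
    abort("`config` must be a `vaval_config` object; see sim_config().")
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("A `seed` is required (argument or config$seed).")
  set.seed(seed)

  n <- config$n_cases
  case_id <- sprintf("case_%06d", seq_len(n))
  cats <- sim_categories()

  true_cause <- sample(cats, n, replace = TRUE, prob = config$csmf)
  covs <- draw_covariates(true_cause, config$covariates)
  stratum <- stratum_of(covs$age_at_death_days, covs$gestation_weeks)
  elig <- build_eligibility(true_cause, stratum, config$p_extra_flag)

  draw_path <- function(a, m, n) {
    sample(c("consensus", "arbiter", "all_differ"), n, replace = TRUE,
           prob = c(a, (1 - a) * m, (1 - a) * (1 - m)))
  }

  # reference side: the adjudicated label is the true cause unless all
  # three reviewers differ
  ref_path <- draw_path(config$reviewer_agreement["reference"],
                        config$arbiter_match["reference"], n)
  ref_final <- ifelse(ref_path == "all_differ", "unclassifiable", true_cause)

  # VA side: the confusion row already carries the unclassifiable mass, so
  # the resolution path is derived from the drawn final label
  va_final <- sample_by_row(true_cause, config$confusion)
  a_va <- unname(config$reviewer_agreement["va"])
  p_unclass <- unname((1 - a_va) * (1 - config$arbiter_match["va"]))
  p_cons_given_class <- if (p_unclass < 1) a_va / (1 - p_unclass) else 0
  va_path <- ifelse(
    va_final == "unclassifiable", "all_differ",
    ifelse(runif(n) < p_cons_given_class, "consensus", "arbiter")
  )

  cases <- dplyr::bind_cols(
    tibble(case_id = case_id),
    covs,
    tibble(source = "hospital"),
    as_tibble(elig) |> setNames(paste0("elig_", colnames(elig)))
  )

  structure(
    list(
      cases = cases,
      reference_reviews = build_reviews(case_id, ref_final, ref_path, "H",
                                        config$csmf),
      va_reviews = build_reviews(case_id, va_final, va_path, "V",
                                 config$csmf),
      truth = tibble(
        case_id = case_id, true_cause = true_cause,
        reference_final = ref_final, va_final = va_final
      )
    ),
    class = "vaval_cohort"
  )
}

#' @export
print.vaval_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic VA validation cohort: %d cases, %d reference and %d VA review rows\n",
    nrow(x$cases), nrow(x$reference_reviews), nrow(x$va_reviews)
  ))
  invisible(x)
}
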