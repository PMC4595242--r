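make_pairs <- function(ref, va) {
  tibble::tibble(
    case_id = as.character(seq_along(ref)),
    reference_cause = ref, va_cause = va
  )
}

test_that("paired_labels joins on case_id and rejects mismatches", {
  ref <- tibble::tibble(case_id = c("a", "b"), final_cause = c("sepsis", "tetanus"))
  va <- tibble::tibble(case_id = c("b", "a"), final_cause = c("sepsis", "sepsis"))
  out <- paired_labels(ref, va)
  expect_equal(nrow(out), 2)
  expect_equal(out$va_cause[out$case_id == "b"], "sepsis")

  expect_error(
    paired_labels(ref, tibble::tibble(case_id = "z", final_cause = "sepsis")),
    "mismatch"
  )
  expect_error(
    paired_labels(dplyr::bind_rows(ref, ref), va), "Duplicate"
  )
  one <- tibble::tibble(case_id = "a", final_cause = "sepsis")
  expect_equal(nrow(paired_labels(one, one)), 1)
})

test_that("contingency counts match an exhaustive per-case comparison", {
  # six-case fixture with known labels
  pairs <- make_pairs(
    ref = c("sepsis", "sepsis", "tetanus", "pneumonia", "unexplained",
            "birth_asphyxia"),
    va = c("sepsis", "tetanus", "tetanus", "sepsis", "pneumonia",
           "unclassifiable")
  )
  targets <- c(assignable_causes(), "severe_infection")
  got <- contingency(pairs, targets)
  for (i in seq_len(nrow(got))) {
    t <- got$cause[i]
    members <- if (t == "severe_infection") severe_infection_causes() else t
    rp <- pairs$reference_cause %in% members
    vp <- pairs$va_cause %in% members
    expect_equal(got$tp[i], sum(rp & vp))
    expect_equal(got$fp[i], sum(!rp & vp))
    expect_equal(got$tn[i], sum(!rp & !vp))
    expect_equal(got$fn[i], sum(rp & !vp))
  }
  # count conservation and composite dominance
  expect_true(all(got$tp + got$fp + got$tn + got$fn == nrow(pairs)))
  sev <- got[got$cause == "severe_infection", ]
  for (m in severe_infection_causes()) {
    expect_gte(sev$tp, got$tp[got$cause == m])
  }
})

test_that("contingency is exact on random pair sets", {
  set.seed(77)
  labels <- c(assignable_causes(), "unexplained", "unclassifiable")
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    pairs <- make_pairs(sample(labels, n, TRUE), sample(labels, n, TRUE))
    target <- sample(c(assignable_causes(), "severe_infection"), 1)
    got <- contingency(pairs, target)
    members <- if (target == "severe_infection") severe_infection_causes() else target
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      r <- pairs$reference_cause[i] %in% members
      v <- pairs$va_cause[i] %in% members
      if (r && v) tp <- tp + 1
      if (!r && v) fp <- fp + 1
      if (!r && !v) tn <- tn + 1
      if (r && !v) fn <- fn + 1
    }
    expect_equal(unlist(got[, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  # a perfect test has no false calls
  perfect <- make_pairs(rep("sepsis", 4), rep("sepsis", 4))
  got <- contingency(perfect, "sepsis")
  expect_equal(got$fp + got$fn, 0)
})

test_that("score_interval matches the score interval of prop.test", {
  set.seed(88)
  for (rep in 1:25) {
    n <- sample(5:600, 1)
    x <- sample(0:n, 1)
    ci <- score_interval(x, n)
    ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(ci$lower, ref[1], tolerance = 1e-8)
    expect_equal(ci$upper, ref[2], tolerance = 1e-8)
  }
  expect_equal(score_interval(0, 10)$lower, 0, tolerance = 1e-12)
  expect_equal(score_interval(10, 10)$upper, 1, tolerance = 1e-12)
  expect_error(score_interval(1, 0), "positive")
  expect_error(score_interval(5, 3), "successes")
})

test_that("diagnostic_accuracy computes the four standard ratios", {
  acc <- diagnostic_accuracy(
    tibble::tibble(cause = "birth_asphyxia", tp = 147, fp = 41, tn = 409, fn = 29)
  )
  expect_equal(acc$sensitivity, 147 / 176)
  expect_equal(acc$specificity, 409 / 450)
  expect_equal(acc$ppv, 147 / 188)
  expect_equal(acc$npv, 409 / 438)
  # estimates sit inside their intervals, intervals inside [0, 1]
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_gte(acc[[m]], acc[[paste0(m, "_low")]])
    expect_lte(acc[[m]], acc[[paste0(m, "_high")]])
    expect_gte(acc[[paste0(m, "_low")]], 0)
    expect_lte(acc[[paste0(m, "_high")]], 1)
  }
  # perfect test
  perf <- diagnostic_accuracy(
    tibble::tibble(cause = "sepsis", tp = 7, fp = 0, tn = 13, fn = 0)
  )
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # zero denominators (both sensitivity and ppv here) -> NA with one
  # warning per undefined metric, not 0
  expect_warning(
    expect_warning(
      und <- diagnostic_accuracy(
        tibble::tibble(cause = "tetanus", tp = 0, fp = 0, tn = 10, fn = 0)
      ),
      "Zero denominator"
    ),
    "Zero denominator"
  )
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$ppv))
  expect_equal(und$specificity, 1)
})

test_that("csmf fractions are counts over total and sum to one", {
  out <- csmf(c("sepsis", "sepsis", "birth_asphyxia", "unexplained"))
  expect_equal(sum(out$fraction), 1)
  expect_equal(out$n[out$cause == "sepsis"], 2)
  expect_equal(out$fraction[out$cause == "sepsis"], 0.5)
  single <- csmf(rep("tetanus", 5))
  expect_equal(single$fraction, 1)
  expect_error(csmf(character(0)), "non-empty")
  expect_error(csmf(c("sepsis", "ASPHIXIA")), "ASPHIXIA")
})

test_that("overall agreement is the fraction of identical labels", {
  expect_equal(overall_agreement(make_pairs(c("a1", "a1"), c("a1", "a1")) |>
    dplyr::mutate(reference_cause = "sepsis", va_cause = "sepsis")), 1)
  disc <- make_pairs(c("sepsis", "tetanus"), c("tetanus", "sepsis"))
  expect_equal(overall_agreement(disc), 0)
  half <- make_pairs(c("sepsis", "tetanus"), c("sepsis", "pneumonia"))
  expect_equal(overall_agreement(half), 0.5)
})

test_that("chi-square matches the textbook Pearson formula", {
  # independent table -> statistic 0
  ind <- tibble::tibble(tp = 10, fp = 10, tn = 10, fn = 10)
  expect_equal(chi_square_2x2(ind)$statistic, 0)

  counts <- tibble::tibble(cause = "birth_asphyxia",
                           tp = 147, fp = 41, tn = 409, fn = 29)
  got <- chi_square_2x2(counts, correct = FALSE)
  # direct formula oracle: sum (O - E)^2 / E over the 2x2 cells
  o <- matrix(c(147, 41, 29, 409), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(got$statistic, sum((o - e)^2 / e), tolerance = 1e-10)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))

  # Yates correction shrinks the statistic
  yates <- chi_square_2x2(counts, correct = TRUE)
  expect_lt(yates$statistic, got$statistic)

  expect_error(
    chi_square_2x2(tibble::tibble(tp = 20, fp = 20, tn = 0, fn = 0)),
    "Degenerate"
  )
  expect_warning(
    chi_square_2x2(tibble::tibble(tp = 2, fp = 3, tn = 30, fn = 2)),
    "below 5"
  )
})

test_that("va_accuracy ties the pieces together with tidy/glance", {
  set.seed(99)
  labels <- c(assignable_causes(), "unexplained")
  pairs <- make_pairs(sample(labels, 300, TRUE), sample(labels, 300, TRUE))
  fit <- suppressWarnings(va_accuracy(pairs))
  expect_s3_class(fit, "va_accuracy")
  td <- tidy(fit)
  expect_setequal(unique(td$metric), c("sensitivity", "specificity", "ppv", "npv"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high,
                  na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$n_pairs, 300)
  expect_equal(gl$overall_agreement, overall_agreement(pairs))
})
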