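---
title: "Methods: validating verbal autopsy diagnoses of neonatal death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating verbal autopsy diagnoses of neonatal death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaval)
library(dplyr)
```

## The problem

In settings where most neonatal deaths occur outside health facilities,
cause-of-death statistics depend on *verbal autopsy* (VA): a structured
interview with the caregiver, later reviewed by physicians who assign a
cause. Before VA-derived cause distributions can be trusted, the
instrument must be validated against a reference standard — deaths that
occurred in hospital, where a cause could be established from clinical
records, laboratory results and direct observation.

`vaval` implements one complete validation design of this kind:

1. **Cause assignment by hierarchy.** Each reviewed death receives a
   single primary cause, chosen by scanning a fixed, stratified priority
   list of case definitions and stopping at the first one the case
   satisfies (`assign_causes()`).
2. **Blinded dual review with arbitration.** Two reviewers
   independently assign a cause from the same source material; a third
   arbiter resolves discrepancies; if all three differ the death is
   *unclassifiable* (`adjudicate()`).
3. **Accuracy against the reference.** With a final VA cause and a
   final clinical cause per death, the package computes per-cause
   sensitivity, specificity and predictive values with score confidence
   intervals, cause-specific mortality fractions (CSMF), overall
   agreement and chi-square comparisons (`va_accuracy()`,
   `csmf_compare()`, `run_pipeline()`).
4. **A synthetic cohort generator** that emulates the misclassification
   and reviewer-disagreement structure of such a study, so the entire
   pipeline can be exercised and tested without patient data
   (`simulate_cohort()`).

## The cause taxonomy

Ten assignable causes are recognised:

```{r}
va_causes()
```

Two labels are terminal rather than assignable: `unexplained` (a
reviewer examined the case and no case definition fit) and
`unclassifiable` (the adjudication process itself failed to converge).
Reviewers may record `unexplained`; only `adjudicate()` may produce
`unclassifiable`.

Four causes — sepsis, meningitis, pneumonia and diarrhea — are members
of a composite *severe infection* category. In the hierarchy they
occupy a single slot; within that slot the member priority is sepsis >
meningitis > pneumonia > diarrhea. In accuracy calculations
`"severe_infection"` may be used as a target, in which case any member
counts as positive.

## The assignment hierarchy

Cases are stratified by **age at death** (< 3 vs ≥ 3 completed days)
and **gestation** (< 32 vs ≥ 32 completed weeks); both boundaries are
strict on the left (age 3 falls in the ≥ 3 stratum, gestation 32.0 in
the ≥ 32 stratum). Each stratum has its own priority ordering:

```{r}
hierarchy_table()
```

Design choices worth noting:

* **Congenital anomalies, injuries and asphyxia head every stratum, in
  that order** — a lethal malformation or trauma is causally prior to
  whatever else the infant had.
* **Birth asphyxia carries an age condition (death before day 7) only
  in the ≥ 3-day strata.** In the < 3-day strata the condition is
  vacuous and is therefore not encoded (`age_lt_days = NA`).
* **The strata differ in which causes are considered at all.** A death
  before day 3 in a very preterm infant can only be a malformation,
  injury, asphyxia or prematurity; tetanus requires survival to day 3,
  and "other specific cause" is only reachable at ≥ 32 weeks.
  Prematurity complications sit at or near the bottom of every list —
  the diagnosis of exclusion among eligible causes.
* If no eligible cause is found, the assigned cause is `unexplained`.

Two policy switches are exposed rather than hard-coded, because
reasonable designs differ here:

* `collapse_lt34 = FALSE` (default): an optional rule reassigns birth
  asphyxia to prematurity complications when gestation is below a
  threshold (default 34 weeks), reflecting the view that "asphyxia" in
  a very preterm infant is usually a manifestation of immaturity. It is
  **off by default** because the published accuracy figures this
  package is tested against were produced without it; note the three
  distinct gestation thresholds in play (32 for stratification, 33
  completed weeks ≈ < 34 for collapsing) are deliberately kept separate
  parameters.
* `missing_gestation = "error"` (default): gestation is required for
  stratification. The alternatives `"assume_ge32"` and `"assume_lt32"`
  let the user impute a stratum when gestational age is unrecorded,
  which is common for home births; we refuse to pick a default
  imputation silently.

## Adjudication

`resolve_cases(r1, r2, arbiter)` implements the two-of-three rule per
case:

| situation | final cause | resolution |
|---|---|---|
| reviewers agree | their cause | `consensus` |
| reviewers differ, arbiter matches one | that cause | `arbiter_agrees_r1` / `_r2` |
| all three differ | `unclassifiable` | `unclassifiable` |

The function is symmetric in the two reviewers and never invents a
cause: the final label is always one of the three opinions, or
`unclassifiable`. An arbiter opinion on a consensus case is ignored
with a warning; a missing arbiter on a discrepant case is an error —
silence would bias agreement statistics upward.

`summarize_adjudication()` reports the consensus accounting
(`n_consensus`, `n_arbiter_agrees_one`, `n_all_differ`,
`pct_consensus`) that is the standard headline of reviewer reliability
in this literature.

## Accuracy statistics

For each target cause, `contingency()` reduces the paired final
diagnoses to a 2×2 table — positive means "final cause is the target"
(or any member, for the composite); terminal labels are negative for
every target. `diagnostic_accuracy()` then computes

$$
\text{sens} = \frac{TP}{TP+FN},\quad
\text{spec} = \frac{TN}{TN+FP},\quad
\text{PPV} = \frac{TP}{TP+FP},\quad
\text{NPV} = \frac{TN}{TN+FN},
$$

with a zero denominator yielding `NA` plus a warning rather than a
silent 0.

### Why the Wilson score interval

Confidence intervals use the **Wilson score interval without continuity
correction**,

$$
\frac{\hat p + \frac{z^2}{2n} \pm z\sqrt{\frac{\hat p(1-\hat p)}{n} + \frac{z^2}{4n^2}}}
     {1 + \frac{z^2}{n}},
$$

hand-implemented in `score_interval()` because the choice of interval
is substantive, not incidental. The study sizes here put several
estimates near the boundary (specificities around 0.97–0.99, a
sensitivity of 6/9), where the Wald interval is badly anti-conservative
and can escape [0, 1]; the Wilson interval reproduces the published
bounds of the reference study to the last printed digit, while Wald
misses by up to ~0.7 percentage points. The test suite cross-checks
`score_interval()` against `stats::prop.test(correct = FALSE)` and
verifies its empirical coverage by simulation (about 95.3% at
$n = 176$, $p = 0.8$).

### Rounding

Published tables in this field print percentages to one decimal using
**half-up** rounding (0.05 rounds to 0.1). R's `round()` is
round-half-even, so the package exports `round_half_up()` and uses it
everywhere a printed percentage is produced (reports, JSON output,
`pct_consensus`). Internal fractions are never pre-rounded.

### Chi-square

`chi_square_2x2()` delegates to `stats::chisq.test` (Yates correction
off by default, matching common practice in validation papers, and
switchable via `correct = TRUE`). A degenerate margin is an error; an
expected cell below 5 triggers a warning.

## The synthetic cohort generator

`simulate_cohort()` produces a cohort whose *observable* statistics —
CSMF, per-cause sensitivity, consensus rates, arbitration rates —
track a configurable target, while every individual case remains fully
consistent with the assignment hierarchy. `default_study_config()`
encodes rates typical of a hospital-based neonatal VA validation study
(626 deaths, prematurity ≈ 36% and sepsis ≈ 26% of deaths, VA
sensitivities of roughly 0.93 for prematurity, 0.84 for asphyxia, 0.79
for severe infection, consensus rates near 79% for clinical review and
74% for VA review).

### Generative model

For each case:

1. **True cause** is drawn from the configured CSMF over the ten
   assignable causes plus `unexplained`.
2. **Covariates** (age at death, gestation, sex, birth weight) are
   drawn from truncated normals whose bounds are *constrained by the
   true cause* so that the cause is reachable in the case's stratum:
   asphyxia deaths get age 0–6, tetanus age ≥ 3, prematurity deaths get
   gestation below 32 weeks, and infection deaths before day 3 are kept
   at ≥ 32 weeks (the < 3-day, < 32-week stratum has no infection
   slot).
3. **Eligibility flags** are built so that `assign_causes()` recovers
   the true cause exactly: the true cause's flag is on, every
   higher-priority flag in the case's stratum is off, and each
   lower-priority flag is on independently with probability
   `p_extra_flag` (default 0.15) to make the first-match scan do real
   work.
4. **Final VA cause** is drawn from the confusion-matrix row of the
   true cause. The matrix has 11 rows (assignable + unexplained) and a
   12th *column* for `unclassifiable`: each row's unclassifiable mass
   must equal $(1 - a)(1 - m)$, where $a$ is the VA reviewer-agreement
   probability and $m$ the arbiter-match probability. `sim_config()`
   validates this identity.
5. **Review triples** are then generated *conditional on* the drawn
   final cause: if it is `unclassifiable`, three distinct causes are
   drawn; otherwise the case is a consensus with probability
   $a / (1 - (1-a)(1-m))$ and an arbiter-resolved discrepancy
   otherwise, with the dissenting opinion drawn from the CSMF excluding
   the final cause. The clinical (reference) side works the same way
   with its own agreement parameters, except its final cause equals the
   true cause unless the all-differ path fires.

Step 4–5's ordering is the key design decision. A naive generator that
first simulates three reviewer opinions and then adjudicates them would
make the *realised* final cause differ from the confusion-row draw
whenever adjudication fails, deflating recovered sensitivities by a
factor of $1 - (1-a)(1-m)$ — about 3% here, which is far outside Monte
Carlo noise at $n = 10{,}000$. Drawing the final label first and the
resolution path second makes pipeline-recovered sensitivity equal the
configured diagonal in expectation, so the generator is testable
against its own configuration. Off-diagonal confusion mass is spread
over the other causes proportionally to their CSMF — a simplification;
real misclassification is structured (asphyxia ↔ prematurity in very
preterm infants, sepsis ↔ pneumonia), and nothing in the package
depends on this choice.

### What the generator does not emulate

* Birth weight is drawn independently of gestation; in reality they are
  strongly correlated. No package statistic uses birth weight, so the
  simplification is harmless here.
* Reviewer opinions within a discrepancy are exchangeable; real
  reviewers have systematic individual biases.
* The two infection members without published per-member accuracy are
  given the composite's diagonal, and causes too rare to estimate
  (injuries, other specific, unexplained) get a diagonal of 0.5 — a
  deliberately uninformative default.
* Deaths are independent; there is no facility- or season-level
  clustering.

### Problem sizes

The default cohort size (626) matches the scale of the motivating
study. Recovery tests use $n = 10{,}000$, chosen so that the Monte
Carlo standard error of a sensitivity around 0.85 on ~2,800 positives
is below 0.7 percentage points — small enough that a 3% generator bias
would be caught, large enough to run in seconds. Coverage checks use
5,000 replicate intervals, giving a standard error on the coverage
estimate of about 0.3 percentage points against an acceptance window of
±1.5. These sizes are this package's own testing choices, not features
of any study design.

## A worked run

```{r}
cfg <- default_study_config(n_cases = 626)
cohort <- simulate_cohort(cfg, seed = 42)
report <- run_pipeline(cohort$reference_reviews, cohort$va_reviews)
report
```

The report object supports `tidy()`, `glance()` and `autoplot()`:

```{r, fig.width = 7, fig.height = 4}
glance(report$accuracy)
autoplot(report$accuracy)
```

`write_validation_report(report, dir)` exports `accuracy.csv`,
`csmf.csv`, `adjudication.csv` and a machine-readable `report.json`.
The same pipeline is scriptable from the shell via
`system.file("scripts", "vaval.R", package = "vaval")`.
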