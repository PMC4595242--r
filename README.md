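# vaval

Validation of verbal autopsy (VA) cause-of-death assignment for
neonatal deaths.

## The problem

Where most neonatal deaths happen at home, cause-of-death statistics
come from *verbal autopsy*: a structured caregiver interview reviewed
by physicians who assign a cause. Before those causes can inform
policy, the instrument must be validated against deaths with a known
clinical cause. `vaval` implements a complete hospital-based validation
pipeline:

* **Hierarchical cause assignment** — each death gets a single primary
  cause by scanning a fixed priority list of case definitions,
  stratified by age at death (< 3 vs ≥ 3 days) and gestation (< 32 vs
  ≥ 32 weeks), and stopping at the first match.
* **Blinded dual review with arbitration** — two independent reviewers
  per death; a third arbiter settles discrepancies; if all three
  disagree the death is *unclassifiable*.
* **Diagnostic accuracy** — per-cause sensitivity, specificity, PPV and
  NPV against the clinical reference, each with a 95% Wilson score
  confidence interval:

  sens = TP/(TP+FN), spec = TN/(TN+FP), PPV = TP/(TP+FP),
  NPV = TN/(TN+FN)

  plus cause-specific mortality fractions (CSMF), overall cause
  agreement, and chi-square comparisons of the 2×2 tables.
* **A synthetic cohort generator** that emulates the misclassification
  and reviewer-agreement structure of such a study, so the whole
  pipeline runs and is tested without patient data.

The methods vignette (`vignettes/va-validation-methods.Rmd`) documents
the model, every tunable parameter, and the generator's design and
limitations.

## Worked example

Assign causes through the hierarchy:

```r
library(vaval)

cases <- tibble::tibble(
  case_id = c("a", "b"),
  age_at_death_days = c(1, 5),
  gestation_weeks = c(30, 38),
  elig_birth_asphyxia = c(TRUE, TRUE),
  elig_prematurity_complications = c(TRUE, FALSE)
)
assign_causes(cases)
#> # A tibble: 2 × 4
#>   case_id assigned_cause stratum  collapse_applied
#>   <chr>   <chr>          <chr>    <lgl>
#> 1 a       birth_asphyxia lt3_lt32 FALSE
#> 2 b       birth_asphyxia ge3_ge32 FALSE
```

Asphyxia outranks prematurity in every stratum, so case `a` is
asphyxia even at 30 weeks. The optional collapse rule (off by default)
reassigns asphyxia to prematurity complications below 34 weeks:

```r
assign_causes(cases, collapse_lt34 = TRUE)
#> # A tibble: 2 × 4
#>   case_id assigned_cause            stratum  collapse_applied
#>   <chr>   <chr>                     <chr>    <lgl>
#> 1 a       prematurity_complications lt3_lt32 TRUE
#> 2 b       birth_asphyxia            ge3_ge32 FALSE
```

Run the full pipeline on a synthetic cohort of 626 deaths:

```r
cfg <- default_study_config(n_cases = 626)
cohort <- simulate_cohort(cfg, seed = 42)
report <- run_pipeline(cohort$reference_reviews, cohort$va_reviews)
report
#> == Accuracy ==
#> Verbal autopsy diagnostic accuracy (626 paired cases, 95% CI)
#> Overall cause agreement: 82.1%
#>
#>                      cause       sensitivity       specificity
#>       congenital_anomalies  52.6 (31.7-72.7)  99.0 (97.9-99.5)
#>  prematurity_complications  93.6 (89.7-96.1)  90.3 (86.9-92.8)
#>             birth_asphyxia  83.5 (77.2-88.4)  95.0 (92.5-96.6)
#>                    tetanus  55.6 (26.7-81.1)  99.4 (98.3-99.7)
#>           severe_infection  79.2 (72.1-84.9)  96.2 (94.1-97.6)
#>                ppv               npv
#>   62.5 (38.6-81.5)  98.5 (97.2-99.2)
#>   85.3 (80.4-89.1)  95.9 (93.4-97.5)
#>   86.1 (80.0-90.5)  93.9 (91.4-95.8)
#>   55.6 (26.7-81.1)  99.4 (98.3-99.7)
#>   87.1 (80.6-91.7)  93.4 (90.9-95.3)
```

(The report also prints adjudication and CSMF tables, elided here.)
The objects are tidyverse-friendly — `tidy()`, `glance()` and
`autoplot()` methods are provided:

```r
glance(report$accuracy)
#> # A tibble: 1 × 4
#>   n_pairs n_causes overall_agreement confidence
#>     <int>    <int>             <dbl>      <dbl>
#> 1     626        5             0.821       0.95
```

Confidence intervals are Wilson score intervals (no continuity
correction), implemented in `score_interval()`:

```r
score_interval(147, 176)   # 83.5% sensitivity on 176 positives
#> # A tibble: 1 × 2
#>   lower upper
#>   <dbl> <dbl>
#> 1 0.773 0.883
```

`write_validation_report(report, dir)` exports CSV tables and a
machine-readable JSON report. A thin command-line interface with
`assign`, `adjudicate`, `validate`, `simulate` and `run` subcommands is
installed at `system.file("scripts", "vaval.R", package = "vaval")`.

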