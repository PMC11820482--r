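# wbq — Water Balance Questionnaire scoring and cohort analysis

`wbq` is an R package for researchers who estimate daily water turnover in
epidemiological cohorts with the Water Balance Questionnaire (WBQ), a
semi-quantitative instrument recording consumption frequencies, excretion
scales and 7-day activity recall. The package turns raw questionnaire
responses into per-respondent water profiles and reproduces the full
cross-sectional analysis workflow built around them — and, because raw WBQ
survey data is typically not publicly deposited, it ships a synthetic-cohort
generator with a plantable effect structure so the entire pipeline can be
validated end to end without any external data.

## The model at its core

Water balance, in mL/day, is net intake minus net loss:

    balance = (W_foods + W_beverages + W_water) − (W_urine + W_feces + W_sweat)

Respiratory loss and metabolic water cancel and are omitted. Consumption
frequencies on the instrument's six-level scale are recoded to mean daily
frequencies (0, 0.066, 0.214, 0.643, 1, 2.5 times/day); water from foods and
beverages is frequency × serving size × water fraction, summed over items;
excretion and sweat scales are configurable mL/day lookups; exercise sweat
adds (weekly hours / 7) × class base rate × scale multiplier over vigorous,
moderate and walking activity. Derived covariates include BMI (+ WHO class),
beverage variety (count of consumed categories, dichotomized at the median
cutoff of 3) and MET·min/week activity.

The analysis stage provides normality-aware gender comparisons (chi-square /
Welch t / Wilcoxon), univariate OLS screens of balance determinants, a
logistic missingness screen, multiple imputation by chained equations
(implemented in-package: Bayesian linear, logistic and multinomial
conditional draws), Rubin's-rules pooling, backward-AIC model selection with
a significance-reduced refit (the "Model 1 → 2 → 3" sequence), VIF/residual
diagnostics and a noncentral-F sample-size calculator.

## Worked example

```r
library(wbq)

spec   <- cohort_spec(n = 208, seed = 42)   # planted effects: the defaults
cohort <- generate_cohort(spec)             # raw questionnaire answers
scored <- score_wbq(cohort)                 # water profile per respondent

round(sapply(scored[c("intake_total", "loss_total", "balance")], median), 1)
#> intake_total   loss_total      balance
#>       2286.6       3105.6       -797.8

ad  <- analysis_data(scored)                             # reference coding
inj <- inject_missingness(ad, spec$missingness, seed = 43)  # 10% MAR
imp <- impute_chained(inj$data, m = 20, maxit = 10, seed = 44)
fit_model(imp, c("education_years", "work_hours_week", "glass_during_day",
                 "bottle_during_day", "water_for_pleasure"))
#> Pooled linear model (m = 20 imputations), n = 208
#>                   term  estimate      se        p
#>            (Intercept) -2317.472 790.288 0.003900
#>        education_years   -51.943  35.822 0.149000
#>        work_hours_week    37.217  10.372 0.000435
#>    glass_during_dayyes   123.123 251.369 0.625000
#>   bottle_during_dayyes   780.780 293.352 0.008430
#>  water_for_pleasureyes   240.727 218.704 0.273000
#> Adjusted R-squared: 0.089   RMSE: 1464.39
```

One cohort of 208 is noisy — the pooled estimates scatter around the planted
values (education −21.88, work hours 30.17, glass 423.13, bottle 873.50,
pleasure 478.63 mL/day; residual SD 1377.49). Averaged over hundreds of
replicate cohorts they converge on them; that is the package's recovery
experiment (`recovery_study()`), and `summary()` of its result reports the
mean estimates with Monte-Carlo standard errors.

The same workflow runs file-to-file:

```r
wbq_run("results/", spec = cohort_spec(), seed = 1)
# -> cohort.csv, scored.csv, table1..table5.csv, diagnostics.json, manifest.json
```

or from a shell via `inst/cli/wbq.R simulate|score|analyze|run`.

## Package layout

- `R/config.R`, `R/codebook.R` — scoring configuration and response-table
  validation (codebook-driven CSV I/O)
- `R/scoring.R` — the scoring engine
- `R/descriptive.R`, `R/models.R`, `R/impute.R` — the statistical pipeline
- `R/synth.R` — synthetic cohorts, missingness injection, recovery study
- `R/pipeline.R`, `inst/cli/wbq.R` — file-to-file stages and CLI
- `vignettes/water-balance-methods.Rmd` — the methods notes: model
  assumptions, default mapping tables and their provenance, numerical
  choices, and what the synthetic validation does and does not demonstrate
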