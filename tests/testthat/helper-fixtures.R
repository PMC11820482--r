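# Fixture builders shared across test files. Everything is generated in code;
# no data files are read from disk except those the tests themselves write to
# tempdir().

# A minimal complete respondent as a one-row character list matching the
# default codebook, overridable field by field.
fixture_row <- function(id = "R1", ...) {
  row <- list(
    id = id, gender = "female", age = "30", weight_kg = "62", height_m = "1.65",
    education_years = "16", residence = "capital", family_status = "unmarried",
    profession = "private", work_hours_week = "40",
    labor_intensity = "2", physical_strain = "2", mental_strain = "3",
    wc_access = "5", weather_exposure = "1", water_access = "5",
    bottle_at_work = "yes", bottle_during_day = "yes",
    glass_during_day = "yes", water_without_thirst = "no",
    water_for_pleasure = "yes",
    bev_juices_soda = "never/rarely", bev_coffee_milk = "1-2 times per day",
    bev_milkshake_granita = "never/rarely", bev_tea = "1-2 times per week",
    bev_alcohol = "never/rarely",
    drinking_water_ml = "2000",
    urination_scale = "3", defecation_scale = "3",
    sweat_rest_scale = "4", sweat_exercise_scale = "5",
    ipaq_vigorous_days = "0", ipaq_vigorous_min = "0",
    ipaq_moderate_days = "2", ipaq_moderate_min = "30",
    ipaq_walking_days = "5", ipaq_walking_min = "20")
  for (item in default_composition()$item)
    row[[paste0("food_", item)]] <- "1-2 times per week"
  for (fl in wbq:::WBQ_EXCLUSION_FLAGS) row[[fl]] <- "no"
  dots <- list(...)
  for (nm in names(dots)) row[[nm]] <- as.character(dots[[nm]])
  row
}

# Write rows (lists from fixture_row) to a temp CSV and return the path.
fixture_csv <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A small scored synthetic cohort for analysis tests.
fixture_scored <- function(n = 150, seed = 424, ...) {
  sp <- cohort_spec(n = n, seed = seed, ...)
  score_wbq(generate_cohort(sp))
}

# Brute-force OLS via the normal equations (independent oracle).
ols_oracle <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Exhaustive all-subsets AIC (independent oracle for backward selection).
all_subsets_aic <- function(data, terms, outcome) {
  best <- list(aic = Inf, terms = character())
  for (k in 0:length(terms)) {
    combs <- utils::combn(terms, k, simplify = FALSE)
    for (tt in combs) {
      f <- if (length(tt)) stats::reformulate(tt, response = outcome)
           else stats::as.formula(paste(outcome, "~ 1"))
      a <- stats::AIC(stats::lm(f, data = data))
      # stats::step uses the extractAIC scale; convert for comparability
      if (a < best$aic) best <- list(aic = a, terms = sort(tt))
    }
  }
  best
}
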