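# Chained-equation imputation: identity, determinism, recovery, and the
# missing-at-random screening diagnostic.

test_that("imputation is the identity on complete data", {
  d <- analysis_data(fixture_scored(n = 80, seed = 12))
  imp <- impute_chained(d, m = 4, maxit = 2, seed = 1)
  expect_length(imp$completions, 4L)
  for (comp in imp$completions) expect_identical(comp, d)
  # pooled fit equals the single OLS fit
  pooled <- fit_model(imp, wbq:::MODEL3_TERMS)
  single <- stats::lm(stats::reformulate(wbq:::MODEL3_TERMS, "balance"), d)
  expect_equal(pooled$table$estimate, unname(coef(single)), tolerance = 1e-12)
  expect_equal(pooled$table$se, unname(sqrt(diag(stats::vcov(single)))),
               tolerance = 1e-10)
})

test_that("the same seed reproduces the imputation set exactly", {
  sp <- cohort_spec(n = 120, seed = 3)
  ad <- analysis_data(score_wbq(generate_cohort(sp)))
  inj <- inject_missingness(ad, sp$missingness, seed = 4)
  i1 <- impute_chained(inj$data, m = 3, maxit = 3, seed = 99)
  i2 <- impute_chained(inj$data, m = 3, maxit = 3, seed = 99)
  expect_identical(i1$completions, i2$completions)
  i3 <- impute_chained(inj$data, m = 3, maxit = 3, seed = 100)
  expect_false(identical(i1$completions, i3$completions))
})

test_that("observed cells are never altered and imputed cells are filled", {
  sp <- cohort_spec(n = 150, seed = 8)
  ad <- analysis_data(score_wbq(generate_cohort(sp)))
  inj <- inject_missingness(ad, sp$missingness, seed = 9)
  imp <- impute_chained(inj$data, m = 3, maxit = 3, seed = 2)
  for (comp in imp$completions) {
    expect_false(anyNA(comp[imp$vars]))
    for (v in imp$vars) {
      obs <- !is.na(inj$data[[v]])
      expect_identical(comp[[v]][obs], inj$data[[v]][obs])
    }
  }
  # factor levels survive the round trip
  expect_identical(levels(imp$completions[[1]]$glass_during_day),
                   c("no", "yes"))
})

test_that("a fully missing variable is a named error", {
  d <- data.frame(x = rnorm(10), y = rep(NA_real_, 10))
  expect_error(impute_chained(d, m = 1, maxit = 1, seed = 1), "100% missing.*y")
})

test_that("multi-level categorical variables impute via multinomial draws", {
  set.seed(61)
  n <- 150
  d <- data.frame(x = rnorm(n),
                  g = sample(c("a", "b", "c"), n, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)))
  d$y <- d$x + (d$g == "b") * 2 + rnorm(n, 0, 0.5)
  d$g[sample(n, 25)] <- NA
  imp <- impute_chained(d, m = 2, maxit = 3, seed = 5)
  expect_equal(unname(imp$methods["g"]), "polyreg")
  for (comp in imp$completions) {
    expect_false(anyNA(comp$g))
    expect_true(all(comp$g %in% c("a", "b", "c")))
  }
})

test_that("pooled estimates after MAR deletion track the complete-data fit", {
  sp <- cohort_spec(n = 500, seed = 314)
  ad <- analysis_data(score_wbq(generate_cohort(sp)))
  complete_fit <- fit_model(ad, wbq:::MODEL3_TERMS)
  inj <- inject_missingness(ad, sp$missingness, seed = 315)
  imp <- impute_chained(inj$data, m = 10, maxit = 10, seed = 316)
  pooled <- fit_model(imp, wbq:::MODEL3_TERMS)
  # every pooled coefficient within 2 pooled SEs of the complete-data value
  dev <- abs(pooled$table$estimate - complete_fit$table$estimate)
  expect_true(all(dev <= 2 * pooled$table$se))
})

test_that("missingness screening flags covariate-driven deletion and stays quiet otherwise", {
  # no missing cells: empty report
  d0 <- data.frame(x = rnorm(20), y = rnorm(20))
  r0 <- assess_mar(d0)
  expect_equal(nrow(r0), 0L)
  # deletion probability increasing in an observed covariate is detected
  set.seed(27)
  hits <- replicate(30, {
    n <- 500
    d <- data.frame(age = rnorm(n, 40, 10), y = rnorm(n))
    p <- stats::plogis(-3 + 0.08 * (d$age - 40))
    d$y[stats::runif(n) < p] <- NA
    rep_ <- assess_mar(d, covariates = "age")
    rep_$p[rep_$covariate == "age"] < 0.05
  })
  expect_gte(mean(hits), 0.90)
  # completely random deletion: per-covariate flag rate near the nominal level
  set.seed(28)
  flags <- replicate(200, {
    n <- 200
    d <- data.frame(age = rnorm(n), z = rnorm(n), y = rnorm(n))
    d$y[stats::runif(n) < 0.15] <- NA
    rep_ <- assess_mar(d, covariates = c("age", "z"))
    rep_$p < 0.05
  })
  rate <- mean(flags)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("separation is reported as non-estimable rather than failing", {
  n <- 60
  d <- data.frame(grp = rep(c("a", "b"), each = n / 2), y = rnorm(n))
  d$y[d$grp == "a"][1:10] <- NA       # missingness only in group a
  rep_ <- assess_mar(d, covariates = "grp")
  expect_s3_class(rep_, "wbq_mar_report")
  expect_true(nrow(rep_) >= 1)
})
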