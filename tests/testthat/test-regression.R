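# Univariate screens, pooled model fits, backward-AIC selection, diagnostics
# and the power calculation, each against an independent oracle where the
# computation is non-trivial.

test_that("the univariate screen recovers a noiseless linear effect", {
  set.seed(3)
  d <- data.frame(balance = 0, x = rnorm(50))
  d$balance <- 2 * d$x + rnorm(50, 0, 1e-9)
  res <- univariate_screen(d, "x")
  expect_equal(res$estimate, 2, tolerance = 1e-6)
  expect_lt(res$p, 1e-12)
})

test_that("every screen fit matches the normal-equations oracle", {
  set.seed(17)
  d <- fixture_scored(n = 180, seed = 17)
  ad <- analysis_data(d)
  res <- univariate_screen(ad)
  for (v in c("age", "education_years", "profession", "bottle_during_day")) {
    dd <- ad[stats::complete.cases(ad[c("balance", v)]), ]
    X <- stats::model.matrix(stats::reformulate(v), data = dd)
    beta <- ols_oracle(X, dd$balance)
    got <- res$estimate[res$predictor == v]
    expect_equal(got, beta[-1], tolerance = 1e-8, label = v)
  }
})

test_that("constant predictors are skipped with a log entry", {
  d <- data.frame(balance = rnorm(30), x = rnorm(30), z = rep(1, 30))
  res <- univariate_screen(d, c("x", "z"))
  expect_equal(attr(res, "skipped"), "z")
  expect_equal(res$predictor, "x")
})

test_that("pooling over identical completions degenerates to the single fit", {
  d <- fixture_scored(n = 140, seed = 9)
  ad <- analysis_data(d)
  single <- stats::lm(stats::reformulate(wbq:::MODEL3_TERMS, "balance"), ad)
  pooled1 <- fit_model(ad, wbq:::MODEL3_TERMS)           # m = 1
  pooled5 <- fit_model(replicate(5, ad, simplify = FALSE), wbq:::MODEL3_TERMS)
  expect_equal(pooled1$table$estimate, unname(coef(single)), tolerance = 1e-12)
  expect_equal(pooled1$table$se,
               unname(sqrt(diag(stats::vcov(single)))), tolerance = 1e-12)
  # identical completions: between-imputation variance is zero
  expect_equal(pooled5$table$estimate, unname(coef(single)), tolerance = 1e-12)
  expect_equal(pooled5$table$se,
               unname(sqrt(diag(stats::vcov(single)))), tolerance = 1e-10)
})

test_that("pooled fits match the Rubin formulas recomputed directly", {
  set.seed(21)
  comps <- lapply(1:4, function(i)
    data.frame(balance = rnorm(60), x = rnorm(60), z = rnorm(60)))
  fit <- fit_model(comps, c("x", "z"))
  ests <- sapply(comps, function(d) coef(lm(balance ~ x + z, d)))
  vars <- sapply(comps, function(d) diag(vcov(lm(balance ~ x + z, d))))
  qbar <- rowMeans(ests)
  Tvar <- rowMeans(vars) + (1 + 1 / 4) * apply(ests, 1, var)
  expect_equal(fit$table$estimate, unname(qbar), tolerance = 1e-12)
  expect_equal(fit$table$se, unname(sqrt(Tvar)), tolerance = 1e-12)
})

test_that("a rank-deficient design errors naming the aliased term", {
  d <- data.frame(balance = rnorm(40), x = rnorm(40))
  d$x2 <- d$x
  expect_error(fit_model(d, c("x", "x2")), "aliased.*x2")
})

test_that("backward selection agrees with exhaustive all-subsets AIC", {
  # orthonormal predictors: greedy backward must find the exact optimum
  set.seed(33)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  d <- as.data.frame(Q)
  names(d) <- paste0("x", 1:6)
  d$balance <- 3 * d$x1 - 2 * d$x4 + rnorm(n, 0, 0.5)
  sel <- backward_aic(d, paste0("x", 1:6))
  oracle <- all_subsets_aic(d, paste0("x", 1:6), "balance")
  expect_identical(sort(sel), oracle$terms)
  # correlated predictors: backward AIC within 2 of the global optimum
  set.seed(34)
  X <- matrix(rnorm(n * 8), n, 8) %*% chol(0.5 + 0.5 * diag(8))
  d2 <- as.data.frame(X)
  names(d2) <- paste0("x", 1:8)
  d2$balance <- 2 * d2$x1 + 1.5 * d2$x2 + rnorm(n)
  sel2 <- backward_aic(d2, paste0("x", 1:8))
  f2 <- if (length(sel2)) stats::reformulate(sel2, "balance") else balance ~ 1
  aic_back <- stats::AIC(stats::lm(f2, d2))
  oracle2 <- all_subsets_aic(d2, paste0("x", 1:8), "balance")
  expect_lte(aic_back, oracle2$aic + 2)
})

test_that("the three-model sequence is nested and reproduces planted structure", {
  d <- fixture_scored(n = 400, seed = 77)
  ad <- analysis_data(d)
  seqs <- fit_model_sequence(ad)
  expect_true(all(seqs$selected_terms %in% wbq:::MODEL1_TERMS))
  if (!is.null(seqs$model3))
    expect_true(all(seqs$model3$terms %in% seqs$model2$terms))
  expect_equal(seqs$model1$n, nrow(ad))
})

test_that("strong true effects survive backward selection consistently", {
  set.seed(55)
  keep <- replicate(50, {
    n <- 300
    d <- as.data.frame(matrix(rnorm(n * 12), n, 12))
    names(d) <- paste0("x", 1:12)
    d$balance <- 1.0 * d$x1 - 1.0 * d$x2 + 0.8 * d$x3 + rnorm(n)
    sel <- backward_aic(d, paste0("x", 1:12))
    all(c("x1", "x2", "x3") %in% sel)
  })
  expect_gte(mean(keep), 0.90)
})

test_that("VIF equals the definitional auxiliary-regression oracle", {
  set.seed(41)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$x3 <- 0.8 * d$x1 + 0.6 * rnorm(n)
  d$balance <- d$x1 + d$x2 + d$x3 + rnorm(n)
  fit <- stats::lm(balance ~ x1 + x2 + x3, d)
  diag_ <- model_diagnostics(fit)
  for (v in c("x1", "x2", "x3")) {
    aux <- summary(stats::lm(stats::reformulate(setdiff(c("x1", "x2", "x3"), v), v), d))
    expect_equal(unname(diag_$vif[v]), 1 / (1 - aux$r.squared),
                 tolerance = 1e-8, label = v)
  }
  # orthogonal (and centered, as VIF is defined on centered predictors)
  # design: all VIF equal 1
  Q <- qr.Q(qr(scale(matrix(rnorm(300), 100, 3), center = TRUE, scale = FALSE)))
  do <- as.data.frame(Q); names(do) <- c("a", "b", "c")
  do$balance <- rowSums(Q) + rnorm(100)
  vo <- model_diagnostics(stats::lm(balance ~ a + b + c, do))$vif
  expect_equal(unname(vo), rep(1, 3), tolerance = 1e-10)
  # near-duplicated predictor: flagged beyond the cap
  dd <- data.frame(x = rnorm(n))
  dd$xdup <- dd$x + rnorm(n, 0, 1e-4)
  dd$balance <- dd$x + rnorm(n)
  dv <- model_diagnostics(stats::lm(balance ~ x + xdup, dd))
  expect_true(all(c("x", "xdup") %in% dv$vif_flagged))
})

test_that("residual diagnostics report normality and heteroscedasticity checks", {
  set.seed(43)
  d <- data.frame(x = rnorm(150))
  d$balance <- 2 * d$x + rnorm(150)
  dg <- model_diagnostics(stats::lm(balance ~ x, d))
  expect_gt(dg$shapiro_p, 0.001)
  expect_true(is.finite(dg$bp_p))
  # strongly heteroscedastic errors are flagged
  dh <- data.frame(x = rnorm(400))
  dh$y2 <- 2 * dh$x + rnorm(400, 0, 0.2 + 3 * abs(dh$x))
  dg2 <- model_diagnostics(stats::lm(y2 ~ x, dh))
  expect_lt(dg2$bp_p, 0.05)
})

test_that("required sample size is minimal, monotone and matches simulated power", {
  n59 <- required_sample_size(0.15, 0.80, 0.05, k = 5)
  # minimality at the returned n
  powf <- function(n, f2, k, alpha = 0.05)
    stats::pf(stats::qf(1 - alpha, k, n - k - 1), k, n - k - 1,
              ncp = f2 * n, lower.tail = FALSE)
  expect_gte(powf(n59, 0.15, 5), 0.80)
  expect_lt(powf(n59 - 1, 0.15, 5), 0.80)
  # monotone in effect size
  ns <- sapply(c(0.05, 0.15, 0.25, 0.35), required_sample_size,
               power = 0.8, alpha = 0.05, k = 3)
  expect_true(all(diff(ns) <= 0))
  # simulation oracle at f2 = 0.35, k = 1: the rejection rate of the omnibus
  # F test at the returned n brackets the target power
  nreq <- required_sample_size(0.35, 0.80, 0.05, k = 1)
  simpow <- function(n, b, reps = 4000) {
    hits <- 0L
    for (i in seq_len(reps)) {
      x <- stats::rnorm(n)
      y <- b * x + stats::rnorm(n)
      f <- summary(stats::lm(y ~ x))$fstatistic
      if (stats::pf(f[1], f[2], f[3], lower.tail = FALSE) < 0.05) hits <- hits + 1L
    }
    hits / reps
  }
  set.seed(71)
  b <- sqrt(0.35)               # slope giving f2 = b^2 / sigma^2 = 0.35
  expect_gte(simpow(nreq, b), 0.80 - 0.03)
  expect_lt(simpow(max(nreq - 4, 3), b), 0.88)
  expect_error(required_sample_size(1e-9, 0.8, 0.05, 1, n_max = 100),
               "unattainable")
})
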