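# Multivariable modelling: pooled OLS over multiply imputed data (Rubin's
# rules), backward-AIC selection, the significance-reduced refit, and
# regression diagnostics.

# Term list of the full multivariable model (Model 1): every covariate kept by
# the study's causal diagram. Multi-level factors count as one term here.
MODEL1_TERMS <- c("beverage_variety_binary", "gender", "age", "bmi",
                  "education_years", "profession", "work_hours_week",
                  "labor_intensity", "physical_strain", "mental_strain",
                  "wc_access", "weather_exposure", "water_access",
                  "bottle_at_work", "glass_during_day", "bottle_during_day",
                  "water_without_thirst", "water_for_pleasure")

# Term list of the final reduced model (Model 3).
MODEL3_TERMS <- c("education_years", "work_hours_week", "glass_during_day",
                  "bottle_during_day", "water_for_pleasure")

#' Prepare a scored table for regression analysis
#'
#' Sets reference levels exactly as the descriptive/regression tables define
#' them: gender reference "female"; profession reference "other"; yes/no
#' items reference "no"; beverage variety reference "3 or fewer types" (0).
#' Likert items (1-5 scales) enter as numeric scores. Returns only the
#' outcome and model covariates (plus `id` if present).
#'
#' @param scored data.frame from [score_wbq()] (covariates + profile).
#' @param outcome outcome column, default `"balance"`.
#' @param extra further columns to carry through.
#' @return data.frame ready for [fit_model()]/[univariate_screen()].
#' @export
analysis_data <- function(scored, outcome = "balance", extra = character()) {
  cols <- unique(c(intersect("id", names(scored)), outcome, MODEL1_TERMS, extra))
  missing_cols <- setdiff(cols, names(scored))
  if (length(missing_cols))
    stop("scored table lacks analysis column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- scored[cols]
  if ("gender" %in% cols) d$gender <- factor(d$gender, levels = c("female", "male"))
  if ("profession" %in% cols)
    d$profession <- factor(d$profession,
                           levels = c("other", "self_employed", "private", "public"))
  for (v in c("bottle_at_work", "glass_during_day", "bottle_during_day",
              "water_without_thirst", "water_for_pleasure")) {
    if (v %in% cols) d[[v]] <- factor(d[[v]], levels = c("no", "yes"))
  }
  d
}

# Fit one OLS on one completed dataset; returns the pieces pooling needs.
.fit_once <- function(data, terms, outcome) {
  f <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(f, data = data)
  als <- is.na(stats::coef(fit))
  if (any(als))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[als], collapse = ", "))
  s <- summary(fit)
  list(coef = stats::coef(fit), vcov = stats::vcov(fit),
       df_resid = fit$df.residual, adj_r2 = s$adj.r.squared,
       rmse = s$sigma, n = length(stats::fitted(fit)), lm = fit)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines m per-completion coefficient vectors and covariance matrices:
#' pooled estimate = mean; total variance = within-imputation mean +
#' (1 + 1/m) between-imputation variance; degrees of freedom by the
#' Barnard-Rubin small-sample formula; two-sided t p-values. With m = 1 the
#' pooled fit equals the single fit.
#'
#' @param fits list of fits as produced internally (each with `coef`, `vcov`,
#'   `df_resid`, `adj_r2`, `rmse`, `n`).
#' @return object of class `wbq_fit`: list with `table` (term/estimate/se/
#'   statistic/df/p), `adj_r2` and `rmse` (means across completions), `n`,
#'   `m`, `terms`.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  Q <- do.call(rbind, lapply(fits, function(f) f$coef))
  qbar <- colMeans(Q)
  W <- Reduce(`+`, lapply(fits, function(f) diag(f$vcov))) / m
  if (m > 1) {
    B <- apply(Q, 2, stats::var)
  } else B <- rep(0, length(qbar))
  Tvar <- W + (1 + 1 / m) * B
  se <- sqrt(Tvar)
  dfcom <- fits[[1]]$df_resid
  if (m > 1) {
    lambda <- pmin(pmax((1 + 1 / m) * B / Tvar, 1e-12), 1 - 1e-12)
    df_old <- (m - 1) / lambda^2
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- df_old * df_obs / (df_old + df_obs)
  } else df <- rep(dfcom, length(qbar))
  tstat <- qbar / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(
    table = data.frame(term = names(qbar), estimate = unname(qbar),
                       se = unname(se), statistic = unname(tstat),
                       df = unname(df), p = unname(p),
                       stringsAsFactors = FALSE),
    adj_r2 = mean(vapply(fits, `[[`, 0, "adj_r2")),
    rmse = mean(vapply(fits, `[[`, 0, "rmse")),
    n = fits[[1]]$n, m = m,
    terms = attr(stats::terms(fits[[1]]$lm), "term.labels"),
    first_lm = fits[[1]]$lm), class = "wbq_fit")
}

#' @export
print.wbq_fit <- function(x, digits = 3, ...) {
  cat("Pooled linear model (m =", x$m, "imputations), n =", x$n, "\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  print(tab[c("term", "estimate", "se", "p")], row.names = FALSE)
  cat(sprintf("Adjusted R-squared: %.3f   RMSE: %.2f\n", x$adj_r2, x$rmse))
  invisible(x)
}

#' Fit a linear model (pooled over imputations)
#'
#' Fits `outcome ~ terms` by OLS on each completed dataset of an imputation
#' set (or a single data.frame) and pools by Rubin's rules.
#'
#' @param data a `wbq_mice` object, a list of data.frames, or one data.frame.
#' @param terms character vector of model terms.
#' @param outcome outcome column, default `"balance"`.
#' @return a `wbq_fit`.
#' @export
fit_model <- function(data, terms, outcome = "balance") {
  comps <- if (inherits(data, "wbq_mice")) data$completions
           else if (is.data.frame(data)) list(data) else data
  pool_rubin(lapply(comps, .fit_once, terms = terms, outcome = outcome))
}

#' @rdname fit_model
#' @details `fit_model1()` fits the full pre-specified covariate set
#'   (the causal-diagram variable list).
#' @export
fit_model1 <- function(data, outcome = "balance") {
  fit_model(data, MODEL1_TERMS, outcome)
}

#' Backward model selection by AIC
#'
#' Starting from the full term set, repeatedly removes the term whose removal
#' lowers the AIC most, until no removal improves it (`stats::step`,
#' direction "backward"). Under multiple imputation the selection runs on a
#' single completed dataset (the first, by default) for determinism; the
#' selected model is then refit on all completions and pooled.
#'
#' @param data as in [fit_model()].
#' @param terms starting term set (default the full model).
#' @param outcome outcome column.
#' @param which_completion completed dataset used for selection (default 1).
#' @return character vector of selected terms (possibly empty), with the
#'   selection trace as attribute `anova`.
#' @export
backward_aic <- function(data, terms = MODEL1_TERMS, outcome = "balance",
                         which_completion = 1) {
  d <- if (inherits(data, "wbq_mice")) data$completions[[which_completion]]
       else if (is.data.frame(data)) data else data[[which_completion]]
  full <- stats::lm(stats::reformulate(terms, response = outcome), data = d)
  sel <- stats::step(full, direction = "backward", trace = 0)
  out <- attr(stats::terms(sel), "term.labels")
  attr(out, "anova") <- sel$anova
  out
}

# Map pooled coefficient rows to model terms via the design's `assign`
# attribute, and return the per-term p-value (minimum over a term's
# coefficients, relevant only for multi-level factors).
term_pvalues <- function(fit) {
  mm <- stats::model.matrix(fit$first_lm)
  asg <- attr(mm, "assign")
  labels <- attr(stats::terms(fit$first_lm), "term.labels")
  keep <- asg > 0
  tapply(fit$table$p[keep], labels[asg[keep]], min)
}

#' Significance-reduced refit
#'
#' Refits the model keeping only the terms whose pooled p-value falls below
#' `alpha` in a previously fitted (pooled) model — the study's "Model 3" step
#' applied to its "Model 2". For a multi-level factor the term survives if any
#' of its coefficients is significant.
#'
#' @param data as in [fit_model()].
#' @param fit a `wbq_fit` (typically the backward-AIC model).
#' @param alpha significance threshold, default 0.05.
#' @param outcome outcome column.
#' @return a `wbq_fit` on the surviving terms; errors if none survive.
#' @export
fit_reduced <- function(data, fit, alpha = 0.05, outcome = "balance") {
  pv <- term_pvalues(fit)
  keep <- names(pv)[pv < alpha]
  if (!length(keep)) stop("no term significant at alpha = ", alpha)
  fit_model(data, keep, outcome)
}

#' Run the three-model multivariable sequence
#'
#' Model 1: pooled OLS on the full pre-specified term set. Model 2: backward
#' AIC selection (on the first completion) refit on all completions and
#' pooled. Model 3: Model 2 terms with pooled p < 0.05, refit and pooled.
#' The nesting terms(M3) within terms(M2) within terms(M1) holds by
#' construction and is asserted.
#'
#' @param data a `wbq_mice`, list of data.frames, or data.frame (from
#'   [analysis_data()]).
#' @param terms full model term set.
#' @param outcome outcome column.
#' @param alpha Model 3 significance threshold.
#' @return list with elements `model1`, `model2`, `model3` (each `wbq_fit`;
#'   `model3` is `NULL` if no Model 2 term is significant) and
#'   `selected_terms`.
#' @export
fit_model_sequence <- function(data, terms = MODEL1_TERMS, outcome = "balance",
                               alpha = 0.05) {
  m1 <- fit_model(data, terms, outcome)
  sel <- backward_aic(data, terms, outcome)
  if (!length(sel)) return(list(model1 = m1, model2 = NULL, model3 = NULL,
                                selected_terms = character()))
  m2 <- fit_model(data, sel, outcome)
  m3 <- tryCatch(fit_reduced(data, m2, alpha, outcome), error = function(e) NULL)
  stopifnot(all(sel %in% terms),
            is.null(m3) || all(m3$terms %in% sel))
  list(model1 = m1, model2 = m2, model3 = m3, selected_terms = sel)
}

#' Univariate screen of water-balance determinants
#'
#' One OLS per predictor (a multi-level factor enters as one model with its
#' dummy terms); reports coefficient, SE, p and adjusted R-squared, in the
#' reference coding of [analysis_data()]. Constant predictors are skipped and
#' listed in the `skipped` attribute.
#'
#' @param data data.frame from [analysis_data()] (complete or raw; rows with
#'   missing outcome/predictor are dropped per fit).
#' @param predictors character vector (default: the full model term set).
#' @param outcome outcome column.
#' @return data.frame: predictor, term, estimate, se, p, adj_r2, n.
#' @export
univariate_screen <- function(data, predictors = MODEL1_TERMS,
                              outcome = "balance") {
  rows <- list()
  skipped <- character()
  for (v in predictors) {
    d <- data[stats::complete.cases(data[c(outcome, v)]), c(outcome, v)]
    x <- d[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      skipped <- c(skipped, v)
      next
    }
    fit <- stats::lm(stats::reformulate(v, response = outcome), data = d)
    s <- summary(fit)$coefficients
    keep <- rownames(s) != "(Intercept)"
    rows[[v]] <- data.frame(
      predictor = v, term = rownames(s)[keep],
      estimate = s[keep, 1], se = s[keep, 2], p = s[keep, 4],
      adj_r2 = summary(fit)$adj.r.squared, n = nrow(d),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(predictor = character(), term = character(),
               estimate = numeric(), se = numeric(), p = numeric(),
               adj_r2 = numeric(), n = integer())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Regression diagnostics
#'
#' Variance inflation factors (flagged above `vif_cap`), Shapiro-Wilk
#' normality of residuals, a Breusch-Pagan heteroscedasticity test and a
#' linearity summary (correlation of residuals with fitted values, which is 0
#' by construction, plus with squared fitted values as a curvature probe).
#'
#' @param fit an `lm` or a `wbq_fit` (its first-completion fit is used).
#' @param vif_cap multicollinearity flag threshold, default 5.
#' @return list of class `wbq_diagnostics`.
#' @export
model_diagnostics <- function(fit, vif_cap = 5) {
  lmfit <- if (inherits(fit, "wbq_fit")) fit$first_lm else fit
  res <- stats::residuals(lmfit)
  fitted <- stats::fitted(lmfit)
  nterms <- length(attr(stats::terms(lmfit), "term.labels"))
  vifs <- if (nterms >= 2) {
    v <- car::vif(lmfit)
    if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  } else NULL
  sw <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    stats::shapiro.test(res) else NULL
  bp <- lmtest::bptest(lmfit)
  structure(list(
    vif = vifs,
    vif_flagged = if (is.null(vifs)) character() else names(vifs)[vifs > vif_cap],
    vif_cap = vif_cap,
    shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
    shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
    bp_statistic = unname(bp$statistic), bp_p = bp$p.value,
    resid_fitted_cor = suppressWarnings(stats::cor(res, fitted)),
    curvature_cor = suppressWarnings(stats::cor(res, fitted^2))),
    class = "wbq_diagnostics")
}

#' @export
print.wbq_diagnostics <- function(x, ...) {
  if (!is.null(x$vif)) {
    cat("VIF (flag > ", x$vif_cap, "):\n", sep = "")
    print(round(x$vif, 2))
    if (length(x$vif_flagged))
      cat("Flagged:", paste(x$vif_flagged, collapse = ", "), "\n")
  }
  cat(sprintf("Residual normality (Shapiro-Wilk): W = %.3f, p = %.3g\n",
              x$shapiro_w, x$shapiro_p))
  cat(sprintf("Heteroscedasticity (Breusch-Pagan): p = %.3g\n", x$bp_p))
  invisible(x)
}

#' Required sample size for the omnibus F test of a linear model
#'
#' Smallest n such that the k-predictor omnibus test with noncentrality
#' f2 * n reaches the target power at level alpha.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param power target power in (0, 1), default 0.80.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param k number of predictors (>= 1).
#' @param n_max search cap (default 1e6).
#' @return integer n; attribute `power` gives the achieved power.
#' @export
#' @examples
#' required_sample_size(0.15, 0.80, 0.05, k = 5)
required_sample_size <- function(f2, power = 0.80, alpha = 0.05, k = 1,
                                 n_max = 1e6) {
  stopifnot(f2 > 0, power > 0, power < 1, alpha > 0, alpha < 1, k >= 1)
  pow <- function(n) {
    df2 <- n - k - 1
    if (df2 < 1) return(0)
    stats::pf(stats::qf(1 - alpha, k, df2), k, df2, ncp = f2 * n,
              lower.tail = FALSE)
  }
  lo <- k + 2
  if (pow(n_max) < power) stop("target power unattainable within n_max")
  hi <- lo
  while (pow(hi) < power) hi <- min(hi * 2, n_max)
  while (lo < hi) {           # binary search for smallest n with pow(n) >= power
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid + 1
  }
  structure(as.integer(lo), power = pow(lo))
}
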