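# Multiple imputation by chained equations, with proper (posterior-draw)
# conditional models, plus the MAR screening diagnostic.
#
# Conditional engines:
#   norm    - Bayesian linear regression: sigma* ~ sqrt(SSR / chisq_df),
#             beta* ~ N(beta_hat, sigma*^2 (X'X)^-1), imputations drawn with
#             residual noise (a "proper" imputation in Rubin's sense).
#   logreg  - logistic regression with an approximate posterior draw
#             beta* ~ N(beta_hat, V_hat), imputations drawn Bernoulli.
#   polyreg - multinomial logistic (nnet); imputations drawn from the fitted
#             class probabilities (no posterior draw; adequate for nuisance
#             categorical variables).

#' Screen the plausibility of a random missingness mechanism
#'
#' For every variable with missing cells, regresses its binary missingness
#' indicator (1 = missing, 0 = observed) on the fully observed covariates via
#' logistic regression. A covariate with p < alpha flags a systematic pattern
#' (evidence against missing-completely-at-random; consistent with
#' missing-at-random given that covariate). Perfect-separation fits are
#' reported as non-estimable rather than failing.
#'
#' @param data data.frame with missing cells.
#' @param covariates columns to regress on (default: all fully observed
#'   columns except `id`).
#' @param alpha flag threshold (default 0.05).
#' @return data.frame (class `wbq_mar_report`) with one row per
#'   variable x covariate: estimate, se, p, estimable; attribute
#'   `systematic_pattern` (logical per variable).
#' @export
assess_mar <- function(data, covariates = NULL, alpha = 0.05) {
  incomplete <- names(data)[vapply(data, anyNA, TRUE)]
  if (is.null(covariates)) {
    complete_cols <- names(data)[!vapply(data, anyNA, TRUE)]
    covariates <- setdiff(complete_cols, "id")
  }
  if (!length(incomplete)) {
    out <- data.frame(variable = character(), covariate = character(),
                      estimate = numeric(), se = numeric(), p = numeric(),
                      estimable = logical(), stringsAsFactors = FALSE)
    attr(out, "systematic_pattern") <- logical()
    class(out) <- c("wbq_mar_report", "data.frame")
    return(out)
  }
  if (!length(covariates)) stop("no fully observed covariates to screen against")
  rows <- list()
  flags <- logical(0)
  for (v in incomplete) {
    ind <- as.integer(is.na(data[[v]]))
    df <- data.frame(.miss = ind, data[covariates], check.names = FALSE)
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.miss ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    keep <- rownames(sm) != "(Intercept)"
    est <- sm[keep, 1]; se <- sm[keep, 2]; p <- sm[keep, 4]
    estimable <- is.finite(se) & se < 1e3 & !(separated & abs(est) > 10)
    p[!estimable] <- NA_real_
    rows[[v]] <- data.frame(variable = v, covariate = rownames(sm)[keep],
                            estimate = est, se = se, p = p,
                            estimable = estimable,
                            stringsAsFactors = FALSE, row.names = NULL)
    flags[v] <- any(p < alpha, na.rm = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "systematic_pattern") <- flags
  class(out) <- c("wbq_mar_report", "data.frame")
  out
}

# Build one numeric design matrix (no intercept) for the whole predictor set,
# with a map from design columns back to source variables so each variable's
# own columns can be excluded when it is being imputed.
.impute_design <- function(data) {
  use <- setdiff(names(data), "id")
  df <- data[use]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., data = df)
  asg <- attr(mm, "assign")
  labels <- attr(stats::terms(~ ., data = df), "term.labels")
  keep <- asg > 0
  list(X = mm[, keep, drop = FALSE], source = labels[asg[keep]])
}

# One proper Bayesian-linear-regression imputation of y[mis] given X.
.draw_norm <- function(y, X, mis) {
  Xo <- cbind(1, X[!mis, , drop = FALSE])
  yo <- y[!mis]
  qrx <- qr(Xo)
  rank <- qrx$rank
  if (rank < ncol(Xo)) {      # drop aliased columns (pivoted to the end)
    keep <- qrx$pivot[seq_len(rank)]
    Xo <- Xo[, keep, drop = FALSE]
    Xm <- cbind(1, X[mis, , drop = FALSE])[, keep, drop = FALSE]
    qrx <- qr(Xo)
  } else {
    Xm <- cbind(1, X[mis, , drop = FALSE])
  }
  beta <- qr.coef(qrx, yo)
  res <- yo - Xo %*% beta
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrx)
  z <- stats::rnorm(ncol(Xo))
  beta_star <- beta + backsolve(R, z) * sqrt(sigma2)
  as.numeric(Xm %*% beta_star + stats::rnorm(sum(mis), 0, sqrt(sigma2)))
}

# Newton-IRLS logistic fit with a tiny ridge for stability under separation
# or collinearity; returns the MLE and the inverse information (the
# approximate posterior covariance).
.logit_irls <- function(X, y, maxit = 10, tol = 1e-5, ridge = 1e-6) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  H <- NULL
  res <- tryCatch({
    for (i in seq_len(maxit)) {
      mu <- stats::plogis(as.numeric(X %*% beta))
      w <- pmax(mu * (1 - mu), 1e-8)
      H <- crossprod(X, X * w)
      diag(H) <- diag(H) + ridge
      R <- chol(H)
      delta <- backsolve(R, forwardsolve(t(R), crossprod(X, y - mu)))
      delta <- pmin(pmax(as.numeric(delta), -5), 5)  # damped; guards separation
      beta <- beta + delta
      if (max(abs(delta)) < tol) break
    }
    list(beta = beta, V = chol2inv(chol(H)))
  }, error = function(e) NULL)
  if (is.null(res)) list(beta = beta, V = NULL) else res
}

# One approximate-posterior logistic imputation. Returns values of `levels`.
.draw_logreg <- function(y, X, mis, levels) {
  yo <- as.integer(y[!mis] == levels[2])
  Xo <- cbind(1, X[!mis, , drop = FALSE])
  Xm <- cbind(1, X[mis, , drop = FALSE])
  fit <- .logit_irls(Xo, yo)
  beta_star <- fit$beta
  if (!is.null(fit$V)) {
    cf <- tryCatch(chol(fit$V), error = function(e) NULL)
    if (!is.null(cf))
      beta_star <- fit$beta + as.numeric(t(cf) %*% stats::rnorm(length(fit$beta)))
  }
  p <- stats::plogis(as.numeric(Xm %*% beta_star))
  levels[1 + stats::rbinom(sum(mis), 1, p)]
}

# Multinomial imputation via nnet, sampling from predicted class probabilities.
.draw_polyreg <- function(y, X, mis, levels) {
  dfo <- data.frame(.y = factor(y[!mis], levels = levels), X[!mis, , drop = FALSE])
  fit <- suppressMessages(nnet::multinom(.y ~ ., data = dfo, trace = FALSE))
  pm <- stats::predict(fit, newdata = data.frame(X[mis, , drop = FALSE]),
                       type = "probs")
  if (is.null(dim(pm))) pm <- rbind(pm)   # single missing row
  apply(pm, 1, function(p) sample(levels, 1, prob = p))
}

#' Multiple imputation by chained equations
#'
#' Iteratively imputes each incomplete variable conditional on all others
#' (current completions), `maxit` sweeps per chain, `m` independent chains,
#' reproducible under `seed`. Conditional models are chosen by type: numeric
#' variables use Bayesian linear regression, two-level variables logistic
#' regression, multi-level factors multinomial regression. Observed cells are
#' never altered.
#'
#' @param data data.frame with missing cells (numeric / character / factor
#'   columns; an `id` column, if present, is never used as a predictor).
#' @param m number of completed datasets (default 20).
#' @param maxit chained-equation sweeps per dataset (default 10).
#' @param seed RNG seed (default 20220512).
#' @param vars variables to impute (default: all with missing cells).
#' @param predictors columns used as predictors (default: all except `id`).
#' @return object of class `wbq_mice`: list with `completions` (list of m
#'   data.frames, no missing cells in `vars`), `methods`, `vars`, `m`,
#'   `maxit`, `seed`, and `chain_means` (per chain/sweep/variable mean of
#'   imputed values, for convergence diagnostics).
#' @export
impute_chained <- function(data, m = 20, maxit = 10, seed = 20220512,
                           vars = NULL, predictors = NULL) {
  stopifnot(m >= 1, maxit >= 1)
  if (is.null(vars)) vars <- names(data)[vapply(data, anyNA, TRUE)]
  all_missing <- vars[vapply(vars, function(v) all(is.na(data[[v]])), TRUE)]
  if (length(all_missing))
    stop("variable(s) 100% missing, cannot impute: ",
         paste(all_missing, collapse = ", "))
  if (is.null(predictors)) predictors <- setdiff(names(data), "id")
  methods <- vapply(vars, function(v) {
    x <- data[[v]]
    ux <- unique(x[!is.na(x)])
    if (is.numeric(x) && length(ux) > 2) "norm"
    else if (length(ux) == 2) "logreg"
    else if (is.numeric(x)) "norm"
    else "polyreg"
  }, "")
  lvls <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
  })
  names(lvls) <- vars
  mis_idx <- lapply(vars, function(v) is.na(data[[v]]))
  names(mis_idx) <- vars

  set.seed(seed)
  completions <- vector("list", m)
  chain_means <- array(NA_real_, dim = c(m, maxit, length(vars)),
                       dimnames = list(NULL, NULL, vars))
  for (chain in seq_len(m)) {
    cur <- data
    # initialize by sampling observed values
    for (v in vars) {
      mis <- mis_idx[[v]]
      if (any(mis)) {
        obs <- cur[[v]][!mis]
        cur[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
      }
    }
    # the design is updated in place after each draw, so it is built once
    # per chain rather than once per sweep
    design <- if (length(vars)) .impute_design(cur[predictors])
    if (length(vars)) for (it in seq_len(maxit)) {
      for (v in vars) {
        mis <- mis_idx[[v]]
        if (!any(mis)) next
        X <- design$X[, design$source != v, drop = FALSE]
        imp <- switch(methods[[v]],
          norm = .draw_norm(data[[v]], X, mis),
          logreg = .draw_logreg(data[[v]], X, mis, lvls[[v]]),
          polyreg = .draw_polyreg(data[[v]], X, mis, lvls[[v]]))
        if (is.factor(cur[[v]])) {
          cur[[v]][mis] <- factor(imp, levels = levels(cur[[v]]))
        } else cur[[v]][mis] <- imp
        # refresh this variable's design columns so later variables in the
        # same sweep condition on the new draws (Gauss-Seidel updating)
        own <- which(design$source == v)
        if (length(own)) {
          xv <- cur[[v]]
          if (is.numeric(xv)) {
            design$X[, own] <- xv
          } else {
            xv <- as.character(xv)
            for (j in seq_along(own))
              design$X[, own[j]] <- as.numeric(xv == lvls[[v]][j + 1])
          }
        }
        chain_means[chain, it, v] <- if (methods[[v]] == "norm")
          mean(as.numeric(imp)) else mean(imp == lvls[[v]][length(lvls[[v]])])
      }
    }
    completions[[chain]] <- cur
  }
  structure(list(completions = completions, methods = methods, vars = vars,
                 m = m, maxit = maxit, seed = seed,
                 chain_means = chain_means),
            class = "wbq_mice")
}

#' @export
print.wbq_mice <- function(x, ...) {
  cat("Chained-equation imputation: m =", x$m, ", maxit =", x$maxit,
      ", seed =", x$seed, "\n")
  if (length(x$vars)) {
    cat("Imputed variables:\n")
    for (v in x$vars) cat("  ", v, " (", x$methods[[v]], ")\n", sep = "")
  } else cat("No missing cells; completions identical to input.\n")
  invisible(x)
}
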