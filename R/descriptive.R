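# Descriptive comparisons: normality assessment, test selection by variable
# type (chi-square / t / Wilcoxon), and table formatting in the conventional
# epidemiological style: n (%) for categorical variables, mean (SD) for
# normal continuous variables, median [Q1, Q3] otherwise.

#' Assess normality of a continuous variable
#'
#' Shapiro-Wilk test; the verdict is "normal" iff p >= alpha. Requires at
#' least 3 non-missing, non-constant values (the test is undefined otherwise).
#' For n > 5000 the test statistic is computed on a fixed-size random
#' subsample (the test is defined up to n = 5000).
#'
#' @param values numeric vector.
#' @param alpha verdict threshold, default 0.05.
#' @return list with `normal` (logical), `statistic` (W), `p`, `n`.
#' @export
assess_normality <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 3) stop("need at least 3 non-missing values")
  if (stats::sd(x) == 0) stop("degenerate input: constant vector")
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  sw <- stats::shapiro.test(x)
  list(normal = sw$p.value >= alpha, statistic = unname(sw$statistic),
       p = sw$p.value, n = length(x))
}

fmt_mean_sd <- function(x, digits = 2)
  sprintf("%.*f (%.*f)", digits, mean(x, na.rm = TRUE),
          digits, stats::sd(x, na.rm = TRUE))

fmt_median_iqr <- function(x, digits = 2) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f [%.*f, %.*f]", digits, q[1], digits, q[2], digits, q[3])
}

fmt_n_pct <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)

#' Compare one variable between genders
#'
#' Categorical variables: chi-square test on the contingency table (with
#' continuity correction only in the 2x2 case, the test's conventional
#' default). Continuous variables: independent-samples t test (Welch) when
#' both gender groups pass the normality assessment, otherwise the Wilcoxon
#' rank-sum test with normal approximation and tie correction. Group
#' summaries are formatted to match the test used.
#'
#' @param data data.frame with a `gender` column ("male"/"female") and the
#'   variable of interest.
#' @param variable column name to compare.
#' @param gender_col grouping column, default `"gender"`.
#' @return list of class `wbq_comparison`: `variable`, `test` (one of
#'   "chi-square", "t", "Wilcoxon"), `statistic`, `p`, `summaries`
#'   (data.frame: level/group summaries), `normal` (per-group verdicts for
#'   continuous variables).
#' @export
compare_by_gender <- function(data, variable, gender_col = "gender") {
  g <- data[[gender_col]]
  x <- data[[variable]]
  keep <- !is.na(g) & !is.na(x)
  g <- factor(g[keep])
  x <- x[keep]
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("gender comparison needs two non-empty groups")
  groups <- levels(g)
  if (is.numeric(x) && length(unique(x)) > 2) {
    verdicts <- lapply(groups, function(lv) assess_normality(x[g == lv]))
    both_normal <- all(vapply(verdicts, `[[`, TRUE, "normal"))
    if (both_normal) {
      tt <- stats::t.test(x ~ g)
      test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
      summaries <- data.frame(
        level = variable,
        total = fmt_mean_sd(x),
        stats::setNames(as.list(vapply(groups, function(lv)
          fmt_mean_sd(x[g == lv]), "")), groups),
        check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      wt <- stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE)
      test <- "Wilcoxon"; statistic <- unname(wt$statistic); p <- wt$p.value
      summaries <- data.frame(
        level = variable,
        total = fmt_median_iqr(x),
        stats::setNames(as.list(vapply(groups, function(lv)
          fmt_median_iqr(x[g == lv]), "")), groups),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    normal <- stats::setNames(vapply(verdicts, `[[`, TRUE, "normal"), groups)
  } else {
    tab <- table(factor(x), g)
    ct <- suppressWarnings(stats::chisq.test(tab))
    test <- "chi-square"; statistic <- unname(ct$statistic); p <- ct$p.value
    n_by_group <- table(g)
    summaries <- do.call(rbind, lapply(rownames(tab), function(lv) {
      data.frame(
        level = paste0(variable, ": ", lv),
        total = fmt_n_pct(sum(tab[lv, ]), length(x)),
        stats::setNames(as.list(vapply(groups, function(gv)
          fmt_n_pct(tab[lv, gv], n_by_group[[gv]]), "")), groups),
        check.names = FALSE, stringsAsFactors = FALSE)
    }))
    normal <- NULL
  }
  structure(list(variable = variable, test = test, statistic = statistic,
                 p = p, summaries = summaries, normal = normal),
            class = "wbq_comparison")
}

#' @export
print.wbq_comparison <- function(x, ...) {
  cat(x$variable, ": ", x$test, " test, p = ", signif(x$p, 3), "\n", sep = "")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Build a descriptive comparison table
#'
#' Applies [compare_by_gender()] to a list of variables and stacks the
#' formatted summaries into one table (one row per variable or per category
#' level), with the test used and its p-value on the first row of each
#' variable block.
#'
#' @param data data.frame including `gender`.
#' @param variables character vector of columns.
#' @return data.frame: level, total, one column per gender, test, p.
#' @export
descriptive_table <- function(data, variables) {
  blocks <- lapply(variables, function(v) {
    cmp <- compare_by_gender(data, v)
    s <- cmp$summaries
    s$test <- c(cmp$test, rep("", nrow(s) - 1))
    s$p <- c(signif(cmp$p, 3), rep(NA, nrow(s) - 1))
    s
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
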