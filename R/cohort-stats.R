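#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality is tested in each group at `normality_alpha`; if
#' both groups are compatible with normality the two-sided pooled-variance
#' Student's t-test is used (Welch available via `var_equal = FALSE`),
#' otherwise the two-sided Mann-Whitney U (Wilcoxon rank-sum) test. Group
#' summaries are formatted to match the chosen branch: mean +/- SD for the
#' t branch, median (IQR) for the rank branch.
#'
#' @param values_by_group A named list of two numeric vectors (each n >= 3),
#'   e.g. `list(ALS = x, HC = y)`.
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @param var_equal Pooled-variance t (default `TRUE`).
#' @param variable Optional variable name carried into the result.
#' @return An object of class `group_comparison`: list with `variable`,
#'   `test_used` (`"student_t"` or `"mann_whitney"`), `statistic`, `p`,
#'   `normality_p` (named, per group), `summary` (named character).
#' @examples
#' set.seed(1)
#' compare_groups(list(ALS = rnorm(41, 0.01, 0.13), HC = rnorm(43, 0.16, 0.14)))
#' @export
compare_groups <- function(values_by_group, normality_alpha = 0.05,
                           var_equal = TRUE, variable = NULL) {
  if (!is.list(values_by_group) || length(values_by_group) != 2L) {
    stop("'values_by_group' must be a list of exactly two numeric vectors")
  }
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  if (any(vapply(values_by_group, length, 1L) < 3L)) {
    stop("each group needs at least 3 non-missing values")
  }
  norm_p <- vapply(values_by_group,
                   function(v) stats::shapiro.test(v)$p.value, numeric(1))
  normal <- all(norm_p >= normality_alpha)
  x <- values_by_group[[1]]
  y <- values_by_group[[2]]
  if (normal) {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    test_used <- "student_t"
    summ <- vapply(values_by_group, function(v)
      sprintf("%.3g ± %.3g", mean(v), stats::sd(v)), character(1))
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    test_used <- "mann_whitney"
    summ <- vapply(values_by_group, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3])
    }, character(1))
  }
  structure(list(variable = variable, test_used = test_used,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 normality_p = norm_p, summary = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s: statistic = %.4g, p = %.3g\n",
              if (is.null(x$variable)) "" else paste0(" ", x$variable),
              x$test_used, x$statistic, x$p))
  for (g in names(x$summary)) cat(sprintf("  %s: %s\n", g, x$summary[[g]]))
  invisible(x)
}

#' Pearson correlation matrix with FDR correction
#'
#' Pearson r and two-sided p for a declared family of variable pairs, with
#' Benjamini-Hochberg step-up q-values computed across exactly that family
#' (the family is explicit, never inferred from the data).
#'
#' @param table A data.frame of numeric marker columns.
#' @param pairs A list of character vectors of length 2 (column-name
#'   pairs), or a 2-column character matrix/data.frame.
#' @return A data.frame `var1, var2, n, r, p, q` (one row per pair).
#' @examples
#' d <- data.frame(a = rnorm(40), b = rnorm(40))
#' correlation_matrix(d, list(c("a", "b")))
#' @export
correlation_matrix <- function(table, pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, ]))
  }
  stopifnot(length(pairs) >= 1L)
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2L) stop("each pair must name exactly two columns")
    miss <- setdiff(pr, names(table))
    if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
    x <- table[[pr[1]]]
    y <- table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L) stop(sprintf("pair %s-%s has fewer than 4 complete cases",
                                   pr[1], pr[2]))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop(sprintf("pair %s-%s involves a constant variable", pr[1], pr[2]))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1], var2 = pr[2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Partial Pearson correlation given one covariate
#'
#' Residualizes `x` and `y` on the covariate by least squares and
#' correlates the residuals; the two-sided p-value uses n - 3 reference
#' degrees of freedom (one lost to the mean, one to the covariate, one to
#' the correlation). A constant covariate falls back to the plain
#' correlation with a warning.
#'
#' @param x,y,covariate Numeric vectors of equal length (n >= 5 complete
#'   cases).
#' @return A data.frame `n, r, p, covariate_used`.
#' @export
partial_correlation <- function(x, y, covariate) {
  ok <- stats::complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; cov <- covariate[ok]
  n <- length(x)
  if (n < 5L) stop("partial correlation needs at least 5 complete cases")
  if (stats::sd(cov) == 0) {
    warning("constant covariate; returning the plain correlation")
    ct <- stats::cor.test(x, y)
    return(data.frame(n = n, r = unname(ct$estimate), p = ct$p.value,
                      covariate_used = FALSE))
  }
  rx <- stats::lm.fit(cbind(1, cov), x)$residuals
  ry <- stats::lm.fit(cbind(1, cov), y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(n = n, r = r, p = p, covariate_used = TRUE)
}

#' Intraclass correlation for two repeated measurements
#'
#' Test-retest reproducibility from the two-way ANOVA decomposition of an
#' n x 2 measurement matrix (same rater, two sessions). Returns both the
#' two-way mixed consistency coefficient ICC(3,1) =
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E)` and the two-way absolute-agreement
#' coefficient `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k/n (MS_C - MS_E))`,
#' since reports often name one definition while printing the other.
#'
#' @param ratings An n x 2 numeric matrix or data.frame (n >= 5 subjects,
#'   no missing entries): rows = subjects, columns = repeated measurements.
#' @return A list `icc_consistency`, `icc_agreement`, plus the mean squares
#'   `ms_rows`, `ms_cols`, `ms_error`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(30, sd = 3)
#' icc_reproducibility(cbind(truth + rnorm(30), truth + rnorm(30)))
#' @export
icc_reproducibility <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("every subject needs both measurements")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k != 2L) stop("exactly 2 repeated measurements are required")
  if (n < 5L) stop("at least 5 subjects are required")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((ratings - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc_c <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  icc_a <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  list(icc_consistency = icc_c, icc_agreement = icc_a,
       ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e)
}

#' Marker group comparisons for a subject table
#'
#' Runs [compare_groups()] for each requested marker column of a subject
#' table, splitting on the `group` column.
#'
#' @param table A subject data.frame with a `group` column (two levels).
#' @param variables Character vector of numeric column names (default: the
#'   three glymphatic markers plus TIV).
#' @param normality_alpha Shapiro-Wilk gate level.
#' @return A data.frame with one row per variable: `variable, test_used,
#'   statistic, p`, and the two formatted group summaries.
#' @export
marker_comparisons <- function(table,
                               variables = c("alps_index", "coupling_index",
                                             "cpv_ml", "tiv_ml",
                                             "cpv_fraction_pct"),
                               normality_alpha = 0.05) {
  groups <- unique(table$group)
  if (length(groups) != 2L) stop("'group' must have exactly two levels")
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(split(table[[v]], factor(table$group, groups)),
                          normality_alpha = normality_alpha, variable = v)
    data.frame(variable = v, test_used = cmp$test_used,
               statistic = cmp$statistic, p = cmp$p,
               summary_1 = cmp$summary[[1]], summary_2 = cmp$summary[[2]])
  })
  out <- do.call(rbind, rows)
  names(out)[5:6] <- paste0("summary_", groups)
  out
}
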