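coerce_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    y <- as.integer(labels)
  } else {
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must contain exactly two classes")
    if (is.null(positive)) positive <- if ("ALS" %in% lev) "ALS" else lev[2]
    if (!positive %in% lev) stop("'positive' class not present in labels")
    y <- as.integer(labels == positive)
  }
  if (length(unique(y)) != 2L) stop("both classes must be present")
  y
}

#' ROC analysis of one diagnostic marker
#'
#' Empirical ROC curve over all distinct score thresholds, with AUC (equal
#' to the Mann-Whitney probability that a random case outscores a random
#' control, ties counted half), a DeLong 95% confidence interval, and the
#' Youden-optimal cut-off (maximizing sensitivity + specificity - 1).
#' Computation is delegated to the pROC package.
#'
#' @param scores Numeric marker values.
#' @param labels Class labels: 0/1, logical, or a two-level factor/character
#'   vector (class `"ALS"`, when present, is the positive class; override
#'   with `positive`).
#' @param direction `"auto"` (default) orients the marker so AUC >= 0.5;
#'   `"greater"` declares that higher scores indicate the positive class
#'   (e.g. the CPV fraction), `"less"` that lower scores do (e.g. the ALPS
#'   index or the coupling index in ALS).
#' @param positive Positive class label for factor/character `labels`.
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000 stratified
#'   replicates).
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (parallel vectors), `auc`, `ci95`, `cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `direction`, `n_pos`, `n_neg`.
#' @examples
#' roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("auto", "greater", "less"),
                         positive = NULL, conf_level = 0.95,
                         ci_method = c("delong", "bootstrap")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  y <- coerce_labels(labels, positive)
  if (anyNA(scores)) stop("scores must not contain missing values")
  # pROC's direction is stated as controls-vs-cases: "<" means controls
  # score lower than cases, i.e. higher score = positive class.
  proc_dir <- switch(direction, auto = "auto", greater = "<", less = ">")
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = proc_dir, quiet = TRUE)
  ci <- withCallingHandlers(
    if (ci_method == "delong") {
      pROC::ci.auc(roc, conf.level = conf_level, method = "delong")
    } else {
      pROC::ci.auc(roc, conf.level = conf_level, method = "bootstrap",
                   boot.n = 2000, progress = "none")
    },
    # a separable marker legitimately yields the degenerate 1-1 interval
    warning = function(w) {
      if (grepl("AUC == 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # first optimum on ties
  structure(list(
    thresholds = roc$thresholds,
    sensitivity = roc$sensitivities,
    specificity = roc$specificities,
    auc = as.numeric(roc$auc),
    ci95 = c(ci[1], ci[3]),
    cutoff = best$threshold,
    sens_at_cutoff = best$sensitivity,
    spec_at_cutoff = best$specificity,
    direction = if (roc$direction == "<") "greater" else "less",
    n_pos = sum(y == 1), n_neg = sum(y == 0)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), cutoff = %.4g (sens %.3f, spec %.3f), higher-is-positive: %s\n",
    x$auc, x$ci95[1], x$ci95[2], x$cutoff, x$sens_at_cutoff,
    x$spec_at_cutoff, x$direction == "greater"))
  invisible(x)
}

#' Fit the combined logistic diagnostic model
#'
#' Unregularized maximum-likelihood logistic regression (IRLS via
#' `stats::glm`, convergence tolerance 1e-8) of the class label on marker
#' main effects — by default the three glymphatic markers (coupling index,
#' ALPS index, CPV fraction). Complete separation is detected and raised as
#' an error instead of returning divergent coefficients.
#'
#' @param features A data.frame (or matrix) of numeric predictors.
#' @param labels Class labels, see [roc_analysis()].
#' @param positive Positive class label for factor/character `labels`.
#' @return An object of class `glym_logit`: `intercept`, `coefficients`
#'   (named per feature), `features` (names), `fitted` (probabilities),
#'   `data` (training predictors), `labels` (0/1), `converged`.
#' @export
fit_logistic <- function(features, labels, positive = NULL) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, TRUE))) {
    stop("all features must be numeric")
  }
  y <- coerce_labels(labels, positive)
  n <- nrow(features)
  p <- ncol(features)
  if (n <= p + 1L) stop("need more observations than features + 1")
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  mu <- fit$fitted.values
  boundary <- mu > 1 - 1e-8 | mu < 1e-8
  if (all((mu > 0.5) == (y == 1)) && any(boundary)) {
    stop("complete or quasi-complete separation detected; coefficients are not identifiable")
  }
  structure(list(intercept = unname(fit$coefficients[1]),
                 coefficients = fit$coefficients[-1],
                 features = colnames(features),
                 fitted = unname(mu),
                 data = features,
                 labels = y,
                 converged = fit$converged),
            class = "glym_logit")
}

#' Predicted probabilities from a fitted diagnostic model
#'
#' @param object A `glym_logit` model.
#' @param newdata A data.frame containing the model's feature columns;
#'   defaults to the training data.
#' @param ... Unused.
#' @return Vector of predicted probabilities in (0, 1).
#' @export
predict.glym_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[object$features])
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' @export
print.glym_logit <- function(x, ...) {
  cat("<glym_logit> logistic diagnostic model\n")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Nomogram point mapping for a logistic model
#'
#' Renders a fitted logistic model as the conventional point scales: each
#' feature's contribution `beta * x` over its observed (or supplied) range
#' is shifted to start at 0 and scaled so the feature with the largest
#' contribution span covers exactly 0-100 points; total points map back to
#' predicted probability through the inverse logit of the reconstructed
#' linear predictor (an affine function of total points, so the mapping is
#' exact, not read off a drawn axis).
#'
#' @param model A `glym_logit` model.
#' @param feature_ranges Optional named list of `c(min, max)` ranges; the
#'   default uses the observed range of each training feature.
#' @return An object of class `glym_nomogram`: per-feature `scales`
#'   (data.frame of value grid and points), `points_per_lp` (points per
#'   unit linear predictor), `lp_at_zero_points`, and a `prob_table`
#'   mapping total points to probability.
#' @export
build_nomogram <- function(model, feature_ranges = NULL) {
  stopifnot(inherits(model, "glym_logit"))
  beta <- model$coefficients
  if (all(abs(beta) < .Machine$double.eps)) {
    stop("cannot build a nomogram from an all-zero-coefficient model")
  }
  if (is.null(feature_ranges)) {
    feature_ranges <- lapply(model$data[model$features], range)
  }
  miss <- setdiff(model$features, names(feature_ranges))
  if (length(miss)) stop("missing range for feature(s): ",
                         paste(miss, collapse = ", "))
  lo <- vapply(model$features, function(f) min(feature_ranges[[f]]), 1)
  hi <- vapply(model$features, function(f) max(feature_ranges[[f]]), 1)
  if (!all(is.finite(c(lo, hi)))) stop("feature ranges must be finite")
  contrib_min <- pmin(beta * lo, beta * hi)
  span <- abs(beta * (hi - lo))
  scale <- 100 / max(span)
  scales <- lapply(seq_along(beta), function(j) {
    grid <- seq(lo[j], hi[j], length.out = 101)
    data.frame(value = grid,
               points = (beta[j] * grid - contrib_min[j]) * scale)
  })
  names(scales) <- model$features
  lp_at_zero <- model$intercept + sum(contrib_min)
  total_grid <- seq(0, sum(span) * scale, length.out = 201)
  prob_table <- data.frame(
    total_points = total_grid,
    probability = stats::plogis(lp_at_zero + total_grid / scale))
  structure(list(scales = scales, points_per_lp = scale,
                 lp_at_zero_points = lp_at_zero, prob_table = prob_table,
                 features = model$features, coefficients = beta,
                 contrib_min = contrib_min),
            class = "glym_nomogram")
}

#' Nomogram points assigned to subjects
#'
#' @param nomogram A `glym_nomogram`.
#' @param newdata Data.frame with the nomogram's feature columns.
#' @return Data.frame of per-feature points plus `total_points` and the
#'   probability implied by the total-points axis.
#' @export
nomogram_points <- function(nomogram, newdata) {
  stopifnot(inherits(nomogram, "glym_nomogram"))
  pts <- sapply(seq_along(nomogram$features), function(j) {
    f <- nomogram$features[j]
    (nomogram$coefficients[j] * newdata[[f]] - nomogram$contrib_min[j]) *
      nomogram$points_per_lp
  })
  pts <- matrix(pts, nrow = nrow(newdata))
  colnames(pts) <- paste0("points_", nomogram$features)
  total <- rowSums(pts)
  out <- as.data.frame(pts)
  out$total_points <- total
  out$probability <- stats::plogis(
    nomogram$lp_at_zero_points + total / nomogram$points_per_lp)
  out
}

#' Bootstrap optimism-corrected calibration curve
#'
#' Apparent calibration: subjects are binned by quantiles of predicted
#' probability (10 bins by default; bins with fewer than 2 subjects are
#' merged with a neighbor, with a warning) and the mean prediction is
#' compared with the observed event fraction per bin. Optimism: the model
#' is refitted on `n_boot` bootstrap resamples; each refit's per-bin
#' calibration error on its own resample minus its error on the original
#' data estimates how optimistic the apparent curve is, and the mean over
#' resamples is subtracted from the apparent observed fractions.
#'
#' @param model A `glym_logit` model (its training data and labels are the
#'   calibration sample).
#' @param n_boot Number of bootstrap refits (default 1000, >= 1).
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Integer seed for the resampling.
#' @return A data.frame of class `glym_calibration`: one row per bin with
#'   `n`, `predicted` (mean predicted probability), `observed` (event
#'   fraction), `optimism`, `observed_corrected`.
#' @export
calibration_bootstrap <- function(model, n_boot = 1000, n_bins = 10,
                                  seed = 1L) {
  stopifnot(inherits(model, "glym_logit"))
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("'n_boot' must be at least 1")
  p_hat <- model$fitted
  y <- model$labels
  edges <- unique(stats::quantile(p_hat, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  if (length(edges) < 3L) stop("predictions too concentrated to bin")
  bin_of <- function(p) {
    cut(p, breaks = edges, include.lowest = TRUE, labels = FALSE)
  }
  bins <- bin_of(p_hat)
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  while (any(counts > 0 & counts < 2L) && length(edges) > 2L) {
    warning("merging a calibration bin with fewer than 2 subjects into its neighbor")
    j <- which(counts > 0 & counts < 2L)[1]
    drop_edge <- if (j == length(counts)) j else j + 1L
    edges <- edges[-drop_edge]
    bins <- bin_of(p_hat)
    counts <- tabulate(bins, nbins = length(edges) - 1L)
  }
  used <- which(counts > 0)
  bin_err <- function(p, yy, b) {  # per-bin observed - predicted
    vapply(used, function(k) {
      i <- which(b == k)
      if (!length(i)) return(NA_real_)
      mean(yy[i]) - mean(p[i])
    }, numeric(1))
  }
  apparent_pred <- vapply(used, function(k) mean(p_hat[bins == k]), 1)
  apparent_obs <- vapply(used, function(k) mean(y[bins == k]), 1)
  set.seed(seed)
  n <- length(y)
  optimism <- matrix(NA_real_, n_boot, length(used))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) next  # degenerate resample
    fit_b <- tryCatch(fit_logistic(model$data[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
    if (is.null(fit_b)) next
    p_boot <- fit_b$fitted
    p_orig <- predict.glym_logit(fit_b, model$data)
    err_boot <- bin_err(p_boot, y[idx], bin_of(p_boot))
    err_orig <- bin_err(p_orig, y, bin_of(p_orig))
    optimism[b, ] <- err_boot - err_orig
  }
  opt <- colMeans(optimism, na.rm = TRUE)
  opt[is.nan(opt)] <- 0
  out <- data.frame(bin = seq_along(used), n = counts[used],
                    predicted = apparent_pred, observed = apparent_obs,
                    optimism = opt,
                    observed_corrected = apparent_obs - opt)
  class(out) <- c("glym_calibration", "data.frame")
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model's predicted probability at each
#' threshold probability `pt`: `NB(pt) = TP/N - FP/N * pt / (1 - pt)` under
#' the rule "treat when p >= pt", alongside the treat-all reference
#' `prevalence - (1 - prevalence) * pt / (1 - pt)` and the treat-none
#' reference (identically zero).
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param labels Class labels, see [roc_analysis()].
#' @param thresholds Threshold-probability grid, strictly inside (0, 1);
#'   default `seq(0.01, 0.99, by = 0.01)`.
#' @param positive Positive class label for factor/character `labels`.
#' @return A data.frame of class `dca_curve`: `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           positive = NULL) {
  y <- coerce_labels(labels, positive)
  if (length(thresholds) == 0L) stop("threshold grid must be nonempty")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    treat <- probabilities >= pt
    tp <- sum(treat & y == 1)
    fp <- sum(treat & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, numeric(1))
  treat_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = treat_all, treat_none = 0)
  class(out) <- c("dca_curve", "data.frame")
  out
}
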