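# Validation-performance measures: concordance statistic (discrimination) and
# calibration slope (calibration).

#' Concordance statistic (c-statistic / AUC)
#'
#' Probability that a randomly chosen event receives a higher prediction than
#' a randomly chosen non-event, with ties counted 1/2 — equivalent to the area
#' under the ROC curve.  Implemented rank-based (O(n log n)) via the
#' Wilcoxon--Mann--Whitney identity with midranks, which matches the all-pairs
#' definition exactly, ties included.
#'
#' @param y Binary outcome vector (0/1), both classes present.
#' @param p Prediction vector (any monotone score: probability or log-odds).
#' @return Scalar in \[0, 1\].
#' @examples
#' concordance_statistic(c(0, 1), c(0.2, 0.8))  # 1
#' @export
concordance_statistic <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both an event and a non-event are required")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope
#'
#' The slope coefficient from a maximum-likelihood logistic regression of the
#' outcome on the model's linear predictor (intercept included).  A slope
#' below 1 in independent validation data signals overfitting: predictions
#' too extreme.  The input must be on the log-odds scale — for
#' likelihood-ratio updaters, the posterior log-odds.
#'
#' @param y Binary outcome vector (0/1), both classes present.
#' @param lp Linear predictor (log-odds scale).
#' @return List with `slope`, `intercept`, and `converged` (separation or
#'   iteration exhaustion flags the fit rather than erroring).
#' @export
calibration_slope <- function(y, lp) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(lp), all(y %in% c(0, 1)))
  if (all(y == 1) || all(y == 0)) stop("both an event and a non-event are required")
  if (stats::var(lp) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, converged = FALSE))
  }
  fit <- irls_logistic(cbind(`(Intercept)` = 1, lp = lp), y)
  list(slope = unname(fit$coef[2]), intercept = unname(fit$coef[1]),
       converged = fit$converged)
}

#' Evaluate a model on a validation dataset
#'
#' Convenience wrapper computing both performance measures from a fitted
#' strategy object's linear predictor on a validation set.
#'
#' @param model Any fitted model object with a [linear_predictor()] method.
#' @param data A validation `predext_dataset`.
#' @return List of class `predext_performance`: `c_statistic`,
#'   `calibration_slope`, `slope_converged`, `n_events`, `n_nonevents`.
#' @export
evaluate_performance <- function(model, data) {
  lp <- linear_predictor(model, data)
  cs <- calibration_slope(data$y, lp)
  structure(
    list(c_statistic = concordance_statistic(data$y, lp),
         calibration_slope = cs$slope, slope_converged = cs$converged,
         n_events = sum(data$y == 1), n_nonevents = sum(data$y == 0)),
    class = "predext_performance"
  )
}

#' @export
print.predext_performance <- function(x, ...) {
  cat(sprintf("c-statistic: %.4f; calibration slope: %.4f (converged: %s); events: %d/%d\n",
              x$c_statistic, x$calibration_slope, x$slope_converged,
              x$n_events, x$n_events + x$n_nonevents))
  invisible(x)
}
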