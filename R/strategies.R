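# Regression-based strategies for extending an existing risk model with a new
# marker.  All fits are plain maximum likelihood on the marker set; nothing is
# penalized.  Strategy tags (serialization / CLI): original, revision,
# revision_shrinkage, recalibration, recalibration_extension, clr, clr_simple,
# imputation.

STRATEGY_TAGS <- c("original", "revision", "revision_shrinkage", "recalibration",
                   "recalibration_extension", "clr", "clr_simple", "imputation")

#' Model revision with extension
#'
#' Refits every regression coefficient, plus a coefficient for the new marker,
#' on the marker set alone.  Estimates `p + 2` parameters (intercept, `p`
#' predictor coefficients, marker coefficient), so it is the most flexible —
#' and in small marker sets the most overfitting-prone — regression strategy.
#'
#' @param marker_set A `predext_dataset` with fully observed marker.
#' @return A `predext_logistic` with a marker coefficient.
#' @export
revise_with_extension <- function(marker_set) {
  fit_logistic(marker_set, include_marker = TRUE)
}

#' Recalibrate an existing model on new data
#'
#' Fits a logistic model with a single covariate — the existing model's linear
#' predictor `lp0` — estimating only a new intercept and an overall
#' calibration slope (2 parameters).  Predictions depend on a patient only
#' through `lp0`.
#'
#' @param prior The existing `predext_logistic` (no marker coefficient used).
#' @param marker_set A `predext_dataset` with both outcome classes present.
#' @return An object of class `predext_recalibrated` with elements
#'   `alpha_hat`, `beta_overall`, `prior`, `fit_meta`.
#' @export
recalibrate <- function(prior, marker_set) {
  lp0 <- linear_predictor(prior, strip_marker_use(prior, marker_set))
  fit <- fit_logistic(marker_set, fixed_covariate = lp0)
  structure(
    list(alpha_hat = fit$alpha, beta_overall = unname(fit$betas[1]),
         prior = prior, fit_meta = fit$fit_meta),
    class = "predext_recalibrated"
  )
}

# evaluate a prior (no-marker) model even when the dataset carries a marker
strip_marker_use <- function(prior, data) {
  if (is.null(prior$beta_marker)) data else stop("prior model must not contain a marker term")
}

#' @export
linear_predictor.predext_recalibrated <- function(model, data, ...) {
  lp0 <- linear_predictor(model$prior, data)
  model$alpha_hat + model$beta_overall * lp0
}

#' Heuristic shrinkage factor
#'
#' \eqn{\hat c = \max(\chi^2 - df, 0) / \chi^2}: the estimated fraction of the
#' revision model's likelihood gain over the recalibrated model that is signal
#' rather than noise.  Returns 0 when `chi2 = 0` or `chi2 <= df`.
#'
#' @param chi2 Difference in -2 log-likelihood between the recalibrated and
#'   the revised fit (must be >= 0).
#' @param df Difference in the number of estimated parameters.
#' @return A scalar in \[0, 1\].
#' @examples
#' heuristic_shrinkage_factor(10, 4)  # 0.6
#' @export
heuristic_shrinkage_factor <- function(chi2, df) {
  if (chi2 < 0) stop("chi2 < 0: nested-model likelihood ordering violated upstream")
  if (chi2 == 0) return(0)
  max(chi2 - df, 0) / chi2
}

#' Model revision with shrinkage
#'
#' Fits both the revised model (`lp1`, all coefficients plus marker) and the
#' recalibrated model (`lp2`, intercept and overall slope on `lp0`) on the
#' same marker set, and blends their linear predictors:
#' \eqn{lp_3 = \hat c \, lp_1 + (1-\hat c)\, lp_2}, with \eqn{\hat c} the
#' heuristic shrinkage factor computed from the -2 log-likelihood difference
#' (`chi2`) and the difference in estimated parameter counts (`df`).  Because
#' `lp2` has no marker term, the effective marker coefficient is
#' \eqn{\hat c \hat\beta_{p+1}}: shrunk toward zero.
#'
#' By default `df` is the count difference `(p + 2) - 2 = p`; pass `df` to
#' override with a different degrees-of-freedom accounting.
#'
#' @inheritParams recalibrate
#' @param df Optional override of the degrees-of-freedom difference.
#' @return An object of class `predext_shrunken` with elements `revised`,
#'   `recalibrated`, `chi2`, `df`, `c_hat`.
#' @export
revise_with_shrinkage <- function(prior, marker_set, df = NULL) {
  revised <- revise_with_extension(marker_set)
  recal <- recalibrate(prior, marker_set)
  chi2 <- recal$fit_meta$m2ll - revised$fit_meta$m2ll
  both_ok <- revised$fit_meta$converged && recal$fit_meta$converged
  if (chi2 < 0) {
    if (both_ok && chi2 > -1e-6) {
      chi2 <- 0  # numerical noise at the optimum
    } else {
      both_ok <- FALSE
      chi2 <- max(chi2, 0)
    }
  }
  if (is.null(df)) {
    df <- revised$fit_meta$n_params - recal$fit_meta$n_params
  }
  structure(
    list(revised = revised, recalibrated = recal, chi2 = chi2,
         df = as.integer(df),
         c_hat = heuristic_shrinkage_factor(chi2, df),
         fit_meta = list(converged = both_ok,
                         message = if (both_ok) "ok" else "component fit unconverged")),
    class = "predext_shrunken"
  )
}

#' @export
linear_predictor.predext_shrunken <- function(model, data, ...) {
  model$c_hat * linear_predictor(model$revised, data) +
    (1 - model$c_hat) * linear_predictor(model$recalibrated, data)
}

#' Recalibration with extension
#'
#' Fits a logistic model on two covariates — the existing model's linear
#' predictor `lp0` and the new marker — estimating 3 parameters for a single
#' marker.  Parsimonious: predictor effects move only jointly through the
#' overall slope.
#'
#' @inheritParams recalibrate
#' @return An object of class `predext_recal_extended` with elements
#'   `alpha_hat`, `beta_overall`, `beta_marker`, `prior`, `fit_meta`.
#' @export
recalibrate_with_extension <- function(prior, marker_set) {
  if (!marker_complete(marker_set)) stop("marker must be fully observed")
  lp0 <- linear_predictor(prior, strip_marker_use(prior, marker_set))
  fit <- fit_logistic(marker_set, include_marker = TRUE, fixed_covariate = lp0)
  structure(
    list(alpha_hat = fit$alpha, beta_overall = unname(fit$betas[1]),
         beta_marker = fit$beta_marker, prior = prior, fit_meta = fit$fit_meta),
    class = "predext_recal_extended"
  )
}

#' @export
linear_predictor.predext_recal_extended <- function(model, data, ...) {
  if (!marker_complete(data)) stop("marker must be fully observed for prediction")
  lp0 <- linear_predictor(model$prior, data)
  model$alpha_hat + model$beta_overall * lp0 + model$beta_marker * data$marker
}

#' Number of parameters estimated by an updating strategy
#'
#' The accounting used to compare how heavily each strategy leans on the new
#' data: `p` is the number of predictor coefficients in the existing model and
#' `m` the number of markers (this package exercises `m = 1`; the formulas are
#' general).
#'
#' * `original`: 0 (no data used)
#' * `revision`, `revision_shrinkage`, `imputation`: `p + m + 1`
#' * `recalibration`: 2 (intercept and overall slope; no marker)
#' * `recalibration_extension`: `m + 2`
#' * `clr`: `2m(p + 1) + m(m + 1)`
#' * `clr_simple`: `m(p + 2) + m(m + 1)/2`
#'
#' @param strategy One of the strategy tags.
#' @param p Number of predictor coefficients in the existing model (>= 1).
#' @param m Number of markers (>= 1).
#' @return Integer parameter count.
#' @examples
#' parameter_count("clr", p = 3, m = 1)         # 10
#' parameter_count("imputation", p = 3, m = 1)  # 5
#' @export
parameter_count <- function(strategy, p, m = 1L) {
  strategy <- match.arg(strategy, STRATEGY_TAGS)
  stopifnot(p >= 1, m >= 1)
  p <- as.integer(p); m <- as.integer(m)
  as.integer(switch(strategy,
    original                = 0L,
    revision                = p + m + 1L,
    revision_shrinkage      = p + m + 1L,
    recalibration           = 2L,
    recalibration_extension = m + 2L,
    clr                     = 2L * m * (p + 1L) + m * (m + 1L),
    clr_simple              = m * (p + 2L) + (m * (m + 1L)) %/% 2L,
    imputation              = p + m + 1L
  ))
}

# convergence accessor shared across strategy objects
strategy_converged <- function(model) {
  fm <- model$fit_meta
  if (!is.null(fm$converged)) return(isTRUE(fm$converged))
  TRUE
}
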