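# Bayes-rule updating of an existing model's predictions with a conditional
# likelihood ratio (LR) for the new marker.  The marker is modelled as
# conditionally normal given the predictors; the LR is the ratio of the
# case and control normal densities at the observed marker value, and
# posterior odds = prior odds x LR.  Predictor effects of the existing model
# are never modified.

# OLS of marker on a design matrix (intercept included), residual SD with the
# unbiased denominator n - q.
ols_marker_fit <- function(Z, m, label) {
  n <- nrow(Z)
  q <- ncol(Z)
  if (n <= q) {
    stop(sprintf("group '%s' too small (%d rows) to estimate %d mean parameters plus a residual SD",
                 label, n, q))
  }
  qr_ <- qr(Z)
  if (qr_$rank < q) {
    stop(sprintf("rank-deficient predictor design in group '%s'", label))
  }
  coef <- qr.coef(qr_, m)
  resid <- m - drop(Z %*% coef)
  s2 <- sum(resid^2) / (n - q)
  if (s2 <= 0 || sqrt(s2) < 1e-10) {
    stop(sprintf("zero residual variance in group '%s': marker is an exact linear function of the predictors (degenerate density)", label))
  }
  list(coef = stats::setNames(drop(coef), colnames(Z)), residual_sd = sqrt(s2), n = n)
}

#' Conditional marker model
#'
#' A linear-normal model of the marker given the encoded predictors: mean
#' `intercept + slopes %*% x`, residual standard deviation `residual_sd > 0`.
#' Pairs of these models (case and control) define a conditional likelihood
#' ratio; they also specify marker generation in truth models.
#'
#' @param intercept Mean-model intercept.
#' @param slopes Mean-model slopes, one per encoded predictor column.
#' @param residual_sd Residual standard deviation (> 0).
#' @return List with elements `coef` (named vector, intercept first) and
#'   `residual_sd`.
#' @export
conditional_marker_model <- function(intercept, slopes, residual_sd) {
  stopifnot(residual_sd > 0)
  list(coef = c(`(Intercept)` = as.numeric(intercept),
                stats::setNames(as.numeric(slopes), names(slopes))),
       residual_sd = as.numeric(residual_sd))
}

cmm_mean <- function(cmm, X) {
  cmm$coef[1] + drop(X %*% cmm$coef[-1])
}

#' Fit the full conditional-likelihood-ratio updater
#'
#' Splits the marker set by outcome and fits, in each group, an ordinary
#' least-squares regression of the marker on the encoded predictors.  The two
#' fitted mean models and their residual standard deviations define the case
#' and control conditional normal densities of the marker; their ratio is the
#' likelihood ratio used to update the prior model's odds.  Estimates
#' `2(p + 1)` mean coefficients plus 2 residual SDs.
#'
#' @param prior The existing `predext_logistic` (must have no marker term).
#' @param marker_set A `predext_dataset` with fully observed marker and both
#'   outcome groups large enough to estimate `p + 1` mean parameters plus a
#'   residual SD.
#' @return An object of class `predext_clr` with elements `prior`, `variant`
#'   (`"full"`), `case_model`, `control_model`.
#' @export
fit_clr <- function(prior, marker_set) {
  stopifnot(inherits(prior, "predext_logistic"))
  if (!is.null(prior$beta_marker)) stop("prior model must not contain a marker term")
  if (!marker_complete(marker_set)) stop("marker must be fully observed")
  Z <- cbind(`(Intercept)` = 1, marker_set$X)
  fits <- lapply(c(control = 0, case = 1), function(g) {
    idx <- marker_set$y == g
    ols_marker_fit(Z[idx, , drop = FALSE], marker_set$marker[idx],
                   label = if (g == 1) "case" else "control")
  })
  structure(
    list(prior = prior, variant = "full",
         case_model = fits$case[c("coef", "residual_sd")],
         control_model = fits$control[c("coef", "residual_sd")],
         fit_meta = list(converged = TRUE,
                         n_case = fits$case$n, n_control = fits$control$n)),
    class = c("predext_clr")
  )
}

#' Fit the parsimonious ("simple") conditional-likelihood-ratio updater
#'
#' A single OLS regression of the marker on the encoded predictors plus the
#' outcome indicator, with one shared residual SD: the case and control
#' conditional means differ only by the indicator coefficient.  Estimates
#' `p + 2` mean coefficients plus 1 residual SD.
#'
#' @inheritParams fit_clr
#' @return A `predext_clr` with `variant = "simple"`; `case_model` and
#'   `control_model` are derived from the shared fit and stored explicitly so
#'   prediction code is variant-agnostic.
#' @export
fit_clr_simple <- function(prior, marker_set) {
  stopifnot(inherits(prior, "predext_logistic"))
  if (!is.null(prior$beta_marker)) stop("prior model must not contain a marker term")
  if (!marker_complete(marker_set)) stop("marker must be fully observed")
  if (!any(marker_set$y == 1) || !any(marker_set$y == 0)) {
    stop("both outcome groups must be non-empty")
  }
  Z <- cbind(`(Intercept)` = 1, marker_set$X, outcome = marker_set$y)
  fit <- ols_marker_fit(Z, marker_set$marker, label = "pooled")
  q <- length(fit$coef)
  base <- fit$coef[-q]            # intercept + p predictor slopes
  delta <- fit$coef[q]            # outcome-indicator coefficient
  control <- list(coef = base, residual_sd = fit$residual_sd)
  case <- control
  case$coef[1] <- case$coef[1] + delta
  structure(
    list(prior = prior, variant = "simple",
         case_model = case, control_model = control,
         shared_fit = list(coef = fit$coef, residual_sd = fit$residual_sd),
         fit_meta = list(converged = TRUE, n = fit$n)),
    class = c("predext_clr")
  )
}

#' Conditional likelihood ratio of a marker value
#'
#' Evaluates \eqn{LR = \phi(m; \mu_{case}(x), \sigma_{case}) /
#' \phi(m; \mu_{control}(x), \sigma_{control})} for each row, where the
#' conditional means are the fitted per-group linear predictors of the marker.
#' Computed on the log scale; strictly positive and finite.
#'
#' @param updater A fitted `predext_clr`.
#' @param X Encoded predictor matrix (rows to evaluate).
#' @param m Marker values, one per row of `X`.
#' @param log Return log LR instead of LR.
#' @return Numeric vector of (log) likelihood ratios.
#' @export
likelihood_ratio <- function(updater, X, m, log = FALSE) {
  stopifnot(inherits(updater, "predext_clr"))
  X <- matrix(as.numeric(X), ncol = length(updater$case_model$coef) - 1L)
  loglr <- stats::dnorm(m, cmm_mean(updater$case_model, X),
                        updater$case_model$residual_sd, log = TRUE) -
    stats::dnorm(m, cmm_mean(updater$control_model, X),
                 updater$control_model$residual_sd, log = TRUE)
  if (log) loglr else exp(loglr)
}

#' Update prior predictions with the conditional likelihood ratio
#'
#' Bayes rule on the odds scale: posterior odds = exp(lp0) x LR.  Returns the
#' posterior probability; the posterior log-odds (`lp0 + log LR`), needed for
#' calibration-slope evaluation, is available via [linear_predictor()].
#'
#' @param updater A fitted `predext_clr`.
#' @param data A `predext_dataset` with fully observed marker.
#' @return Numeric vector of posterior event probabilities in (0, 1).
#' @export
update_prediction <- function(updater, data) {
  stats::plogis(linear_predictor(updater, data))
}

#' @export
linear_predictor.predext_clr <- function(model, data, ...) {
  stopifnot(inherits(data, "predext_dataset"))
  if (!marker_complete(data)) stop("marker must be fully observed")
  lp0 <- linear_predictor(model$prior, data)
  lp0 + likelihood_ratio(model, data$X, data$marker, log = TRUE)
}

#' @export
print.predext_clr <- function(x, ...) {
  cat(sprintf("Conditional likelihood ratio updater (%s variant)\n", x$variant))
  cat("  case model:    sd =", format(x$case_model$residual_sd), "\n")
  cat("  control model: sd =", format(x$control_model$residual_sd), "\n")
  invisible(x)
}
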