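# Combine-and-impute strategy: stack the development set (marker
# systematically missing) with the marker set, multiply impute the missing
# marker, fit the extended logistic model in each completed dataset and pool
# the coefficients by averaging (Rubin's rules for point estimates).
#
# Only one variable is ever incomplete, so chained equations reduce to a
# single Bayesian-linear-regression imputation model: the marker regressed on
# all encoded predictors plus the outcome, with parameter draws from their
# approximate posterior and residual noise added to every imputed value
# (proper imputation, matching the behaviour of standard chained-equations
# software for a single incomplete continuous variable).

#' Multiply impute a systematically missing marker
#'
#' Stacks the development and marker sets and returns `n_imputations`
#' completed datasets.  Observed marker values are never altered; development
#' rows receive random draws from the imputation model
#' `marker ~ predictors + outcome` fitted on the marker-set rows: for each
#' imputation, the residual variance is drawn from its scaled inverse
#' chi-squared posterior, the regression coefficients from their conditional
#' normal, and each imputed value adds N(0, sigma*^2) residual noise.
#'
#' @param dev_set `predext_dataset` with no marker (systematically missing).
#' @param marker_set `predext_dataset` with fully observed marker and an
#'   identical schema.
#' @param n_imputations Number of completed datasets (default 10).
#' @param seed Optional integer seed for reproducible draws.
#' @return List of `n_imputations` completed `predext_dataset`s, development
#'   rows first and marker-set rows after, each with a fully observed marker.
#' @export
impute_marker <- function(dev_set, marker_set, n_imputations = 10L, seed = NULL) {
  stopifnot(inherits(dev_set, "predext_dataset"), inherits(marker_set, "predext_dataset"))
  if (!identical(unclass(dev_set$schema), unclass(marker_set$schema))) {
    stop("development and marker sets must share one schema")
  }
  if (!marker_complete(marker_set)) stop("marker set must have a fully observed marker")
  if (!is.null(dev_set$marker)) stop("development set must have no observed marker")
  p <- dev_set$schema$p
  if (marker_set$n < p + 3L) {
    stop(sprintf("marker set too small (%d rows) to fit the imputation model (need >= %d)",
                 marker_set$n, p + 3L))
  }
  if (!is.null(seed)) set.seed(seed)

  Zobs <- cbind(`(Intercept)` = 1, marker_set$X, outcome = marker_set$y)
  Zmis <- cbind(`(Intercept)` = 1, dev_set$X, outcome = dev_set$y)
  m_obs <- marker_set$marker
  qr_ <- qr(Zobs)
  q <- ncol(Zobs)
  if (qr_$rank < q) stop("rank-deficient imputation design in the marker set")
  beta_hat <- qr.coef(qr_, m_obs)
  resid <- m_obs - drop(Zobs %*% beta_hat)
  sse <- sum(resid^2)
  R <- qr.R(qr_)                              # chol factor of Zobs'Zobs (up to signs)
  nu <- marker_set$n - q

  stacked <- dataset_stack(dev_set, marker_set)
  mis_idx <- seq_len(dev_set$n)               # dev rows come first in the stack
  lapply(seq_len(n_imputations), function(j) {
    sigma2_star <- sse / stats::rchisq(1L, nu)
    # beta* ~ N(beta_hat, sigma2* (Z'Z)^-1) via the R factor
    beta_star <- beta_hat + sqrt(sigma2_star) * backsolve(R, stats::rnorm(q))
    draws <- drop(Zmis %*% beta_star) + stats::rnorm(dev_set$n, 0, sqrt(sigma2_star))
    marker <- stacked$marker
    marker[mis_idx] <- draws
    new_dataset(stacked$schema, stacked$X, stacked$y, marker = marker)
  })
}

#' Fit the extended model on completed datasets and pool
#'
#' Fits the extended logistic model (predictors + marker) on each completed
#' dataset and pools the per-imputation coefficient vectors by their
#' coordinate-wise mean.
#'
#' @param completed List of completed `predext_dataset`s (fully observed
#'   marker), as returned by [impute_marker()].
#' @return An object of class `predext_pooled` with elements `per_imputation`
#'   (list of named coefficient vectors, intercept first, marker last),
#'   `pooled` (their mean), `J`, `schema`, `fit_meta` (overall convergence and
#'   the per-imputation flags).
#' @export
fit_pooled <- function(completed) {
  stopifnot(length(completed) >= 1L)
  fits <- lapply(completed, fit_logistic, include_marker = TRUE)
  coefs <- lapply(fits, function(f) c(`(Intercept)` = f$alpha, f$betas, marker = f$beta_marker))
  conv <- vapply(fits, function(f) f$fit_meta$converged, logical(1))
  pooled <- Reduce(`+`, coefs) / length(coefs)
  structure(
    list(per_imputation = coefs, pooled = pooled, J = length(coefs),
         schema = completed[[1]]$schema,
         fit_meta = list(converged = all(conv), per_imputation_converged = conv,
                         message = if (all(conv)) "ok" else "one or more per-imputation fits unconverged")),
    class = "predext_pooled"
  )
}

#' @export
linear_predictor.predext_pooled <- function(model, data, ...) {
  stopifnot(inherits(data, "predext_dataset"))
  if (!marker_complete(data)) stop("marker must be fully observed for prediction")
  p <- model$schema$p
  cf <- model$pooled
  cf[1] + drop(data$X %*% cf[1 + seq_len(p)]) + cf[p + 2L] * data$marker
}

#' @export
print.predext_pooled <- function(x, ...) {
  cat(sprintf("Pooled extended model over J = %d imputations\n", x$J))
  print(round(x$pooled, 4))
  invisible(x)
}
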