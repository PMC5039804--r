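# ---- IRLS core --------------------------------------------------------------

# Damped Newton / iteratively reweighted least squares for binary logistic
# regression.  X includes the intercept column.  Convergence: relative change
# in -2 log-likelihood below `tol`.  Divergence of coefficients (complete or
# quasi-complete separation) and iteration exhaustion are flagged, never
# silently accepted.
irls_logistic <- function(X, y, offset = NULL, tol = 1e-8, max_iter = 100L,
                          coef_bound = 1e4) {
  n <- nrow(X)
  q <- ncol(X)
  if (is.null(offset)) offset <- rep(0, n)
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate outcome: all events or all non-events")
  }
  beta <- numeric(q)
  # start from the marginal log-odds in the intercept if present
  const_cols <- apply(X, 2L, function(col) all(col == col[1]))
  if (any(const_cols & X[1, ] != 0)) {
    ic <- which(const_cols & X[1, ] != 0)[1]
    beta[ic] <- stats::qlogis(mean(y)) / X[1, ic]
  }
  m2ll_of <- function(beta) {
    eta <- drop(X %*% beta) + offset
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }
  dev <- m2ll_of(beta)
  converged <- FALSE
  msg <- "ok"
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- (y - p)
    g <- crossprod(X, z)                      # score
    H <- crossprod(X * w, X)                  # expected information
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      # rank-deficient information: fall back to least-squares direction
      step <- tryCatch(qr.solve(H, g, tol = 1e-12), error = function(e) NULL)
      if (is.null(step)) {
        msg <- "singular information matrix (collinear design)"
        break
      }
    }
    # step-halving if the deviance does not improve
    lambda <- 1
    repeat {
      cand <- beta + lambda * drop(step)
      dev_new <- m2ll_of(cand)
      if (dev_new <= dev + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    rel <- abs(dev - dev_new) / (abs(dev) + 0.1)
    beta <- cand
    dev <- dev_new
    if (max(abs(beta)) > coef_bound) {
      msg <- "coefficients diverging: possible complete or quasi-complete separation"
      break
    }
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && msg == "ok") {
    msg <- sprintf("no convergence within %d iterations", max_iter)
  }
  if (converged && dev < 1e-6 * n) {
    # a numerically perfect fit on finite coefficients means the classes are
    # completely separated; the MLE does not exist
    converged <- FALSE
    msg <- "perfect fit: complete separation, maximum-likelihood estimate does not exist"
  }
  list(coef = drop(beta), converged = converged, m2ll = dev,
       n = n, n_params = q, message = msg, iterations = it)
}

# ---- user-facing fitting ----------------------------------------------------

#' Fit a logistic regression risk model by maximum likelihood
#'
#' Plain (unpenalized) maximum-likelihood logistic regression on the encoded
#' predictors of a dataset, optionally extended with the marker.  When
#' `fixed_covariate` is supplied it *replaces* the predictor design: the model
#' is then an intercept plus that single column (plus the marker when
#' requested) — the mechanism used to recalibrate on a frozen linear
#' predictor.
#'
#' No penalization or ridge fallback is applied anywhere: small-sample
#' overfitting is part of what downstream comparisons measure.  Separation and
#' non-convergence are flagged via `fit_meta$converged`, never hidden.
#'
#' @param data A `predext_dataset` with at least one event and one non-event.
#' @param include_marker Include the marker as a predictor (requires a fully
#'   observed marker).
#' @param offset Optional fixed offset on the linear-predictor scale.
#' @param fixed_covariate Optional numeric vector used as the single covariate
#'   instead of the predictor matrix.
#' @return An object of class `predext_logistic` with elements `alpha`,
#'   `betas` (named, length `schema$p`, or length 1 for a fixed covariate),
#'   `beta_marker` (or `NULL`), `schema`, and `fit_meta` (list: `converged`,
#'   `m2ll`, `n`, `n_params`, `message`).
#' @export
fit_logistic <- function(data, include_marker = FALSE, offset = NULL,
                         fixed_covariate = NULL) {
  stopifnot(inherits(data, "predext_dataset"))
  if (include_marker && !marker_complete(data)) {
    stop("include_marker = TRUE requires a fully observed marker")
  }
  if (is.null(fixed_covariate)) {
    Z <- data$X
  } else {
    fixed_covariate <- as.numeric(fixed_covariate)
    if (length(fixed_covariate) != data$n) {
      stop("fixed_covariate must have one entry per row")
    }
    if (stats::var(fixed_covariate) == 0) {
      stop("fixed_covariate is constant: degenerate single-covariate design")
    }
    Z <- matrix(fixed_covariate, ncol = 1, dimnames = list(NULL, "fixed"))
  }
  if (include_marker) Z <- cbind(Z, marker = data$marker)
  design <- cbind(`(Intercept)` = 1, Z)
  fit <- irls_logistic(design, data$y, offset = offset)
  k <- ncol(Z) - include_marker
  structure(
    list(
      alpha = unname(fit$coef[1]),
      betas = stats::setNames(fit$coef[seq_len(k) + 1L], colnames(Z)[seq_len(k)]),
      beta_marker = if (include_marker) unname(fit$coef[length(fit$coef)]) else NULL,
      schema = if (is.null(fixed_covariate)) data$schema else NULL,
      fit_meta = fit[c("converged", "m2ll", "n", "n_params", "message")]
    ),
    class = "predext_logistic"
  )
}

#' Construct a logistic model from known coefficients
#'
#' Builds a `predext_logistic` without fitting — used to specify truth models
#' for the synthetic-data generator or externally published coefficients.
#'
#' @param alpha Intercept (logit scale).
#' @param betas Coefficient vector aligned with the schema's encoded columns.
#' @param schema The matching [predictor_schema()].
#' @param beta_marker Optional marker coefficient.
#' @return A `predext_logistic` flagged as externally specified.
#' @export
logistic_model <- function(alpha, betas, schema, beta_marker = NULL) {
  stopifnot(inherits(schema, "predext_schema"))
  betas <- stats::setNames(as.numeric(betas), encoded_column_names(schema))
  if (length(betas) != schema$p) stop("betas must match the encoded width p")
  structure(
    list(alpha = as.numeric(alpha), betas = betas,
         beta_marker = if (!is.null(beta_marker)) as.numeric(beta_marker),
         schema = schema,
         fit_meta = list(converged = TRUE, m2ll = NA_real_, n = NA_integer_,
                         n_params = NA_integer_, message = "externally specified")),
    class = "predext_logistic"
  )
}

#' @export
print.predext_logistic <- function(x, ...) {
  cat("Logistic risk model",
      if (!is.null(x$beta_marker)) "(with marker)" else "(no marker)", "\n")
  cf <- c(`(Intercept)` = x$alpha, x$betas,
          if (!is.null(x$beta_marker)) c(marker = x$beta_marker))
  print(round(cf, 4))
  cat(sprintf("converged: %s; -2logLik: %s; n: %s\n",
              x$fit_meta$converged, format(x$fit_meta$m2ll), x$fit_meta$n))
  invisible(x)
}

# ---- predictions ------------------------------------------------------------

#' Linear predictor of a model on a dataset
#'
#' Evaluates the log-odds-scale score of a fitted or specified model for every
#' row of a dataset.  For conditional-likelihood-ratio updaters this is the
#' posterior log-odds (see [update_prediction()]); for every regression-based
#' strategy it is the strategy's `lp`.
#'
#' @param model A fitted model object from this package.
#' @param data A `predext_dataset` compatible with the model's schema.
#' @param ... Passed on to methods.
#' @return Numeric vector, one log-odds value per row.
#' @export
linear_predictor <- function(model, data, ...) UseMethod("linear_predictor")

#' @export
linear_predictor.predext_logistic <- function(model, data, ...) {
  stopifnot(inherits(data, "predext_dataset"))
  if (!is.null(model$schema)) {
    if (ncol(data$X) != model$schema$p ||
        !identical(colnames(data$X), encoded_column_names(model$schema))) {
      stop("schema mismatch between model and dataset")
    }
    lp <- model$alpha + drop(data$X %*% model$betas)
  } else {
    stop("model was fitted on a fixed covariate; supply it via its strategy object")
  }
  if (!is.null(model$beta_marker)) {
    if (!marker_complete(data)) stop("model has a marker coefficient but the marker is not fully observed")
    lp <- lp + model$beta_marker * data$marker
  }
  lp
}

#' Predicted event probabilities
#'
#' Inverse-logit of [linear_predictor()]; values are strictly inside (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric probability vector.
#' @export
predict_probability <- function(model, data, ...) {
  lp <- linear_predictor(model, data, ...)
  p <- stats::plogis(lp)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' -2 log-likelihood of a model on a dataset
#'
#' Evaluates \eqn{-2 \sum [y \log p + (1-y)\log(1-p)]} for the model's
#' predicted probabilities, clamping probabilities at 1e-12 from each boundary
#' before taking logs.
#'
#' @inheritParams linear_predictor
#' @return Non-negative scalar.
#' @export
minus_two_log_likelihood <- function(model, data, ...) {
  p <- predict_probability(model, data, ...)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(data$y * log(p) + (1 - data$y) * log(1 - p))
}
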