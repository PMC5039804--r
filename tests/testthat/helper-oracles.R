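# Independent oracles used to check package computations against a second
# route.  These never call the package's own fitting/metric code.

# ML logistic fit via stats::glm (IRLS as implemented in base R)
oracle_logistic <- function(X, y, offset = NULL) {
  df <- as.data.frame(X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial(),
                                     offset = offset))
  list(coef = stats::coef(fit), m2ll = as.numeric(fit$deviance),
       se = summary(fit)$coefficients[, "Std. Error"],
       converged = fit$converged)
}

# All-pairs O(n^2) concordance with ties counted 1/2
oracle_concordance <- function(y, p) {
  pe <- p[y == 1]
  pn <- p[y == 0]
  tot <- 0
  for (a in pe) tot <- tot + sum(a > pn) + 0.5 * sum(a == pn)
  tot / (length(pe) * length(pn))
}

# Direct summation of -2 log-likelihood from probabilities
oracle_m2ll <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# OLS coefficients + unbiased residual SD via stats::lm
oracle_ols <- function(X, m) {
  fit <- stats::lm(m ~ ., data = as.data.frame(X))
  list(coef = stats::coef(fit), residual_sd = summary(fit)$sigma,
       se = summary(fit)$coefficients[, "Std. Error"])
}
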