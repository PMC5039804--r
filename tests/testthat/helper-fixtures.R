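# Small in-code fixtures shared across test files.

fix_schema <- function() {
  predictor_schema(
    names  = c("psa", "volume", "dre"),
    kinds  = c("continuous", "categorical", "categorical"),
    levels = list(volume = c("vol25", "vol40", "vol60"), dre = c("no", "yes"))
  )
}

# dataset of n rows drawn from a known logistic truth on 2 standard-normal
# predictors (simple schema), optionally with a normal marker
fix_dataset_2p <- function(n, alpha = -0.5, betas = c(x1 = 0.8, x2 = -0.6),
                           beta_marker = NULL, seed = 1) {
  set.seed(seed)
  sch <- predictor_schema(c("x1", "x2"), c("continuous", "continuous"))
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  lp <- alpha + drop(X %*% betas)
  marker <- NULL
  if (!is.null(beta_marker)) {
    marker <- rnorm(n, 1 + 0.5 * X[, 1], 1)
    lp <- lp + beta_marker * marker
  }
  y <- rbinom(n, 1, plogis(lp))
  new_dataset(sch, X, y, marker = marker)
}

# dataset on the package's default synthetic population
fix_marker_set <- function(n, seed = 1, config = default_logistic_config()) {
  generate_dataset(config, n, seed = seed)
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
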