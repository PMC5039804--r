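# helper: a hand-built updater on a 1-predictor schema
toy_updater <- function(mu_case, mu_control, sd_case, sd_control,
                        slope_case = 0, slope_control = 0) {
  sch <- predictor_schema("x", "continuous")
  structure(
    list(prior = logistic_model(0, 0.7, sch), variant = "full",
         case_model = conditional_marker_model(mu_case, c(x = slope_case), sd_case),
         control_model = conditional_marker_model(mu_control, c(x = slope_control), sd_control),
         fit_meta = list(converged = TRUE)),
    class = "predext_clr")
}

test_that("likelihood_ratio evaluates the normal-density ratio", {
  # identical case and control models: LR = 1 everywhere
  u <- toy_updater(1, 1, 2, 2, 0.5, 0.5)
  X <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  m <- seq(-3, 3, length.out = 9)
  expect_equal(likelihood_ratio(u, X, m), rep(1, 9))

  # mu_case = 1, mu_control = 0, shared sd 1, m = 1: LR = phi(0)/phi(1)
  u2 <- toy_updater(1, 0, 1, 1)
  expect_equal(likelihood_ratio(u2, matrix(0), 1),
               dnorm(1, 1, 1) / dnorm(1, 0, 1))
  expect_equal(likelihood_ratio(u2, matrix(0), 1), exp(0.5))

  # equal means, unequal sds, m at the shared mean: LR = sd_control/sd_case
  u3 <- toy_updater(2, 2, 3, 1.5)
  expect_equal(likelihood_ratio(u3, matrix(0), 2), 1.5 / 3)

  # log LR is antisymmetric under swapping case and control
  u4 <- toy_updater(1.2, -0.4, 1.1, 2.3, 0.6, -0.2)
  u4s <- toy_updater(-0.4, 1.2, 2.3, 1.1, -0.2, 0.6)
  grid_m <- seq(-4, 4, length.out = 7)
  for (x in c(-1, 0, 2)) {
    expect_equal(likelihood_ratio(u4, matrix(rep(x, 7)), grid_m, log = TRUE),
                 -likelihood_ratio(u4s, matrix(rep(x, 7)), grid_m, log = TRUE))
  }
  # strictly positive and finite even for extreme markers
  expect_true(all(is.finite(likelihood_ratio(u4, matrix(0), c(-500, 500)))))
})

test_that("update_prediction applies Bayes rule on the odds scale", {
  sch <- predictor_schema("x", "continuous")
  d <- new_dataset(sch, matrix(c(0, 0), ncol = 1, dimnames = list(NULL, "x")),
                   c(0, 1), marker = c(1, 1))

  # LR = 1 (identical models): posterior = prior
  u <- toy_updater(0, 0, 1, 1)
  expect_equal(update_prediction(u, d), plogis(linear_predictor(u$prior, d)))

  # prior odds 1, LR 2 -> posterior 2/3
  u2 <- toy_updater(1, 0, 1, 1)          # at m = 1: LR = exp(0.5)... use exact:
  # choose m so that LR = 2: log LR = (m - 0)^2/2 - (m - 1)^2/2 = m - 1/2
  m_star <- log(2) + 0.5
  d2 <- new_dataset(sch, matrix(0, dimnames = list(NULL, "x")), 1, marker = m_star)
  u2$prior <- logistic_model(0, 0, sch)  # prior odds exp(0) = 1
  expect_equal(update_prediction(u2, d2), 2 / 3)

  # posterior strictly increasing in LR at fixed prior
  ms <- seq(-3, 3, length.out = 21)
  dd <- new_dataset(sch, matrix(0, 21, 1, dimnames = list(NULL, "x")),
                    rep(1, 21), marker = ms)
  expect_true(all(diff(update_prediction(u2, dd)) > 0))
})

test_that("homoscedastic full CLR posterior matches the closed form to 1e-10", {
  sch <- default_schema()
  prior <- default_clr_config()$truth$prior
  sigma <- 4.2
  case <- conditional_marker_model(40, c(2, 1, -1, 0.5), sigma)
  control <- conditional_marker_model(34, c(1.5, 0.8, -0.7, 0.2), sigma)
  u <- structure(list(prior = prior, variant = "full", case_model = case,
                      control_model = control,
                      fit_meta = list(converged = TRUE)),
                 class = "predext_clr")
  X <- generate_covariates(default_clr_config(), 40, seed = 404)
  for (m in c(20, 35, 50, 80)) {
    d <- new_dataset(sch, X, rep(1, 40), marker = rep(m, 40))
    lp0 <- linear_predictor(prior, d)
    mu_case <- case$coef[1] + drop(X %*% case$coef[-1])
    mu_ctl <- control$coef[1] + drop(X %*% control$coef[-1])
    closed <- lp0 + ((m - mu_ctl)^2 - (m - mu_case)^2) / (2 * sigma^2)
    expect_equal(linear_predictor(u, d), closed, tolerance = 1e-10)
  }
})

test_that("fit_clr recovers generating per-group models (parameter recovery)", {
  cfg <- default_clr_config()
  d <- generate_from_clr_truth(cfg, 50000, seed = 405)
  prior <- cfg$truth$prior
  u <- fit_clr(prior, d)
  for (g in c("case", "control")) {
    idx <- d$y == (g == "case")
    o <- oracle_ols(d$X[idx, ], d$marker[idx])
    truth <- cfg$truth[[paste0(g, "_model")]]
    est <- u[[paste0(g, "_model")]]
    expect_true(all(abs(est$coef - truth$coef) < 3 * o$se), label = g)
    # residual-sd sampling SE ~ sd / sqrt(2 (n - q))
    sd_se <- truth$residual_sd / sqrt(2 * (sum(idx) - 5))
    expect_true(abs(est$residual_sd - truth$residual_sd) < 3 * sd_se, label = g)
    # and the OLS itself matches the lm oracle
    expect_equal(unname(est$coef), unname(o$coef), tolerance = 1e-8)
    expect_equal(est$residual_sd, o$residual_sd, tolerance = 1e-8)
  }
})

test_that("full and simple variants agree when the truth is a constant shift", {
  # equal slopes and equal residual SDs in both groups -> the simple model is
  # correctly specified and both variants estimate the same LR
  cfg <- default_clr_config()
  truth <- cfg$truth
  shift <- truth$case_model$coef[1] - truth$control_model$coef[1]
  hom <- population_config(truth = list(
    kind = "clr", prior = truth$prior,
    control_model = conditional_marker_model(30, truth$control_model$coef[-1], 16),
    case_model = conditional_marker_model(30 + shift, truth$control_model$coef[-1], 16)))
  u_true <- clr_truth_updater(hom)
  mads <- vapply(c(2000, 20000), function(n) {
    d <- generate_from_clr_truth(hom, n, seed = 406)
    eval_set <- generate_from_clr_truth(hom, 5000, seed = 4060)
    uf <- fit_clr(hom$truth$prior, d)
    us <- fit_clr_simple(hom$truth$prior, d)
    lrf <- likelihood_ratio(uf, eval_set$X, eval_set$marker, log = TRUE)
    lrs <- likelihood_ratio(us, eval_set$X, eval_set$marker, log = TRUE)
    lrt <- likelihood_ratio(u_true, eval_set$X, eval_set$marker, log = TRUE)
    c(fs = mean(abs(lrf - lrs)), ft = mean(abs(lrf - lrt)),
      st = mean(abs(lrs - lrt)), cor = cor(lrf, lrs))
  }, numeric(4))
  # both variants converge to the same true LR, so their mutual disagreement
  # and their errors all shrink as the marker set grows
  expect_true(all(mads[c("fs", "ft", "st"), 2] < mads[c("fs", "ft", "st"), 1]))
  expect_gt(mads["cor", 2], 0.99)

  # null marker: indicator coefficient 0 in truth -> LR ~ 1 for all rows
  null <- population_config(truth = list(
    kind = "clr", prior = truth$prior,
    control_model = conditional_marker_model(30, truth$control_model$coef[-1], 16),
    case_model = conditional_marker_model(30, truth$control_model$coef[-1], 16)))
  dn <- generate_from_clr_truth(null, 50000, seed = 407)
  un <- fit_clr_simple(null$truth$prior, dn)
  expect_lt(mean(abs(likelihood_ratio(un, dn$X, dn$marker, log = TRUE))), 0.02)
})

test_that("fit_clr guards degenerate inputs", {
  cfg <- default_clr_config()
  d <- generate_from_clr_truth(cfg, 200, seed = 408)
  # marker an exact linear function of predictors: zero residual variance
  d2 <- d; d2$marker <- 3 + 2 * d2$X[, "psa"]
  expect_error(fit_clr(cfg$truth$prior, d2), "zero residual variance")
  # a group too small to estimate p + 1 means plus an SD
  few <- c(which(d$y == 1)[1:3], which(d$y == 0))
  expect_error(fit_clr(cfg$truth$prior, dataset_rows(d, few)), "case")
  # prior with marker term is rejected
  expect_error(fit_clr(default_logistic_config()$truth$model, d), "marker term")
})

test_that("fitted full CLR posterior converges to the generator's truth", {
  cfg <- default_clr_config()
  u_true <- clr_truth_updater(cfg)
  err <- vapply(c(2000, 50000), function(n) {
    d <- generate_from_clr_truth(cfg, n, seed = 409)
    u <- fit_clr(cfg$truth$prior, d)
    test <- generate_from_clr_truth(cfg, 5000, seed = 410)
    mean(abs(update_prediction(u, test) - update_prediction(u_true, test)))
  }, numeric(1))
  expect_lt(err[2], err[1])      # shrinks with n
  expect_lt(err[2], 0.01)        # and is small at n = 50,000
})
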