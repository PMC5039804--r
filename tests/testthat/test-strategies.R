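test_that("heuristic shrinkage factor follows max(chi2 - df, 0)/chi2", {
  expect_equal(heuristic_shrinkage_factor(10, 4), 0.6)
  expect_equal(heuristic_shrinkage_factor(3, 4), 0)     # clamp
  expect_equal(heuristic_shrinkage_factor(4, 4), 0)     # boundary chi2 = df
  expect_equal(heuristic_shrinkage_factor(0, 4), 0)     # chi2 = 0
  expect_error(heuristic_shrinkage_factor(-1, 2), "chi2 < 0")
  # in [0, 1] and monotone non-decreasing in chi2 at fixed df
  chi2 <- seq(0, 50, by = 0.5)
  c_hat <- vapply(chi2, heuristic_shrinkage_factor, numeric(1), df = 5)
  expect_true(all(c_hat >= 0 & c_hat <= 1))
  expect_true(all(diff(c_hat) >= 0))
})

test_that("parameter_count reproduces the case-study accounting at p = 3, m = 1", {
  expect_identical(parameter_count("original", 3), 0L)
  expect_identical(parameter_count("revision", 3), 5L)
  expect_identical(parameter_count("revision_shrinkage", 3), 5L)
  expect_identical(parameter_count("recalibration_extension", 3), 3L)
  expect_identical(parameter_count("clr", 3), 10L)
  expect_identical(parameter_count("clr_simple", 3), 6L)
  expect_identical(parameter_count("imputation", 3), 5L)
  # general-m formulas
  expect_identical(parameter_count("clr", p = 4, m = 2), 2L * 2L * 5L + 2L * 3L)
  expect_identical(parameter_count("clr_simple", p = 4, m = 2), 2L * 6L + 3L)
  expect_error(parameter_count("stepwise", 3), "arg")
})

test_that("revision refits all coefficients plus the marker (parameter recovery)", {
  cfg <- default_logistic_config()
  big <- generate_from_logistic_truth(cfg, 50000, seed = 301)
  fit <- revise_with_extension(big)
  expect_true(fit$fit_meta$converged)
  o <- oracle_logistic(cbind(big$X, marker = big$marker), big$y)
  truth <- c(cfg$truth$model$alpha, cfg$truth$model$betas,
             cfg$truth$model$beta_marker)
  est <- c(fit$alpha, fit$betas, fit$beta_marker)
  expect_true(all(abs(est - truth) < 3 * o$se))
  # and the fit itself agrees with the oracle
  expect_equal(unname(est), unname(o$coef), tolerance = 1e-6)
})

test_that("recalibration is self-consistent and equivariant", {
  cfg <- default_logistic_config()
  # data generated from the prior itself: alpha ~ 0, slope ~ 1
  sch <- default_schema()
  prior <- cfg$truth$model
  prior_nm <- logistic_model(prior$alpha, prior$betas, sch)  # drop marker term
  set.seed(302)
  X <- generate_covariates(cfg, 50000)
  lp0 <- prior_nm$alpha + drop(X %*% prior_nm$betas)
  y <- generate_outcome(plogis(lp0))
  d <- new_dataset(sch, X, y)
  rec <- recalibrate(prior_nm, d)
  o <- oracle_logistic(matrix(lp0, dimnames = list(NULL, "lp")), y)
  expect_true(abs(rec$alpha_hat - 0) < 3 * o$se[1])
  expect_true(abs(rec$beta_overall - 1) < 3 * o$se[2])

  # doubling lp0 halves the overall slope (affine reparameterization)
  doubled <- logistic_model(2 * prior_nm$alpha, 2 * prior_nm$betas, sch)
  rec2 <- recalibrate(doubled, d)
  expect_equal(rec2$beta_overall, rec$beta_overall / 2, tolerance = 1e-6)
  # prediction depends on rows only through lp0
  expect_equal(linear_predictor(rec2, d), linear_predictor(rec, d),
               tolerance = 1e-6)

  # constant lp0 is a degenerate design
  flat <- logistic_model(0.3, rep(0, 4), sch)
  expect_error(recalibrate(flat, d), "constant|degenerate")
})

test_that("shrinkage blends revision toward recalibration", {
  cfg <- default_logistic_config()
  mk <- fix_marker_set(400, seed = 303)
  prior <- fit_logistic(drop_marker(fix_marker_set(500, seed = 304)))
  sh <- revise_with_shrinkage(prior, mk)

  expect_gte(sh$chi2, 0)                      # nesting: lp2 within lp1's span
  expect_identical(sh$df, 4L)                 # (p + 2) - 2 with p = 4 encoded
  expect_true(sh$c_hat >= 0 && sh$c_hat <= 1)
  expect_identical(revise_with_shrinkage(prior, mk, df = 3L)$df, 3L)  # override

  # lp3 = c lp1 + (1 - c) lp2, row-wise between the two
  test <- fix_marker_set(200, seed = 305)
  lp1 <- linear_predictor(sh$revised, test)
  lp2 <- linear_predictor(sh$recalibrated, test)
  lp3 <- linear_predictor(sh, test)
  expect_equal(lp3, sh$c_hat * lp1 + (1 - sh$c_hat) * lp2)
  expect_true(all(lp3 >= pmin(lp1, lp2) - 1e-12 & lp3 <= pmax(lp1, lp2) + 1e-12))
  # effective marker coefficient is c_hat * revised marker coefficient: the
  # derivative of lp3 in the marker
  expect_equal(sh$c_hat * sh$revised$beta_marker,
               (function(dm) {
                 t2 <- test; t2$marker <- t2$marker + dm
                 (linear_predictor(sh, t2) - lp3)[1] / dm
               })(1), tolerance = 1e-8)
})

test_that("c_hat reflects marker information content", {
  cfg <- default_logistic_config()
  prior <- fit_logistic(drop_marker(fix_marker_set(5000, seed = 306)))

  # pure-noise marker in tiny sets: c_hat mostly small
  set.seed(307)
  c_noise <- replicate(60, {
    mk <- fix_marker_set(100, seed = sample.int(1e6, 1))
    mk$marker <- rnorm(mk$n)        # decouple marker from outcome
    revise_with_shrinkage(prior, mk)$c_hat
  })
  expect_lt(median(c_noise), 0.5)

  # strongly informative marker, large set: c_hat near 1
  mk_big <- fix_marker_set(5000, seed = 308)
  expect_gt(revise_with_shrinkage(prior, mk_big)$c_hat, 0.9)
})

test_that("recalibration with extension estimates (lp0, marker) effects", {
  cfg <- default_logistic_config()
  sch <- default_schema()
  # truth additive in (lp0, marker): generate from prior lp + marker effect
  set.seed(309)
  X <- generate_covariates(cfg, 50000)
  mm <- cfg$truth$marker_model
  marker <- rnorm(nrow(X), mm$coef[1] + drop(X %*% mm$coef[-1]), mm$residual_sd)
  prior_nm <- logistic_model(-4.34, cfg$truth$model$betas, sch)
  lp0 <- linear_predictor(prior_nm, new_dataset(sch, X, rep(0, nrow(X))))
  lp_true <- lp0 + 0.03 * marker
  y <- generate_outcome(plogis(lp_true))
  d <- new_dataset(sch, X, y, marker = marker)

  fit <- recalibrate_with_extension(prior_nm, d)
  o <- oracle_logistic(cbind(lp0 = lp0, marker = marker), y)
  expect_true(abs(fit$beta_overall - 1) < 3 * o$se[2])
  expect_true(abs(fit$beta_marker - 0.03) < 3 * o$se[3])
  expect_equal(unname(c(fit$alpha_hat, fit$beta_overall, fit$beta_marker)),
               unname(o$coef), tolerance = 1e-6)

  # null marker: coefficient within 3 SEs of zero
  marker0 <- rnorm(nrow(X), 45, 17)
  y0 <- generate_outcome(plogis(lp0), seed = 310)
  d0 <- new_dataset(sch, X, y0, marker = marker0)
  fit0 <- recalibrate_with_extension(prior_nm, d0)
  o0 <- oracle_logistic(cbind(lp0 = lp0, marker = marker0), y0)
  expect_true(abs(fit0$beta_marker) < 3 * o0$se[3])
})
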