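# Replicated simulation comparing the updating strategies: per replicate,
# draw a development set (prior model fitted without the marker), a marker
# set, apply every strategy, and evaluate the c-statistic and calibration
# slope on a fresh independent test set.

#' Configure a simulation scenario
#'
#' @param n_dev Development-sample size.
#' @param n_marker Marker-sample size.
#' @param n_test Independent validation-sample size per replicate
#'   (default 100,000).
#' @param n_replicates Number of replicates (default 500).
#' @param population A [population_config()]; its `truth$kind` decides the
#'   generating model.
#' @param seed Root seed; per-replicate seeds are spawned from it (see
#'   Details).
#' @param strategies Character vector of strategy tags to run.
#'
#' @details Replicate seeding: the root seed initializes R's RNG once, from
#' which `n_replicates` 31-bit integers are drawn; replicate `r` then runs
#' under `set.seed(replicate_seeds[r])`.  Replicates are therefore mutually
#' independent and individually reproducible.
#'
#' @return An object of class `predext_scenario_config`.
#' @export
scenario_config <- function(n_dev, n_marker, n_test = 100000L,
                            n_replicates = 500L,
                            population = default_logistic_config(),
                            seed = 1L,
                            strategies = c("original", "revision",
                                           "revision_shrinkage", "recalibration",
                                           "recalibration_extension", "clr",
                                           "clr_simple", "imputation")) {
  stopifnot(n_dev >= 1, n_marker >= 1, n_test >= 1, n_replicates >= 1,
            inherits(population, "predext_population"))
  strategies <- match.arg(strategies, STRATEGY_TAGS, several.ok = TRUE)
  structure(
    list(n_dev = as.integer(n_dev), n_marker = as.integer(n_marker),
         n_test = as.integer(n_test), n_replicates = as.integer(n_replicates),
         population = population, seed = as.integer(seed),
         strategies = strategies),
    class = "predext_scenario_config"
  )
}

# Fit one strategy; returns NULL on a fitting error (counted as unconverged).
fit_strategy <- function(tag, prior, marker_set, dev_set) {
  tryCatch(
    switch(tag,
      original                = prior,
      revision                = revise_with_extension(marker_set),
      revision_shrinkage      = revise_with_shrinkage(prior, marker_set),
      recalibration           = recalibrate(prior, marker_set),
      recalibration_extension = recalibrate_with_extension(prior, marker_set),
      clr                     = fit_clr(prior, marker_set),
      clr_simple              = fit_clr_simple(prior, marker_set),
      imputation              = fit_pooled(impute_marker(drop_marker(dev_set), marker_set))
    ),
    error = function(e) NULL
  )
}

#' Run a simulation scenario
#'
#' For each replicate: draw a development set and fit the prior (no-marker)
#' model on it; draw a marker set; apply each configured strategy (the
#' imputation strategy stacks the development and marker sets); draw a fresh
#' test set and evaluate each strategy's c-statistic and calibration slope on
#' it.  Strategy fits that fail or do not converge are recorded and excluded
#' from summaries rather than aborting the replicate.
#'
#' @param config A [scenario_config()].
#' @return An object of class `predext_scenario_result`: `results` (long
#'   data.frame: replicate, strategy, c_statistic, calibration_slope,
#'   converged), `config`, and `replicate_seeds`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "predext_scenario_config"))
  set.seed(config$seed)
  replicate_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  pop <- config$population
  rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(replicate_seeds[r])
    dev_set <- drop_marker(generate_dataset(pop, config$n_dev))
    marker_set <- generate_dataset(pop, config$n_marker)
    test_set <- generate_dataset(pop, config$n_test)
    prior <- tryCatch(fit_logistic(dev_set), error = function(e) NULL)
    res <- lapply(config$strategies, function(tag) {
      model <- if (is.null(prior)) NULL else {
        fit_strategy(tag, prior, marker_set, dev_set)
      }
      ok <- !is.null(model) && strategy_converged(model)
      if (ok) {
        perf <- tryCatch(evaluate_performance(model, test_set),
                         error = function(e) NULL)
        if (is.null(perf)) ok <- FALSE
      }
      if (!ok) {
        data.frame(replicate = r, strategy = tag, c_statistic = NA_real_,
                   calibration_slope = NA_real_, converged = FALSE)
      } else {
        data.frame(replicate = r, strategy = tag,
                   c_statistic = perf$c_statistic,
                   calibration_slope = perf$calibration_slope,
                   converged = isTRUE(perf$slope_converged))
      }
    })
    rows[[r]] <- do.call(rbind, res)
  }
  structure(
    list(results = do.call(rbind, rows), config = config,
         replicate_seeds = replicate_seeds),
    class = "predext_scenario_result"
  )
}

#' Summarize a scenario result
#'
#' Long-format summary table with one row per strategy and metric: median and
#' quartiles over converged replicates plus the number converged — the
#' numbers a box plot of the scenario would display.
#'
#' @param result A `predext_scenario_result`.
#' @return data.frame with columns `n_dev`, `n_marker`, `truth`, `strategy`,
#'   `metric`, `median`, `q25`, `q75`, `n_converged`.
#' @export
summarize_scenario <- function(result) {
  stopifnot(inherits(result, "predext_scenario_result"))
  df <- result$results
  cfg <- result$config
  out <- list()
  for (tag in cfg$strategies) {
    sub <- df[df$strategy == tag & df$converged, , drop = FALSE]
    for (metric in c("c_statistic", "calibration_slope")) {
      v <- sub[[metric]]
      v <- v[is.finite(v)]
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
           else rep(NA_real_, 3)
      out[[length(out) + 1L]] <- data.frame(
        n_dev = cfg$n_dev, n_marker = cfg$n_marker,
        truth = cfg$population$truth$kind, strategy = tag, metric = metric,
        median = q[2], q25 = q[1], q75 = q[3], n_converged = length(v))
    }
  }
  do.call(rbind, out)
}

#' @export
print.predext_scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario: n_dev = %d, n_marker = %d, n_test = %d, %d replicates, %s truth\n",
              cfg$n_dev, cfg$n_marker, cfg$n_test, cfg$n_replicates,
              cfg$population$truth$kind))
  print(summarize_scenario(x), digits = 3)
  invisible(x)
}
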