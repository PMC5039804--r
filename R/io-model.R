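# Human-readable structured-text (JSON) serialization of fitted models.
# Every file carries format_version and a strategy tag; numeric fields are
# written at full precision so round-trips are lossless.

MODEL_FORMAT_VERSION <- "1.0"

schema_to_list <- function(schema) {
  if (is.null(schema)) return(NULL)
  list(names = schema$names, kinds = schema$kinds, levels = schema$levels)
}

schema_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  predictor_schema(unlist(x$names), unlist(x$kinds),
                   lapply(x$levels, unlist))
}

fit_meta_to_list <- function(fm) fm

model_strategy_tag <- function(model) {
  if (inherits(model, "predext_logistic")) {
    if (is.null(model$beta_marker)) "original" else "revision"
  } else if (inherits(model, "predext_recalibrated")) "recalibration"
  else if (inherits(model, "predext_shrunken")) "revision_shrinkage"
  else if (inherits(model, "predext_recal_extended")) "recalibration_extension"
  else if (inherits(model, "predext_clr")) {
    if (model$variant == "full") "clr" else "clr_simple"
  }
  else if (inherits(model, "predext_pooled")) "imputation"
  else stop("unsupported model type: ", paste(class(model), collapse = "/"))
}

model_to_list <- function(model) {
  tag <- model_strategy_tag(model)
  base <- list(format_version = MODEL_FORMAT_VERSION, strategy = tag)
  body <- switch(tag,
    original = ,
    revision = list(
      coefficients = list(alpha = model$alpha, betas = as.list(model$betas),
                          beta_marker = model$beta_marker),
      schema = schema_to_list(model$schema),
      fit_meta = model$fit_meta),
    recalibration = list(
      coefficients = list(alpha_hat = model$alpha_hat,
                          beta_overall = model$beta_overall),
      prior = model_to_list(model$prior),
      fit_meta = model$fit_meta),
    recalibration_extension = list(
      coefficients = list(alpha_hat = model$alpha_hat,
                          beta_overall = model$beta_overall,
                          beta_marker = model$beta_marker),
      prior = model_to_list(model$prior),
      fit_meta = model$fit_meta),
    revision_shrinkage = list(
      shrinkage = list(chi2 = model$chi2, df = model$df, c_hat = model$c_hat),
      revised = model_to_list(model$revised),
      recalibrated = model_to_list(model$recalibrated),
      fit_meta = model$fit_meta),
    clr = ,
    clr_simple = list(
      variant = model$variant,
      prior = model_to_list(model$prior),
      case_model = list(coef = as.list(model$case_model$coef),
                        residual_sd = model$case_model$residual_sd),
      control_model = list(coef = as.list(model$control_model$coef),
                           residual_sd = model$control_model$residual_sd),
      shared_fit = if (!is.null(model$shared_fit)) {
        list(coef = as.list(model$shared_fit$coef),
             residual_sd = model$shared_fit$residual_sd)
      },
      fit_meta = model$fit_meta),
    imputation = list(
      J = model$J,
      per_imputation = lapply(model$per_imputation, as.list),
      pooled = as.list(model$pooled),
      schema = schema_to_list(model$schema),
      fit_meta = model$fit_meta)
  )
  c(base, body)
}

#' Write a fitted model to a structured-text file
#'
#' Serializes any of the package's fitted model objects (logistic models,
#' recalibrated / shrunken / extended-recalibrated strategies,
#' conditional-likelihood-ratio updaters, pooled imputation models) to JSON
#' with a format-version field.  Round-trips through [read_model()] are
#' lossless for all coefficients, schema, and strategy metadata.
#'
#' @param model A fitted model object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  # I(17) = 17 *significant* digits: lossless decimal round-trip for doubles
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

named_vec <- function(x) {
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

model_from_list <- function(x) {
  if (is.null(x$format_version)) stop("not a model file: no format_version field")
  if (!identical(x$format_version, MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model format version '%s' (supported: %s)",
                 x$format_version, MODEL_FORMAT_VERSION))
  }
  tag <- x$strategy
  fm <- x$fit_meta
  switch(tag,
    original = ,
    revision = structure(
      list(alpha = x$coefficients$alpha,
           betas = named_vec(x$coefficients$betas),
           beta_marker = x$coefficients$beta_marker,
           schema = schema_from_list(x$schema), fit_meta = fm),
      class = "predext_logistic"),
    recalibration = structure(
      list(alpha_hat = x$coefficients$alpha_hat,
           beta_overall = x$coefficients$beta_overall,
           prior = model_from_list(x$prior), fit_meta = fm),
      class = "predext_recalibrated"),
    recalibration_extension = structure(
      list(alpha_hat = x$coefficients$alpha_hat,
           beta_overall = x$coefficients$beta_overall,
           beta_marker = x$coefficients$beta_marker,
           prior = model_from_list(x$prior), fit_meta = fm),
      class = "predext_recal_extended"),
    revision_shrinkage = structure(
      list(revised = model_from_list(x$revised),
           recalibrated = model_from_list(x$recalibrated),
           chi2 = x$shrinkage$chi2, df = as.integer(x$shrinkage$df),
           c_hat = x$shrinkage$c_hat, fit_meta = fm),
      class = "predext_shrunken"),
    clr = ,
    clr_simple = structure(
      list(prior = model_from_list(x$prior), variant = x$variant,
           case_model = list(coef = named_vec(x$case_model$coef),
                             residual_sd = x$case_model$residual_sd),
           control_model = list(coef = named_vec(x$control_model$coef),
                                residual_sd = x$control_model$residual_sd),
           shared_fit = if (!is.null(x$shared_fit)) {
             list(coef = named_vec(x$shared_fit$coef),
                  residual_sd = x$shared_fit$residual_sd)
           },
           fit_meta = fm),
      class = "predext_clr"),
    imputation = structure(
      list(per_imputation = lapply(x$per_imputation, named_vec),
           pooled = named_vec(x$pooled), J = as.integer(x$J),
           schema = schema_from_list(x$schema), fit_meta = fm),
      class = "predext_pooled"),
    stop(sprintf("unknown strategy tag '%s' in model file", tag))
  )
}

#' Read a fitted model from a structured-text file
#'
#' @param path Path to a file written by [write_model()].
#' @return The reconstructed model object, of the class matching the file's
#'   strategy tag.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  model_from_list(x)
}
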