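#' Define a predictor schema
#'
#' A predictor schema fixes the order, type and (for categorical predictors)
#' the level set of the clinical predictors entering a risk model.  Categorical
#' predictors are dummy-coded against their first level (reference-cell
#' coding), so the encoded design width is
#' `p = n_continuous + sum(n_levels - 1)`.
#'
#' @param names Character vector of unique, non-empty predictor names, in
#'   model order.
#' @param kinds Character vector, one of `"continuous"` or `"categorical"` per
#'   predictor.
#' @param levels Named list mapping each categorical predictor to its ordered
#'   level labels; the first label is the reference level.
#'
#' @return An object of class `predext_schema` with elements `names`, `kinds`,
#'   `levels`, and `p` (the encoded design width).
#' @examples
#' sch <- predictor_schema(
#'   names  = c("psa", "volume", "dre"),
#'   kinds  = c("continuous", "categorical", "continuous"),
#'   levels = list(volume = c("vol25", "vol40", "vol60"))
#' )
#' sch$p  # 1 + 2 + 1 = 4
#' @export
predictor_schema <- function(names, kinds, levels = list()) {
  if (length(names) == 0L || anyDuplicated(names) || any(!nzchar(names))) {
    stop("schema error: predictor names must be unique and non-empty")
  }
  kinds <- match.arg(kinds, c("continuous", "categorical"), several.ok = TRUE)
  if (length(kinds) != length(names)) {
    stop("schema error: 'kinds' must have one entry per predictor")
  }
  cat_names <- names[kinds == "categorical"]
  if (!setequal(names(levels), cat_names)) {
    stop("schema error: 'levels' must name exactly the categorical predictors")
  }
  for (nm in cat_names) {
    lv <- levels[[nm]]
    if (length(lv) < 2L || anyDuplicated(lv)) {
      stop(sprintf("schema error: categorical predictor '%s' needs >= 2 distinct levels", nm))
    }
  }
  p <- sum(kinds == "continuous") +
    sum(vapply(levels, function(lv) length(lv) - 1L, integer(1)))
  structure(
    list(names = names, kinds = kinds, levels = levels, p = as.integer(p)),
    class = "predext_schema"
  )
}

#' @export
print.predext_schema <- function(x, ...) {
  cat("Predictor schema (encoded width p =", x$p, ")\n")
  for (i in seq_along(x$names)) {
    nm <- x$names[i]
    if (x$kinds[i] == "categorical") {
      cat(sprintf("  %s: categorical [%s] (ref = %s)\n", nm,
                  paste(x$levels[[nm]], collapse = ", "), x$levels[[nm]][1]))
    } else {
      cat(sprintf("  %s: continuous\n", nm))
    }
  }
  invisible(x)
}

# Column names of the encoded design: continuous predictors keep their name,
# categorical predictors expand to <name><level> for each non-reference level.
encoded_column_names <- function(schema) {
  out <- character(0)
  for (i in seq_along(schema$names)) {
    nm <- schema$names[i]
    if (schema$kinds[i] == "categorical") {
      lv <- schema$levels[[nm]]
      out <- c(out, paste0(nm, lv[-1]))
    } else {
      out <- c(out, nm)
    }
  }
  out
}

# Encode a data.frame of raw predictor columns (schema order / schema names)
# into the numeric design matrix.  Categorical columns must hold level labels.
encode_predictors <- function(schema, df) {
  n <- nrow(df)
  cols <- vector("list", 0L)
  for (i in seq_along(schema$names)) {
    nm <- schema$names[i]
    v <- df[[nm]]
    if (is.null(v)) stop(sprintf("schema error: missing predictor column '%s'", nm))
    if (schema$kinds[i] == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric value '%s' for continuous predictor '%s' at row %d",
                     as.character(v[bad[1]]), nm, bad[1]))
      }
      if (anyNA(num)) {
        stop(sprintf("missing value for predictor '%s' at row %d (predictor missingness is not supported)",
                     nm, which(is.na(num))[1]))
      }
      cols[[nm]] <- num
    } else {
      lv <- schema$levels[[nm]]
      v <- as.character(v)
      if (anyNA(v)) {
        stop(sprintf("missing value for predictor '%s' at row %d (predictor missingness is not supported)",
                     nm, which(is.na(v))[1]))
      }
      bad <- which(!(v %in% lv))
      if (length(bad)) {
        stop(sprintf("schema error: unknown level '%s' for categorical predictor '%s' at row %d",
                     v[bad[1]], nm, bad[1]))
      }
      for (l in lv[-1]) cols[[paste0(nm, l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Construct a dataset container
#'
#' Bundles an encoded predictor design matrix, an optional continuous marker
#' (with an explicit per-row observation mask), and a binary outcome.
#'
#' @param schema A [predictor_schema()].
#' @param X Numeric matrix, `n` rows by `schema$p` encoded columns, no missing
#'   values.
#' @param y Binary outcome vector (0/1), length `n`; 1 codes the event.
#' @param marker Numeric marker vector of length `n`, or `NULL` if the marker
#'   was never measured in this set.  Entries may be `NA` only where
#'   `marker_observed` is `FALSE`.
#' @param marker_observed Logical length-`n` mask; defaults to `!is.na(marker)`.
#'   A marker observed nowhere degenerates to `marker = NULL`.
#'
#' @return An object of class `predext_dataset` with elements `schema`, `X`,
#'   `marker`, `marker_observed`, `y`, `n`.
#' @export
new_dataset <- function(schema, X, y, marker = NULL, marker_observed = NULL) {
  stopifnot(inherits(schema, "predext_schema"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 1L) stop("dataset must contain at least one row")
  if (ncol(X) != schema$p) {
    stop(sprintf("design width %d does not match schema width p = %d", ncol(X), schema$p))
  }
  if (anyNA(X)) stop("X must not contain missing values")
  if (is.null(colnames(X))) colnames(X) <- encoded_column_names(schema)
  y <- as.numeric(y)
  if (length(y) != n || !all(y %in% c(0, 1))) {
    stop("y must be a 0/1 vector with one entry per row")
  }
  if (!is.null(marker)) {
    marker <- as.numeric(marker)
    if (length(marker) != n) stop("marker must have one entry per row")
    if (is.null(marker_observed)) marker_observed <- !is.na(marker)
    marker_observed <- as.logical(marker_observed)
    if (length(marker_observed) != n) stop("marker_observed must have one entry per row")
    if (anyNA(marker[marker_observed])) {
      stop("marker is NA on a row flagged as observed")
    }
    if (!any(marker_observed)) {
      marker <- NULL
      marker_observed <- NULL
    }
  } else {
    marker_observed <- NULL
  }
  structure(
    list(schema = schema, X = X, marker = marker,
         marker_observed = marker_observed, y = y, n = as.integer(n)),
    class = "predext_dataset"
  )
}

#' @export
print.predext_dataset <- function(x, ...) {
  cat(sprintf("predext dataset: n = %d, p = %d encoded predictors, %d events (%.1f%%)\n",
              x$n, x$schema$p, sum(x$y), 100 * mean(x$y)))
  if (is.null(x$marker)) {
    cat("  marker: absent\n")
  } else {
    cat(sprintf("  marker: observed on %d/%d rows\n", sum(x$marker_observed), x$n))
  }
  invisible(x)
}

# TRUE when the marker is observed on every row
marker_complete <- function(data) {
  !is.null(data$marker) && all(data$marker_observed)
}

# Subset rows of a dataset
dataset_rows <- function(data, idx) {
  new_dataset(data$schema, data$X[idx, , drop = FALSE], data$y[idx],
              marker = if (!is.null(data$marker)) data$marker[idx],
              marker_observed = if (!is.null(data$marker)) data$marker_observed[idx])
}

# Stack two datasets that share a schema (used by the imputation strategy)
dataset_stack <- function(a, b) {
  if (!identical(unclass(a$schema), unclass(b$schema))) {
    stop("cannot stack datasets with different schemas")
  }
  to_m <- function(d) if (is.null(d$marker)) rep(NA_real_, d$n) else d$marker
  to_o <- function(d) if (is.null(d$marker)) rep(FALSE, d$n) else d$marker_observed
  new_dataset(a$schema, rbind(a$X, b$X), c(a$y, b$y),
              marker = c(to_m(a), to_m(b)),
              marker_observed = c(to_o(a), to_o(b)))
}
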