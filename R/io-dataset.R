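#' Read a patient dataset from CSV
#'
#' Reads a header-bearing CSV, maps its columns onto a predictor schema,
#' dummy-encodes categorical predictors against their reference level, and
#' returns a [new_dataset()].  The event level of the outcome must be declared
#' explicitly in `column_map`; it is never inferred from labels.
#'
#' Rows with missing predictor or outcome values are an error (predictor
#' missingness is out of scope).  Missing marker values are allowed and are
#' recorded in the per-row observation mask; a marker column that is missing
#' everywhere degenerates to an absent marker.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [predictor_schema()].
#' @param column_map A list with elements:
#'   \describe{
#'     \item{predictors}{named character vector mapping schema names to CSV
#'       column names; defaults to identity.}
#'     \item{outcome}{CSV column holding the binary outcome (required).}
#'     \item{event}{value of the outcome column coding an event (required).}
#'     \item{nonevent}{optional; when omitted, the single remaining distinct
#'       value is taken as the non-event code.}
#'     \item{marker}{optional CSV column holding the marker.}
#'   }
#' @return A `predext_dataset`.
#' @export
read_dataset <- function(path, schema, column_map) {
  stopifnot(inherits(schema, "predext_schema"))
  if (is.null(column_map$outcome) || is.null(column_map$event)) {
    stop("column_map must declare 'outcome' and 'event' explicitly")
  }
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  pmap <- column_map$predictors
  if (is.null(pmap)) pmap <- stats::setNames(schema$names, schema$names)
  needed <- c(unname(pmap), column_map$outcome, column_map$marker)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop(sprintf("schema error: column '%s' not found in %s", absent[1], path))
  }

  # blank cells read as "" -> treat as missing
  df[df == ""] <- NA

  raw <- df[, unname(pmap), drop = FALSE]
  names(raw) <- names(pmap)
  X <- encode_predictors(schema, raw)

  yraw <- df[[column_map$outcome]]
  if (anyNA(yraw)) {
    stop(sprintf("missing outcome value at row %d", which(is.na(yraw))[1]))
  }
  event <- as.character(column_map$event)
  nonevent <- column_map$nonevent
  vals <- unique(as.character(yraw))
  if (!is.null(nonevent)) {
    bad <- setdiff(vals, c(event, as.character(nonevent)))
    if (length(bad)) {
      stop(sprintf("outcome column contains undeclared value '%s'", bad[1]))
    }
  } else {
    others <- setdiff(vals, event)
    if (length(others) > 1L) {
      stop(sprintf("outcome column has %d distinct non-event values (%s); declare 'nonevent'",
                   length(others), paste(others, collapse = ", ")))
    }
  }
  y <- as.numeric(yraw == event)

  marker <- NULL
  if (!is.null(column_map$marker)) {
    mraw <- df[[column_map$marker]]
    marker <- suppressWarnings(as.numeric(mraw))
    bad <- which(is.na(marker) & !is.na(mraw))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric marker value '%s' at row %d",
                   mraw[bad[1]], bad[1]))
    }
    if (all(is.na(marker))) marker <- NULL
  }
  new_dataset(schema, X, y, marker = marker)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: decodes dummy-coded categorical predictors back
#' to their level labels and writes one column per clinical predictor plus
#' `marker` (if present, `NA` where unobserved) and `outcome` (0/1).
#'
#' @param data A `predext_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "predext_dataset"))
  sch <- data$schema
  out <- list()
  j <- 1L
  for (i in seq_along(sch$names)) {
    nm <- sch$names[i]
    if (sch$kinds[i] == "categorical") {
      lv <- sch$levels[[nm]]
      k <- length(lv) - 1L
      dm <- data$X[, j:(j + k - 1L), drop = FALSE]
      lab <- rep(lv[1], data$n)
      for (l in seq_len(k)) lab[dm[, l] == 1] <- lv[l + 1L]
      out[[nm]] <- lab
      j <- j + k
    } else {
      out[[nm]] <- data$X[, j]
      j <- j + 1L
    }
  }
  if (!is.null(data$marker)) {
    m <- data$marker
    m[!data$marker_observed] <- NA
    out$marker <- m
  }
  out$outcome <- data$y
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
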