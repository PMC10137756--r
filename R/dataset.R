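#' Build a survival dataset from a patient-level data frame
#'
#' Validates a tabular cohort against a [feature_schema()] and packs it into
#' the internal representation used by the models: a continuous covariate
#' matrix, an integer code matrix for categorical covariates (codes
#' `0 .. c_i - 1` in the schema's level order), durations in days and event
#' indicators. Missing values are rejected, never imputed.
#'
#' @param df Data frame with one row per patient, containing every
#'   schema-declared column. An `id` column is used as patient identifier if
#'   present, otherwise row numbers are used.
#' @param schema A [feature_schema()].
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(df, schema) {
  df <- as_tibble(df)
  need <- c(schema$features$name, schema$duration, schema$event)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("columns missing from data: ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(df)
  if (n == 0L) abort("dataset has no rows")
  ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(n))

  for (col in need) {
    if (anyNA(df[[col]])) {
      abort(paste0("missing values in column '", col, "' (rows ",
                   paste(utils::head(which(is.na(df[[col]])), 5), collapse = ","),
                   "); imputation is not performed"))
    }
  }

  t <- as.numeric(df[[schema$duration]])
  if (anyNA(t)) abort(paste0("non-numeric duration in column '", schema$duration, "'"))
  if (any(t <= 0)) {
    abort(paste0("non-positive duration at rows ",
                 paste(utils::head(which(t <= 0), 5), collapse = ",")))
  }
  d <- df[[schema$event]]
  dn <- suppressWarnings(as.numeric(d))
  if (anyNA(dn) || !all(dn %in% c(0, 1))) {
    abort(paste0("event indicator must be 0 or 1 in column '", schema$event, "'"))
  }
  d <- as.integer(dn)

  cont <- schema_cont(schema)
  x_cont <- matrix(0, n, nrow(cont), dimnames = list(NULL, cont$name))
  for (nm in cont$name) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) abort(paste0("non-numeric value in continuous column '", nm, "'"))
    x_cont[, nm] <- v
  }

  cat <- schema_cat(schema)
  x_cat <- matrix(0L, n, nrow(cat), dimnames = list(NULL, cat$name))
  for (i in seq_len(nrow(cat))) {
    nm <- cat$name[i]
    lv <- cat$levels[[i]]
    lab <- as.character(df[[nm]])
    code <- match(lab, lv)
    if (anyNA(code)) {
      bad <- which(is.na(code))[1]
      abort(paste0("unknown level '", lab[bad], "' for feature '", nm,
                   "' at row ", bad, " (known: ", paste(lv, collapse = ", "), ")"))
    }
    x_cat[, i] <- code - 1L
  }

  structure(
    list(n = n, x_cont = x_cont, x_cat = x_cat, t = t, d = d, ids = ids,
         schema = schema),
    class = "survival_dataset"
  )
}

#' Load a survival dataset from delimited text
#'
#' Reads a comma-separated file with a header row and interprets it against
#' the schema via [survival_dataset()]. Unknown category labels, missing
#' values, non-positive durations and out-of-range event indicators are
#' errors.
#'
#' @param path Path to a CSV file.
#' @param schema A [feature_schema()].
#' @param true_risk If `TRUE` and the file carries a `.true_risk` column
#'   (written by the cohort simulator for oracle evaluation), attach it;
#'   otherwise the column is ignored.
#' @return A `survival_dataset`.
#' @export
load_dataset <- function(path, schema, true_risk = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ds <- survival_dataset(df, schema)
  if (true_risk) {
    if (!".true_risk" %in% names(df)) abort("no .true_risk column in file")
    ds$true_risk <- as.numeric(df$.true_risk)
  }
  ds
}

#' Write a survival dataset as delimited text
#'
#' Inverse of [load_dataset()]: categorical codes are written back as their
#' level labels, so a load/write/load round trip is the identity.
#'
#' @param data A `survival_dataset`.
#' @param path Output CSV path.
#' @param true_risk Include the simulator's `.true_risk` column if present.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, true_risk = !is.null(data$true_risk)) {
  df <- as_tibble(data)
  if (true_risk && !is.null(data$true_risk)) df$.true_risk <- data$true_risk
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as_tibble.survival_dataset <- function(x, ...) {
  out <- tibble(id = x$ids)
  for (nm in colnames(x$x_cont)) out[[nm]] <- x$x_cont[, nm]
  cat <- schema_cat(x$schema)
  for (i in seq_len(nrow(cat))) {
    out[[cat$name[i]]] <- cat$levels[[i]][x$x_cat[, i] + 1L]
  }
  out[[x$schema$duration]] <- x$t
  out[[x$schema$event]] <- x$d
  out
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> n=", x$n, ", ", ncol(x$x_cont), " continuous + ",
      ncol(x$x_cat), " categorical features, ",
      sum(x$d), " events (", sprintf("%.1f", 100 * mean(x$d == 0)),
      "% censored)\n", sep = "")
  invisible(x)
}

#' Subset a survival dataset by row indices
#' @param data A `survival_dataset`.
#' @param idx Integer row indices.
#' @return A `survival_dataset` with the selected patients, in `idx` order.
#' @export
dataset_subset <- function(data, idx) {
  out <- data
  out$n <- length(idx)
  out$x_cont <- data$x_cont[idx, , drop = FALSE]
  out$x_cat <- data$x_cat[idx, , drop = FALSE]
  out$t <- data$t[idx]
  out$d <- data$d[idx]
  out$ids <- data$ids[idx]
  if (!is.null(data$true_risk)) out$true_risk <- data$true_risk[idx]
  out
}

#' Restrict a dataset to the features of a treatment stage
#'
#' @param data A `survival_dataset`.
#' @param stage `"pretreatment"` or `"on-treatment"`.
#' @return A `survival_dataset` under the stage-restricted schema.
#' @export
dataset_for_stage <- function(data, stage = c("on-treatment", "pretreatment")) {
  stage <- match.arg(stage)
  sch <- schema_for_stage(data$schema, stage)
  out <- data
  out$schema <- sch
  out$x_cont <- data$x_cont[, schema_cont(sch)$name, drop = FALSE]
  out$x_cat <- data$x_cat[, schema_cat(sch)$name, drop = FALSE]
  out
}
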