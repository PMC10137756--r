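#' Fit a standardizing preprocessor on training data
#'
#' Computes, per continuous feature, the training-set mean and the
#' uncorrected (population) standard deviation. Categorical codes are left
#' untouched by the preprocessor; their level-to-code mapping lives in the
#' schema. Fitting on anything but the training split leaks information, so
#' cross-validation refits the preprocessor inside every fold.
#'
#' @param train A `survival_dataset` with at least two rows.
#' @param schema Schema the preprocessor is bound to; defaults to the
#'   training set's own schema.
#' @return An object of class `preprocessor`.
#' @export
fit_preprocessor <- function(train, schema = train$schema) {
  if (train$n < 2) abort("need at least 2 training rows to fit a preprocessor")
  x <- train$x_cont
  loc <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, loc)^2))
  if (any(scl <= 0)) {
    abort(paste0("constant continuous feature(s) on training data: ",
                 paste(colnames(x)[scl <= 0], collapse = ", ")))
  }
  structure(
    list(location = loc, scale = scl, feature_names = colnames(x),
         schema_features = schema$features$name),
    class = "preprocessor"
  )
}

#' Apply a fitted preprocessor
#'
#' Replaces each continuous column by `(x - location) / scale`. Categorical
#' codes, durations and event indicators pass through unchanged.
#'
#' @param pre A [fit_preprocessor()] result.
#' @param data A `survival_dataset` under the same schema.
#' @return A transformed `survival_dataset`.
#' @export
apply_preprocessor <- function(pre, data) {
  if (!identical(pre$feature_names, colnames(data$x_cont)) ||
      !identical(pre$schema_features, data$schema$features$name)) {
    abort("preprocessor was fitted under a different schema")
  }
  out <- data
  out$x_cont <- sweep(sweep(data$x_cont, 2, pre$location), 2, pre$scale, "/")
  out
}
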