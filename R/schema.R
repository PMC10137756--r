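#' Declare the covariate schema of a survival cohort
#'
#' A feature schema names every covariate, its role (continuous or
#' categorical), the ordered level labels of the categorical ones, and the
#' treatment stage at which each covariate becomes available
#' (`"pretreatment"` or `"on-treatment"`). The schema is authoritative: data
#' files are interpreted against it, never type-inferred.
#'
#' Ordinal clinical scores (ECOG, Ann Arbor stage, IPI, Deauville) are stored
#' with their levels in severity order, so the integer codes preserve the
#' ordering even though the model treats the features as categorical.
#'
#' @param features A data frame (or tibble) with columns `name`, `role`
#'   (`"continuous"`/`"categorical"`), `levels` (list-column of character
#'   vectors; `NULL` for continuous features) and `stage`
#'   (`"pretreatment"`/`"on-treatment"`).
#' @param duration Name of the column holding observed time in days.
#' @param event Name of the column holding the event indicator (1 = event,
#'   0 = censored).
#' @return An object of class `feature_schema`.
#' @examples
#' sch <- feature_schema(
#'   tibble::tibble(
#'     name = c("age", "stage"),
#'     role = c("continuous", "categorical"),
#'     levels = list(NULL, c("I", "II", "III", "IV")),
#'     stage = "pretreatment"
#'   ),
#'   duration = "time_days", event = "event"
#' )
#' @export
feature_schema <- function(features, duration, event) {
  features <- as_tibble(features)
  req <- c("name", "role", "levels", "stage")
  if (!all(req %in% names(features))) {
    abort(paste0("`features` must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(features$name)) abort("duplicate feature names in schema")
  if (!all(features$role %in% c("continuous", "categorical"))) {
    abort("feature roles must be 'continuous' or 'categorical'")
  }
  if (!all(features$stage %in% c("pretreatment", "on-treatment"))) {
    abort("feature stages must be 'pretreatment' or 'on-treatment'")
  }
  for (i in seq_len(nrow(features))) {
    lv <- features$levels[[i]]
    if (features$role[i] == "categorical") {
      if (is.null(lv) || length(lv) == 0) {
        abort(paste0("categorical feature '", features$name[i], "' has no levels"))
      }
      if (anyDuplicated(lv)) {
        abort(paste0("duplicate levels for feature '", features$name[i], "'"))
      }
    } else if (!is.null(lv)) {
      abort(paste0("continuous feature '", features$name[i], "' must not declare levels"))
    }
  }
  if (!sum(features$role == "categorical")) {
    abort("schema needs at least one categorical feature (the categorical branch must have input)")
  }
  if (length(duration) != 1L || length(event) != 1L) {
    abort("exactly one duration column and one event column are required")
  }
  if (duration == event || duration %in% features$name || event %in% features$name) {
    abort("duration/event columns must be distinct from each other and from features")
  }
  structure(
    list(features = features, duration = duration, event = event),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", nrow(x$features), " features; duration='",
      x$duration, "', event='", x$event, "'\n", sep = "")
  f <- x$features
  for (i in seq_len(nrow(f))) {
    cat(sprintf(
      "  %-12s %-11s %-13s %s\n", f$name[i], f$role[i], f$stage[i],
      if (f$role[i] == "categorical") paste(f$levels[[i]], collapse = "|") else ""
    ))
  }
  invisible(x)
}

schema_cat <- function(schema) {
  dplyr::filter(schema$features, .data$role == "categorical")
}

schema_cont <- function(schema) {
  dplyr::filter(schema$features, .data$role == "continuous")
}

#' Number of levels of each categorical feature, in schema order
#' @param schema A [feature_schema()].
#' @return Named integer vector.
#' @export
schema_cardinalities <- function(schema) {
  cat <- schema_cat(schema)
  setNames(vapply(cat$levels, length, integer(1)), cat$name)
}

#' Restrict a schema to a treatment stage
#'
#' `"pretreatment"` keeps pretreatment features only; `"on-treatment"` keeps
#' all features (on-treatment availability includes everything known before
#' treatment).
#'
#' @param schema A [feature_schema()].
#' @param stage `"pretreatment"` or `"on-treatment"`.
#' @return A [feature_schema()].
#' @export
schema_for_stage <- function(schema, stage = c("on-treatment", "pretreatment")) {
  stage <- match.arg(stage)
  keep <- if (stage == "on-treatment") {
    rep(TRUE, nrow(schema$features))
  } else {
    schema$features$stage == "pretreatment"
  }
  feature_schema(schema$features[keep, ], schema$duration, schema$event)
}

#' Read / write a feature schema as a YAML document
#'
#' The on-disk form lists features with `name`, `role`, `levels` (categorical
#' only) and `stage`, plus top-level `duration` and `event` keys.
#'
#' @param path File path.
#' @return `read_schema()` returns a [feature_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  feats <- purrr::map(doc$features, function(f) {
    tibble(
      name = f$name, role = f$role,
      levels = list(if (is.null(f$levels)) NULL else as.character(f$levels)),
      stage = f$stage %||% "pretreatment"
    )
  })
  feature_schema(dplyr::bind_rows(feats), doc$duration, doc$event)
}

#' @rdname read_schema
#' @param schema A [feature_schema()].
#' @export
write_schema <- function(schema, path) {
  doc <- list(
    features = purrr::pmap(schema$features, function(name, role, levels, stage) {
      out <- list(name = name, role = role, stage = stage)
      if (!is.null(levels)) out$levels <- as.list(levels)
      out
    }),
    duration = schema$duration,
    event = schema$event
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
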