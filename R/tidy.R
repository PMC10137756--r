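#' Tidy a trained risk model
#'
#' For the linear baseline: one row per covariate with the coefficient on the
#' raw code scale. For the transformer model: one row per parameter group
#' with its element count and norm (the parameters themselves are not
#' table-shaped).
#'
#' @param x A trained `risk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_model <- function(x, ...) {
  if (x$type == "linear") {
    co <- linear_coefficients(x)
    return(tibble(term = names(co), estimate = unname(co)))
  }
  flat <- unlist(x$params)
  groups <- sub("^([a-z]+)\\..*$", "\\1", names(flat))
  dplyr::summarise(
    dplyr::group_by(tibble(group = groups, value = flat), .data$group),
    n_parameters = dplyr::n(),
    l2_norm = sqrt(sum(.data$value^2)),
    .groups = "drop"
  )
}

#' One-row model summary
#'
#' @param x A trained `risk_model`.
#' @param ... Unused.
#' @return A tibble with model type, parameter count, best epoch and best
#'   validation loss.
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    type = x$type,
    n_parameters = length(unlist(x$params)),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_valid_loss = x$best_valid_loss %||% NA_real_,
    epochs_run = if (is.null(x$history)) NA_integer_ else nrow(x$history)
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model:", x$type, "> ", length(unlist(x$params)), " parameters",
      if (isTRUE(x$trained)) paste0(", trained (best epoch ", x$best_epoch, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.survival_curve <- function(x, ...) as_tibble(x)

#' @export
tidy.baseline_hazard <- function(x, ...) as_tibble(x)
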