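#' Plot a survival curve
#'
#' Right-continuous step plot of `S(t)`; works for Kaplan-Meier curves and
#' model-predicted curves alike.
#'
#' @param object A `survival_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survival_curve <- function(object, ...) {
  df <- as_tibble(object)
  df <- dplyr::bind_rows(tibble(time = 0, surv = 1), df[c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "S(t)") +
    ggplot2::theme_minimal()
}

#' Plot several predicted survival curves together
#'
#' @param curves A named list of `survival_curve`s (as from
#'   [predict_survival()]).
#' @return A ggplot with one step per patient.
#' @export
plot_survival_curves <- function(curves) {
  df <- dplyr::bind_rows(purrr::imap(curves, function(cv, id) {
    tibble(id = id, time = c(0, cv$time), surv = c(1, cv$surv))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$id)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "S(t)", colour = "Patient") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot stratified by a grouping variable
#'
#' @param data A `survival_dataset`.
#' @param by Name of a categorical feature to stratify on, or `NULL` for a
#'   single overall curve.
#' @return A ggplot.
#' @export
plot_km <- function(data, by = NULL) {
  if (is.null(by)) {
    return(autoplot(kaplan_meier(data$t, data$d)))
  }
  df <- as_tibble(data)
  if (!by %in% names(df)) abort(paste0("no feature '", by, "'"))
  parts <- dplyr::bind_rows(purrr::map(unique(df[[by]]), function(lv) {
    sel <- df[[by]] == lv
    km <- kaplan_meier(data$t[sel], data$d[sel])
    tibble(group = lv, time = c(0, km$time), surv = c(1, km$surv))
  }))
  ggplot2::ggplot(parts, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "S(t)", colour = by) +
    ggplot2::theme_minimal()
}

#' Training-history plot of a fitted model
#'
#' @param model A trained `risk_model` with a `history` field.
#' @return A ggplot of train and validation loss per epoch.
#' @export
plot_history <- function(model) {
  if (is.null(model$history)) abort("model carries no training history")
  df <- tidyr::pivot_longer(model$history, c("train_loss", "valid_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Partial-likelihood loss") +
    ggplot2::theme_minimal()
}
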