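#' Breslow estimate of the baseline cumulative hazard
#'
#' For every unique event time `t_i` with `e_i` events, the increment is
#' `e_i / sum_{j: t_j >= t_i} exp(g(t_i, x_j))`: the risk-set denominator
#' re-evaluates the time-dependent risk at `t_i` for every subject still at
#' risk. Tied events share one increment (Breslow tie handling). With
#' `g == 0` the estimator reduces to Nelson-Aalen.
#'
#' @param model A trained `risk_model`.
#' @param train The (preprocessed) dataset the model was trained on.
#' @param chunk Maximum number of (event time, subject) pairs evaluated per
#'   block; bounds memory on large cohorts.
#' @return A `baseline_hazard`: tibble-backed list with `time` (sorted unique
#'   event times), `increment` and `cumhaz`.
#' @export
breslow_fit <- function(model, train, chunk = 2e5) {
  ev_t <- train$t[train$d == 1L]
  if (!length(ev_t)) abort("no events: baseline hazard undefined")
  ut <- sort(unique(ev_t))
  e_i <- as.vector(table(factor(ev_t, levels = ut)))
  ord <- order(train$t)
  t_sorted <- train$t[ord]
  enc <- if (model$type == "ttsurv") encode_covariates(model, train) else NULL
  Xlin <- if (model$type == "linear") linear_design(model, train) else NULL
  denom <- numeric(length(ut))
  # subjects at risk at ut[i]: those with t >= ut[i]
  first_at_risk <- findInterval(ut - 1e-9, t_sorted) + 1L
  if (model$type == "linear") {
    r <- exp(as.vector(Xlin %*% model$params$beta))[ord]
    rev_cum <- rev(cumsum(rev(r)))
    denom <- rev_cum[first_at_risk]
  } else {
    # time-dependent g: evaluate g(ut[i], x_j) for all at-risk j, chunked
    fh <- fast_head_prepare(enc$Z, model$params$head)
    pair_t <- integer(0); pair_j <- integer(0)
    flush <- function(pt, pj) {
      ts <- scale_time(model, ut[pt])
      g <- fast_head_g(fh, pj, ts)
      agg <- rowsum(exp(g), pt)
      denom[as.integer(rownames(agg))] <<-
        denom[as.integer(rownames(agg))] + as.vector(agg)
    }
    for (i in seq_along(ut)) {
      js <- ord[first_at_risk[i]:train$n]
      pair_t <- c(pair_t, rep(i, length(js)))
      pair_j <- c(pair_j, js)
      if (length(pair_t) >= chunk) {
        flush(pair_t, pair_j)
        pair_t <- integer(0); pair_j <- integer(0)
      }
    }
    if (length(pair_t)) flush(pair_t, pair_j)
  }
  inc <- e_i / denom
  structure(
    list(time = ut, increment = inc, cumhaz = cumsum(inc),
         n_events = sum(train$d), model_type = model$type),
    class = "baseline_hazard"
  )
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("<baseline_hazard> ", length(x$time), " event times, H0(max) = ",
      sprintf("%.4f", max(x$cumhaz)), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.baseline_hazard <- function(x, ...) {
  tibble(time = x$time, increment = x$increment, cumhaz = x$cumhaz)
}

new_survival_curve <- function(time, surv, n_risk = NULL) {
  structure(list(time = time, surv = surv, n_risk = n_risk),
            class = "survival_curve")
}

#' @export
as_tibble.survival_curve <- function(x, ...) {
  out <- tibble(time = x$time, surv = x$surv)
  if (!is.null(x$n_risk)) out$n_risk <- x$n_risk
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> ", length(x$time), " steps, S(max t) = ",
      sprintf("%.4f", x$surv[length(x$surv)]), "\n", sep = "")
  invisible(x)
}

#' Predicted survival curves from a model and its baseline hazard
#'
#' `S(t|x) = exp(- sum_{t_i <= t} dH0(t_i) exp(g(t_i, x)))`, a
#' right-continuous step function on the baseline's event-time grid (no
#' interpolation between steps). Adding a constant to `g` is absorbed by the
#' baseline, so predicted curves are invariant to it.
#'
#' @param model A trained `risk_model`.
#' @param hazard A [breslow_fit()] result from the same model.
#' @param data A preprocessed `survival_dataset` of patients to predict.
#' @param chunk Pair-count bound per evaluation block.
#' @return A list of `survival_curve` objects, one per patient, named by id.
#' @export
predict_survival <- function(model, hazard, data, chunk = 2e5) {
  M <- length(hazard$time)
  n <- data$n
  if (model$type == "linear") {
    r <- as.vector(linear_design(model, data) %*% model$params$beta)
    curves <- purrr::map(seq_len(n), function(j) {
      new_survival_curve(hazard$time,
                         exp(-cumsum(hazard$increment * exp(r[j]))))
    })
  } else {
    enc <- encode_covariates(model, data)
    fh <- fast_head_prepare(enc$Z, model$params$head)
    ts_all <- scale_time(model, hazard$time)
    per <- max(1L, floor(chunk / M))
    curves <- vector("list", n)
    for (start in seq(1L, n, by = per)) {
      js <- start:min(n, start + per - 1L)
      pj <- rep(js, each = M)
      pt <- rep(ts_all, times = length(js))
      g <- fast_head_g(fh, pj, pt)
      gm <- matrix(g, nrow = M)
      for (kk in seq_along(js)) {
        curves[[js[kk]]] <- new_survival_curve(
          hazard$time, exp(-cumsum(hazard$increment * exp(gm[, kk]))))
      }
    }
  }
  setNames(curves, data$ids)
}

#' Median survival time of a predicted curve
#'
#' The smallest grid time at which `S(t) <= 0.5`. When the curve never
#' reaches 0.5 within the grid, the largest grid time is returned with
#' `crossed = FALSE`, so downstream error metrics remain computable for every
#' patient; the flag lets callers exclude such patients instead if they wish.
#'
#' @param curve A `survival_curve`.
#' @return A list with `days` and logical `crossed`.
#' @export
median_survival_time <- function(curve) {
  if (!length(curve$time)) abort("empty survival curve")
  hit <- which(curve$surv <= 0.5)
  if (length(hit)) {
    list(days = curve$time[hit[1]], crossed = TRUE)
  } else {
    list(days = curve$time[length(curve$time)], crossed = FALSE)
  }
}

#' Median life table for a set of patients
#'
#' @param curves A list of `survival_curve`s as from [predict_survival()].
#' @return A tibble with `id`, `median_life_days`, `crossed`.
#' @export
median_life_table <- function(curves) {
  ml <- purrr::map(curves, median_survival_time)
  tibble(
    id = names(curves) %||% as.character(seq_along(curves)),
    median_life_days = unname(purrr::map_dbl(ml, "days")),
    crossed = unname(purrr::map_lgl(ml, "crossed"))
  )
}

#' Export a baseline hazard / survival curve as delimited text
#' @param x A `baseline_hazard` or `survival_curve`.
#' @param path Output path (tab-separated, with header).
#' @return `path` invisibly.
#' @export
write_steps <- function(x, path) {
  utils::write.table(as_tibble(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a baseline hazard written by [write_steps()]
#' @param path File path.
#' @return A `baseline_hazard`.
#' @export
read_baseline_hazard <- function(path) {
  df <- utils::read.delim(path)
  structure(list(time = df$time, increment = df$increment,
                 cumhaz = cumsum(df$increment), model_type = "file"),
            class = "baseline_hazard")
}
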