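#' Concordance index for right-censored survival data
#'
#' Pairwise concordance: the numerator counts ordered pairs (i, j) with
#' `T_j < T_i`, the shorter time an observed event (`d_j = 1`), and the
#' shorter-lived patient assigned the strictly higher risk (`eta_j > eta_i`);
#' the denominator counts all pairs with `T_j < T_i` and `d_j = 1`. With the
#' default strict inequalities, tied risk scores earn no credit;
#' `ties = "half"` gives the Harrell-style half credit for risk ties instead.
#' 1.0 is perfect concordance, 0.5 is chance level.
#'
#' @param times Observed times.
#' @param risks Risk scores (higher = predicted to die sooner).
#' @param events Event indicators (1 = observed event, 0 = censored).
#' @param ties `"strict"` (default) or `"half"`.
#' @param chunk Row-block size for the pairwise computation.
#' @return A number in `[0, 1]`.
#' @export
c_index <- function(times, risks, events, ties = c("strict", "half"),
                    chunk = 512L) {
  ties <- match.arg(ties)
  n <- length(times)
  stopifnot(length(risks) == n, length(events) == n)
  num <- 0
  den <- 0
  ev <- which(events == 1)
  if (!length(ev)) abort("no comparable pairs (no event precedes another time)")
  for (start in seq(1L, length(ev), by = chunk)) {
    j <- ev[start:min(length(ev), start + chunk - 1L)]
    cmp <- outer(times[j], times, "<")          # T_j < T_i
    den <- den + sum(cmp)
    conc <- outer(risks[j], risks, ">")
    num <- num + sum(cmp & conc)
    if (ties == "half") {
      tied <- outer(risks[j], risks, "==")
      # a pair tied on risk with itself never satisfies T_j < T_i
      num <- num + 0.5 * sum(cmp & tied)
    }
  }
  if (den == 0) abort("no comparable pairs (no event precedes another time)")
  num / den
}

#' Mean absolute error over patients with observed events
#'
#' `mean(|y_i - yhat_i|)` restricted to patients whose event was observed
#' (`d = 1`); censored patients carry only a lower bound on survival and are
#' excluded entirely. Undefined (an error) when no event was observed.
#'
#' @param true_days True survival times in days.
#' @param predicted_days Predicted survival times (median life) in days.
#' @param events Event indicators.
#' @return Non-negative number (days).
#' @export
mae_uncensored <- function(true_days, predicted_days, events) {
  stopifnot(length(true_days) == length(predicted_days),
            length(true_days) == length(events))
  keep <- events == 1
  if (!sum(keep)) abort("no observed events: event-only MAE undefined")
  mean(abs(true_days[keep] - predicted_days[keep]))
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t) = prod_{t_i <= t} (1 - e_i / n_i)` over the event times, with `e_i`
#' events among `n_i` at risk. Computed via the survival package's
#' product-limit machinery and returned on the package's step-curve type.
#'
#' @param times Observed times.
#' @param events Event indicators.
#' @return A `survival_curve` (with an `n_risk` column) whose grid is the
#'   distinct observed times.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  new_survival_curve(fit$time, fit$surv, n_risk = fit$n.risk)
}

#' Log-rank test for two or more groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance (via the survival package), with an asymptotic chi-square p-value
#' on `groups - 1` degrees of freedom.
#'
#' @param times Observed times.
#' @param events Event indicators.
#' @param groups Group labels (>= 2 distinct values).
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("log-rank test needs >= 2 groups")
  if (!sum(events)) abort("log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  tibble(statistic = fit$chisq, df = df,
         p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Assemble an evaluation report from per-fold metric rows
#'
#' @param per_fold A tibble with one row per (fold, cohort) and columns
#'   `fold`, `cohort`, `c_index`, `mae_days`, `n_events_used`.
#' @return An `evaluation_report` whose [tidy()] method returns the per-fold
#'   rows and [glance()] the per-cohort means.
#' @export
evaluation_report <- function(per_fold) {
  per_fold <- as_tibble(per_fold)
  structure(list(per_fold = per_fold), class = "evaluation_report")
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_fold

#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$per_fold, .data$cohort),
    mean_c_index = mean(.data$c_index),
    mean_mae_days = mean(.data$mae_days),
    folds = dplyr::n(),
    .groups = "drop"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(glance(x))
  invisible(x)
}
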