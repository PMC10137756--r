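#' Stratified k-fold split on the event indicator
#'
#' Partitions patients into `k` folds so that the number of events (and of
#' censored patients) differs by at most one across folds: within each
#' stratum (d = 1 and d = 0) the indices are shuffled under the seed and
#' dealt round-robin. Stratifying on the event indicator keeps every fold's
#' event rate comparable, which stabilises both the partial-likelihood fit
#' and the event-only metrics.
#'
#' @param data A `survival_dataset`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the split is deterministic given it.
#' @return A list of `k` elements, each `list(train = <int>, valid = <int>)`;
#'   the validation sets partition `1:n`.
#' @export
stratified_kfold <- function(data, k, seed) {
  if (k < 2) abort("k must be at least 2")
  n <- data$n
  for (s in c(0L, 1L)) {
    if (sum(data$d == s) < k) {
      abort(paste0("stratum d=", s, " has fewer than k=", k, " members"))
    }
  }
  assign_fold <- withr::with_seed(seed, {
    fold <- integer(n)
    for (s in c(1L, 0L)) {
      idx <- sample(which(data$d == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  purrr::map(seq_len(k), function(f) {
    list(train = which(assign_fold != f), valid = which(assign_fold == f))
  })
}

#' Fold assignments as a tidy table
#' @param data A `survival_dataset`.
#' @param folds Result of [stratified_kfold()].
#' @return A tibble with columns `id` and `fold` (validation fold of each
#'   patient).
#' @export
fold_table <- function(data, folds) {
  fold <- integer(data$n)
  for (f in seq_along(folds)) fold[folds[[f]]$valid] <- f
  tibble(id = data$ids, fold = fold)
}
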