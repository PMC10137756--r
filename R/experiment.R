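#' Stratified cross-validation with external-cohort validation
#'
#' The experimental protocol: the training cohort is split into `k`
#' stratified folds; within each fold the preprocessor is fitted on the
#' fold's training split only, a model is trained with the fold's validation
#' split driving early stopping ("best weights"), the Breslow baseline is
#' fitted on the training split, and C-index and event-only MAE are computed
#' on (a) the fold's validation split and (b) the full external cohort, which
#' is never touched by preprocessing fitting, training or model selection.
#' Per-fold metrics and their means are reported; external metrics are the
#' average over the k fold models, not an ensemble.
#'
#' The C-index risk score of the time-dependent model is the predicted
#' cumulative hazard at the last baseline grid time (a continuous, tie-free
#' monotone summary of each patient's predicted risk); the linear baseline
#' uses `beta' x` directly.
#'
#' @param train_data Training-cohort `survival_dataset`.
#' @param external_data Optional external-cohort `survival_dataset` under the
#'   same schema.
#' @param stage Feature stage: `"pretreatment"` or `"on-treatment"` (all
#'   features).
#' @param k Number of folds.
#' @param seed Seed controlling folds, initialization and training.
#' @param model `"ttsurv"` or `"linear"`.
#' @param encoder An [encoder_config()] (ignored for the linear model).
#' @param training A [training_config()]; its seed is derived from `seed`.
#' @param dense_width Hidden width of the dense block.
#' @return A `cv_report`: [tidy()] gives per-fold rows, [glance()] per-cohort
#'   means; `$fold_models` holds the per-fold fits, `$folds` the index sets.
#' @export
run_cross_validation <- function(train_data, external_data = NULL,
                                 stage = c("on-treatment", "pretreatment"),
                                 k = 5, seed = 1, model = c("ttsurv", "linear"),
                                 encoder = encoder_config(),
                                 training = training_config(),
                                 dense_width = 64) {
  stage <- match.arg(stage)
  model_kind <- match.arg(model)
  tr_all <- dataset_for_stage(train_data, stage)
  ext_all <- if (!is.null(external_data)) {
    dataset_for_stage(external_data, stage)
  }
  folds <- stratified_kfold(tr_all, k, seed)
  rows <- list()
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dataset_subset(tr_all, folds[[f]]$train)
    va <- dataset_subset(tr_all, folds[[f]]$valid)
    pre <- fit_preprocessor(tr)
    trp <- apply_preprocessor(pre, tr)
    vap <- apply_preprocessor(pre, va)
    cfg <- training
    cfg$seed <- seed * 1000L + f
    fit <- if (model_kind == "ttsurv") {
      m0 <- risk_model(trp$schema, encoder, dense_width, seed = cfg$seed)
      train(m0, trp, vap, cfg)
    } else {
      linear_baseline(trp, vap, cfg)
    }
    hz <- breslow_fit(fit, trp)
    fold_models[[f]] <- list(model = fit, preprocessor = pre, hazard = hz)
    rows[[length(rows) + 1L]] <-
      cbind(tibble(fold = f, cohort = "internal"),
            evaluate_cohort(fit, hz, pre, va))
    if (!is.null(ext_all)) {
      rows[[length(rows) + 1L]] <-
        cbind(tibble(fold = f, cohort = "external"),
              evaluate_cohort(fit, hz, pre, ext_all))
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  structure(
    list(per_fold = as_tibble(per_fold), folds = folds,
         fold_models = fold_models, stage = stage, k = k, seed = seed,
         model = model_kind, version = as.character(utils::packageVersion("ttsurv"))),
    class = c("cv_report", "evaluation_report")
  )
}

# C-index + event-only MAE of one fitted fold model on a raw cohort.
evaluate_cohort <- function(fit, hazard, pre, cohort_raw) {
  cp <- apply_preprocessor(pre, cohort_raw)
  eta <- risk_score(fit, hazard, cp)
  ml <- median_life_table(predict_survival(fit, hazard, cp))
  tibble(
    c_index = c_index(cp$t, eta, cp$d),
    mae_days = mae_uncensored(cp$t, ml$median_life_days, cp$d),
    n_events_used = sum(cp$d)
  )
}

#' Scalar risk score used for concordance evaluation
#'
#' For the time-dependent model: the log cumulative hazard at the last
#' baseline grid time, `log H(t_ref | x)`; for the linear model: `beta' x`.
#'
#' @param fit A trained `risk_model`.
#' @param hazard Its [breslow_fit()] baseline.
#' @param data A preprocessed `survival_dataset`.
#' @return Numeric vector, higher = higher predicted risk.
#' @export
risk_score <- function(fit, hazard, data) {
  if (fit$type == "linear") {
    return(as.vector(linear_design(fit, data) %*% fit$params$beta))
  }
  curves <- predict_survival(fit, hazard, data)
  log(-log(pmax(purrr::map_dbl(curves, function(cv) {
    cv$surv[length(cv$surv)]
  }), 1e-300)))
}

#' Compare pretreatment and on-treatment feature groups
#'
#' Runs [run_cross_validation()] twice under identical folds and seeds,
#' differing only in the feature stage (the on-treatment arm adds the
#' Deauville score), and reports side-by-side metrics with their differences
#' — the design used to quantify the prognostic contribution of the
#' interim-PET response.
#'
#' @inheritParams run_cross_validation
#' @return A `stage_comparison`: `$pre`, `$on` (the two `cv_report`s) and
#'   `$paired`, a tibble of paired means and differences.
#' @export
compare_stages <- function(train_data, external_data = NULL, k = 5, seed = 1,
                           model = "ttsurv", encoder = encoder_config(),
                           training = training_config(), dense_width = 64) {
  if (!any(train_data$schema$features$stage == "on-treatment")) {
    abort("schema has no on-treatment feature to compare")
  }
  pre_rep <- run_cross_validation(train_data, external_data, "pretreatment",
                                  k, seed, model, encoder, training,
                                  dense_width)
  on_rep <- run_cross_validation(train_data, external_data, "on-treatment",
                                 k, seed, model, encoder, training,
                                 dense_width)
  g_pre <- glance(pre_rep)
  g_on <- glance(on_rep)
  paired <- dplyr::inner_join(
    dplyr::rename(g_pre, c_index_pre = "mean_c_index", mae_pre = "mean_mae_days"),
    dplyr::rename(g_on, c_index_on = "mean_c_index", mae_on = "mean_mae_days"),
    by = c("cohort", "folds")
  )
  paired$c_index_diff <- paired$c_index_on - paired$c_index_pre
  paired$mae_diff <- paired$mae_on - paired$mae_pre
  structure(list(pre = pre_rep, on = on_rep, paired = paired),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("<stage_comparison>\n")
  print(x$paired)
  invisible(x)
}

#' @export
tidy.stage_comparison <- function(x, ...) x$paired

#' Per-patient survival predictions from serialized artifacts
#'
#' Loads a serialized model (with its preprocessor) and baseline hazard,
#' predicts every patient of a cohort file and emits the per-patient median
#' life table plus the full survival curves in long form.
#'
#' @param model_file Path written by [write_model()].
#' @param hazard_file Path written by [write_steps()] on a baseline hazard.
#' @param cohort_file CSV cohort path (read under the model's schema).
#' @return A list with `predictions` (tibble: id, median_life_days, crossed)
#'   and `curves` (long tibble: id, time, surv).
#' @export
predict_patients <- function(model_file, hazard_file, cohort_file) {
  bundle <- read_model(model_file)
  hz <- read_baseline_hazard(hazard_file)
  cohort <- load_dataset(cohort_file, bundle$model$schema)
  cohort <- apply_preprocessor(bundle$preprocessor, cohort)
  curves <- predict_survival(bundle$model, hz, cohort)
  preds <- median_life_table(curves)
  long <- dplyr::bind_rows(purrr::imap(curves, function(cv, id) {
    tibble(id = id, time = cv$time, surv = cv$surv)
  }))
  list(predictions = preds, curves = long)
}
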