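# Protocol tests use small cohorts and a lean configuration: they verify the
# cross-validation contract (shapes, determinism, external-cohort hygiene),
# not model quality.

lean_cfg <- function(seed = 1) {
  training_config(max_epochs = 3, patience = 2, seed = seed)
}

lean_enc <- function() {
  encoder_config(d_embed = 8, n_layers = 1, n_heads = 2, mlp_hidden = 16,
                 t_tokens = 1)
}

test_that("cross-validation reports k folds per cohort plus means, deterministically", {
  tr <- simulate_cohort(linear_ph_scenario(0.5), 240, seed = 61)
  ex <- simulate_cohort(linear_ph_scenario(0.5), 120, seed = 62)
  rep1 <- run_cross_validation(tr, ex, stage = "on-treatment", k = 2,
                               seed = 3, model = "ttsurv",
                               encoder = lean_enc(), training = lean_cfg(),
                               dense_width = 16)
  td <- tidy(rep1)
  expect_equal(nrow(td), 2 * 2)       # k folds x {internal, external}
  expect_setequal(unique(td$cohort), c("internal", "external"))
  expect_equal(nrow(glance(rep1)), 2) # one mean row per cohort
  expect_true(all(td$c_index >= 0 & td$c_index <= 1))
  expect_true(all(td$mae_days >= 0))

  rep2 <- run_cross_validation(tr, ex, stage = "on-treatment", k = 2,
                               seed = 3, model = "ttsurv",
                               encoder = lean_enc(), training = lean_cfg(),
                               dense_width = 16)
  expect_identical(tidy(rep1), tidy(rep2))
})

test_that("the linear model runs through the same protocol", {
  tr <- simulate_cohort(linear_ph_scenario(0.5), 200, seed = 63)
  rep <- run_cross_validation(tr, NULL, stage = "pretreatment", k = 2,
                              seed = 4, model = "linear",
                              training = lean_cfg())
  expect_equal(nrow(tidy(rep)), 2)
  expect_true(all(tidy(rep)$cohort == "internal"))
})

test_that("stage comparison shares folds and differences are arithmetic", {
  tr <- simulate_cohort(linear_ph_scenario(0.5), 240, seed = 64)
  cmp <- compare_stages(tr, NULL, k = 2, seed = 5, model = "linear",
                        training = lean_cfg())
  expect_identical(cmp$pre$folds, cmp$on$folds)
  paired <- tidy(cmp)
  expect_equal(paired$c_index_diff, paired$c_index_on - paired$c_index_pre)
  expect_equal(paired$mae_diff, paired$mae_on - paired$mae_pre)
  # the pretreatment arm must not see the on-treatment feature
  expect_false("deauville" %in%
                 cmp$pre$fold_models[[1]]$model$schema$features$name)
})

test_that("external cohort with a level unseen in the schema errors at load", {
  tr <- simulate_cohort(linear_ph_scenario(0.5), 80, seed = 65)
  p <- withr::local_tempfile(fileext = ".csv")
  df <- as_tibble(tr)
  df$stage[1] <- "V"
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(load_dataset(p, dlbcl_schema()), "unknown level 'V'")
})

test_that("predict_patients round trips artifacts and matches curve crossings", {
  tr <- simulate_cohort(linear_ph_scenario(0.5), 150, seed = 66)
  vi <- withr::with_seed(1, sample(150, 30))
  trn <- dataset_subset(tr, setdiff(1:150, vi))
  va <- dataset_subset(tr, vi)
  pre <- fit_preprocessor(trn)
  fit <- train(risk_model(trn$schema, lean_enc(), 16, seed = 2),
               apply_preprocessor(pre, trn), apply_preprocessor(pre, va),
               lean_cfg())
  hz <- breslow_fit(fit, apply_preprocessor(pre, trn))
  mfile <- withr::local_tempfile(fileext = ".json")
  hfile <- withr::local_tempfile(fileext = ".tsv")
  cfile <- withr::local_tempfile(fileext = ".csv")
  write_model(fit, pre, mfile)
  write_steps(hz, hfile)
  write_dataset(va, cfile)

  out <- predict_patients(mfile, hfile, cfile)
  expect_equal(nrow(out$predictions), va$n)
  expect_setequal(out$predictions$id, va$ids)
  # each median-life value is the first 0.5-crossing of the exported curve
  for (id in out$predictions$id[1:5]) {
    cv <- dplyr::filter(out$curves, .data$id == !!id)
    ml <- out$predictions$median_life_days[out$predictions$id == id]
    crossed <- out$predictions$crossed[out$predictions$id == id]
    if (crossed) {
      expect_equal(ml, cv$time[which(cv$surv <= 0.5)[1]])
    } else {
      expect_equal(ml, max(cv$time))
    }
  }
  out2 <- predict_patients(mfile, hfile, cfile)
  expect_identical(out, out2)
})

test_that("plot builders return ggplot objects", {
  ds <- simulate_cohort(linear_ph_scenario(0.5), 120, seed = 67)
  expect_s3_class(plot_km(ds, by = "stage"), "ggplot")
  expect_s3_class(autoplot(kaplan_meier(ds$t, ds$d)), "ggplot")
  km <- kaplan_meier(ds$t, ds$d)
  expect_s3_class(tidy(km), "tbl_df")
})
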