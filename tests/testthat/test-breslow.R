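const_g_model <- function(ds, value = 0) {
  m <- tiny_model(ds, seed = 3)
  m$params$head$wout[] <- 0
  m$params$head$bout <- value
  m
}

test_that("null-risk Breslow reduces to the Nelson-Aalen closed form", {
  # three subjects, events at t = 1, 2, 3: increments 1/3, 1/2, 1/1
  ds <- tiny_cohort(n = 3, seed = 1, events = c(1, 1, 1))
  ds$t <- c(1, 2, 3)
  m <- const_g_model(ds, 0)
  hz <- breslow_fit(m, ds)
  expect_equal(hz$time, c(1, 2, 3))
  expect_equal(hz$increment, c(1 / 3, 1 / 2, 1))
  expect_equal(hz$cumhaz, c(1 / 3, 5 / 6, 11 / 6))

  # survival plug-in: S = exp(-H0) for the null model
  cv <- predict_survival(m, hz, dataset_subset(ds, 1))[[1]]
  expect_equal(cv$surv, exp(-c(1 / 3, 5 / 6, 11 / 6)))
})

test_that("single event among n at risk gives increment 1/n under null risk", {
  ds <- tiny_cohort(n = 5, seed = 2, events = c(0, 0, 1, 0, 0))
  ds$t <- c(10, 20, 5, 30, 40)   # event at 5, everyone at risk
  m <- const_g_model(ds, 0)
  hz <- breslow_fit(m, ds)
  expect_equal(hz$increment, 1 / 5)
  cens <- ds
  cens$d <- rep(0L, 5)
  expect_error(breslow_fit(m, cens), "no events")
})

test_that("a constant added to g is absorbed: increments scale by exp(-c), S unchanged", {
  ds <- tiny_cohort(n = 12, seed = 4)
  m1 <- tiny_model(ds, seed = 5, randomize = 6)
  m2 <- m1
  m2$params$head$bout <- m2$params$head$bout + 1.3
  h1 <- breslow_fit(m1, ds)
  h2 <- breslow_fit(m2, ds)
  expect_equal(h2$increment, h1$increment * exp(-1.3), tolerance = 1e-12)
  s1 <- predict_survival(m1, h1, ds)
  s2 <- predict_survival(m2, h2, ds)
  for (i in seq_len(ds$n)) expect_equal(s2[[i]]$surv, s1[[i]]$surv,
                                        tolerance = 1e-10)
})

test_that("tied events share one increment with a common denominator", {
  ds <- tiny_cohort(n = 4, seed = 7, events = c(1, 1, 1, 0))
  ds$t <- c(5, 5, 9, 9)
  m <- const_g_model(ds, 0)
  hz <- breslow_fit(m, ds)
  expect_equal(hz$time, c(5, 9))
  expect_equal(hz$increment, c(2 / 4, 1 / 2))
})

test_that("predicted curves start at 1, never increase, and order by risk", {
  ds <- tiny_cohort(n = 15, seed = 8)
  m <- tiny_model(ds, seed = 9, randomize = 10)
  hz <- breslow_fit(m, ds)
  curves <- predict_survival(m, hz, ds)
  for (cv in curves) {
    expect_true(all(cv$surv <= 1 + 1e-12 & cv$surv >= 0))
    expect_true(all(diff(cv$surv) <= 1e-12))
  }
  # higher g at all grid times implies lower survival everywhere
  fh <- ttsurv:::fast_head_prepare(
    ttsurv:::encode_covariates(m, ds)$Z, m$params$head)
  ts <- ttsurv:::scale_time(m, hz$time)
  gmat <- vapply(seq_len(ds$n), function(j) {
    ttsurv:::fast_head_g(fh, rep(j, length(ts)), ts)
  }, numeric(length(hz$time)))
  for (a in 1:4) {
    for (b in 1:4) {
      if (a != b && all(gmat[, a] > gmat[, b])) {
        expect_true(all(curves[[a]]$surv <= curves[[b]]$surv + 1e-12))
      }
    }
  }
})

test_that("null-model survival tracks Kaplan-Meier within the NA-KM gap on small n", {
  ds <- tiny_cohort(n = 8, seed = 11, events = rep(1, 8))
  ds$t <- sort(ds$t) + seq(0, 0.7, 0.1)   # break ties
  m <- const_g_model(ds, 0)
  hz <- breslow_fit(m, ds)
  km <- kaplan_meier(ds$t, ds$d)
  s_na <- exp(-hz$cumhaz)
  # exp(-1/k) >= 1 - 1/k term by term; the gap is bounded by 1/(2 n_i^2) per
  # factor, accumulate generously for n = 8
  expect_true(all(s_na >= km$surv - 1e-12))
  expect_lt(max(abs(s_na - km$surv)), 0.15)
})

test_that("median survival time follows the first-crossing convention", {
  cv <- ttsurv:::new_survival_curve(c(100, 200, 300, 400),
                                    c(0.9, 0.6, 0.4, 0.1))
  expect_equal(median_survival_time(cv), list(days = 300, crossed = TRUE))
  cv2 <- ttsurv:::new_survival_curve(c(100, 200), c(0.9, 0.8))
  expect_equal(median_survival_time(cv2), list(days = 200, crossed = FALSE))
  cv3 <- ttsurv:::new_survival_curve(c(50, 60), c(0.5, 0.2))
  expect_equal(median_survival_time(cv3)$days, 50)
  expect_error(median_survival_time(ttsurv:::new_survival_curve(numeric(0),
                                                                numeric(0))),
               "empty")
})

test_that("baseline hazard export/import round trips through text", {
  ds <- tiny_cohort(n = 10, seed = 12)
  m <- tiny_model(ds, seed = 13, randomize = 14)
  hz <- breslow_fit(m, ds)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_steps(hz, p)
  hz2 <- read_baseline_hazard(p)
  expect_equal(hz2$time, hz$time)
  expect_equal(hz2$increment, hz$increment, tolerance = 1e-12)
})
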