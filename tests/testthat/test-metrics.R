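test_that("C-index endpoints: perfect reversal gives 1, identical order gives 0", {
  t <- 1:20
  expect_equal(c_index(t, -t, rep(1, 20)), 1.0)
  expect_equal(c_index(t, t, rep(1, 20)), 0.0)
  expect_error(c_index(1, 1, 1), "no comparable")
})

test_that("C-index matches the exhaustive pairwise oracle on random instances", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      n <- sample(4:25, 1)
      times <- sample(100, n, replace = TRUE)
      risks <- if (rep %% 3 == 0) sample(5, n, replace = TRUE) else rnorm(n)
      events <- if (rep %% 2 == 0) rep(1L, n) else rbinom(n, 1, 0.5)
      if (!any(events == 1)) events[1] <- 1L
      ok <- tryCatch({
        expect_identical(c_index(times, risks, events),
                         c_index_oracle(times, risks, events))
        expect_identical(c_index(times, risks, events, ties = "half"),
                         c_index_oracle(times, risks, events, half_ties = TRUE))
        TRUE
      }, error = function(e) {
        # no comparable pairs: both implementation and oracle must refuse
        expect_error(c_index_oracle(times, risks, events), "no comparable")
        TRUE
      })
      expect_true(ok)
    }
  })
})

test_that("C-index complement identity holds without risk ties", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- 15
      times <- sample(1000, n)
      risks <- rnorm(n)
      events <- rbinom(n, 1, 0.6)
      if (!any(events == 1)) events[1] <- 1L
      expect_equal(c_index(times, risks, events) +
                     c_index(times, -risks, events), 1)
    }
  })
})

test_that("event-only MAE reproduces the worked per-patient fixtures", {
  # five patients: truths vs predicted median life, before treatment
  truth <- c(321, 403, 1537, 2340, 2127)
  before <- c(324, 600, 977, 1571, 673)
  during <- c(332, 564, 1531, 1611, 677)
  expect_equal(mae_uncensored(truth[1], before[1], 1), 3)
  expect_equal(mae_uncensored(truth, before, rep(1, 5)), 596.6)
  expect_equal(mae_uncensored(truth, during, rep(1, 5)), 471.4)
})

test_that("MAE ignores censored patients entirely and is order-invariant", {
  truth <- c(100, 900, 250, 400)
  pred <- c(120, 111, 300, 350)
  ev <- c(1, 0, 1, 1)
  base <- mae_uncensored(truth, pred, ev)
  expect_equal(base, mean(c(20, 50, 50)))
  pred2 <- pred
  pred2[2] <- 1e6   # censored patient's value is irrelevant
  expect_equal(mae_uncensored(truth, pred2, ev), base)
  o <- c(3, 1, 4, 2)
  expect_equal(mae_uncensored(truth[o], pred[o], ev[o]), base)
  expect_error(mae_uncensored(truth, pred, rep(0, 4)), "no observed events")
})

test_that("Kaplan-Meier matches the product-limit hand computation", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  km_c <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  # no censoring: 1 - empirical CDF at every event time
  withr::with_seed(12, {
    t <- sample(50, 30, replace = TRUE)
    km2 <- kaplan_meier(t, rep(1, 30))
    expect_equal(km2$surv, 1 - ecdf(t)(km2$time))
  })
})

test_that("log-rank test: identical groups give statistic 0, and it matches a hand oracle", {
  t <- c(3, 6, 9, 12)
  lr0 <- logrank_test(c(t, t), c(1, 0, 1, 1, 1, 0, 1, 1),
                      rep(c("A", "B"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # A events at 1, 2; B events at 10, 20; no censoring.
  # Observed A = 2; expected A = 2/4 + 1/3 = 5/6; hypergeometric variances
  # at the four event times: v1 = (2*2)/(4*4) * (4-1)/(4-1)... computed as
  # e_i * (n_Ai/n_i) * (1 - n_Ai/n_i) * (n_i - e_i)/(n_i - 1) with e_i = 1:
  # t=1: p=2/4, v=1/4; t=2: p=1/3, v=2/9; t=10: p=0; t=20: p=0.
  tt <- c(1, 2, 10, 20)
  ev <- rep(1, 4)
  gp <- c("A", "A", "B", "B")
  O_A <- 2
  E_A <- 2 / 4 + 1 / 3
  V_A <- 1 / 4 + 2 / 9
  lr <- logrank_test(tt, ev, gp)
  expect_equal(lr$statistic, (O_A - E_A)^2 / V_A, tolerance = 1e-10)
  # invariant to relabeling
  lr_swap <- logrank_test(tt, ev, c("B", "B", "A", "A"))
  expect_equal(lr_swap$statistic, lr$statistic, tolerance = 1e-12)
  expect_error(logrank_test(tt, ev, rep("A", 4)), "2 groups")
})

test_that("evaluation report tidies per fold and averages per cohort", {
  rep <- evaluation_report(tibble::tibble(
    fold = c(1, 2, 1, 2), cohort = c("internal", "internal", "external", "external"),
    c_index = c(0.7, 0.8, 0.6, 0.7), mae_days = c(100, 120, 200, 220),
    n_events_used = c(10, 11, 20, 20)
  ))
  expect_equal(nrow(tidy(rep)), 4)
  g <- glance(rep)
  expect_equal(g$mean_c_index[g$cohort == "internal"], 0.75)
  expect_equal(g$mean_mae_days[g$cohort == "external"], 210)
})
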