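# Shared fixtures: a tiny mixed schema, cohort builders, and independent
# oracles (brute-force C-index, direct-summation partial likelihood) used to
# cross-check the vectorized implementations.

tiny_schema <- function() {
  feature_schema(
    tibble::tibble(
      name = c("x1", "f1", "f2"),
      role = c("continuous", "categorical", "categorical"),
      levels = list(NULL, c("a", "b"), c("p", "q", "r")),
      stage = c("pretreatment", "pretreatment", "on-treatment")
    ),
    duration = "time_days", event = "event"
  )
}

tiny_cohort <- function(n = 8, seed = 1, events = NULL) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      id = sprintf("P%02d", seq_len(n)),
      x1 = rnorm(n),
      f1 = sample(c("a", "b"), n, replace = TRUE),
      f2 = sample(c("p", "q", "r"), n, replace = TRUE),
      time_days = round(rexp(n, 1 / 300) + 1),
      event = if (is.null(events)) rbinom(n, 1, 0.6) else events
    )
    survival_dataset(df, tiny_schema())
  })
}

tiny_model <- function(ds, d_embed = 4, seed = 42, randomize = NULL) {
  cfg <- encoder_config(d_embed = d_embed, n_layers = 1, n_heads = 2,
                        mlp_hidden = 3, t_tokens = 1)
  m <- ttsurv:::risk_model(ds$schema, cfg, dense_width = 3, seed = seed)
  m <- ttsurv:::set_time_scale(m, ds)
  if (!is.null(randomize)) {
    # fully random parameters keep ReLU activations away from exact kinks
    theta <- unlist(m$params)
    theta <- withr::with_seed(randomize,
                              theta + rnorm(length(theta), sd = 0.05))
    m$params <- utils::relist(theta, m$params)
  }
  m
}

# Exhaustive double-loop concordance oracle, straight from the pairwise
# definition (strict inequalities; optional half credit for risk ties).
c_index_oracle <- function(times, risks, events, half_ties = FALSE) {
  n <- length(times)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (times[j] < times[i] && events[j] == 1) {
        den <- den + 1
        if (risks[j] > risks[i]) num <- num + 1
        else if (half_ties && risks[j] == risks[i]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Direct-summation full-risk-set partial likelihood oracle: for every event
# i, log sum_{j: t_j >= t_i} exp(g_j - g_i), averaged over events. g is a
# function(t, dataset_row_indices) -> numeric.
pll_oracle <- function(g_fun, ds) {
  ev <- which(ds$d == 1)
  terms <- vapply(ev, function(i) {
    rs <- which(ds$t >= ds$t[i])
    g <- g_fun(ds$t[i], rs)
    gi <- g_fun(ds$t[i], i)
    log(sum(exp(g - gi)))
  }, numeric(1))
  mean(terms)
}

# Numeric gradient by central finite differences on the flattened parameters.
numeric_gradient <- function(model, ds, pairs, eps = 1e-5) {
  theta <- unlist(model$params)
  f <- function(th) {
    model$params <- utils::relist(th, model$params)
    fw <- ttsurv:::model_pairs_forward(model, ds, pairs)
    ttsurv:::loss_from_g(fw$g, pairs)$loss
  }
  vapply(seq_along(theta), function(i) {
    tp <- theta
    tp[i] <- theta[i] + eps
    up <- f(tp)
    tp[i] <- theta[i] - eps
    dn <- f(tp)
    (up - dn) / (2 * eps)
  }, numeric(1))
}
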