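#' Construct an untrained TTSurv risk model
#'
#' The model realizes a time-dependent log relative risk `g(t, x)` in the
#' hazard factorization `h(t|x) = h0(t) exp(g(t, x))`. Categorical covariates
#' are column-embedded and contextualized by a transformer encoder; the `N`
#' feature tokens are flattened (special tokens excluded from pooling) and
#' concatenated with the continuous covariates and the standardized time,
#' then mapped to a scalar by a residual dense block.
#'
#' @param schema A [feature_schema()] describing the (already stage-selected)
#'   covariates the model will see.
#' @param config An [encoder_config()].
#' @param dense_width Hidden width of the residual dense block.
#' @param seed Seed for parameter initialization.
#' @return An object of class `c("ttsurv_model", "risk_model")`.
#' @export
risk_model <- function(schema, config = encoder_config(), dense_width = 64,
                       seed = 1) {
  card <- schema_cardinalities(schema)
  N <- length(card)
  p_cont <- nrow(schema_cont(schema))
  d <- config$d_embed
  p_in <- N * d + p_cont + 1L
  tab <- column_embedding_table(schema, d, config$t_tokens, seed)
  params <- list(
    emb = list(levels = tab$levels, cols = tab$cols, special = tab$special),
    enc = init_encoder_params(config, seed + 1L),
    head = init_head_params(p_in, dense_width, seed + 2L)
  )
  structure(
    list(type = "ttsurv", schema = schema, config = config,
         dense_width = dense_width, params = params,
         offsets = tab$offsets, cardinalities = card,
         N = N, p_cont = p_cont, p_in = p_in,
         time_mu = 0, time_sd = 1),
    class = c("ttsurv_model", "risk_model")
  )
}

#' Construct an untrained linear risk model
#'
#' A sanity baseline sharing the loss machinery of [risk_model()] but with
#' `g(t, x) = beta' x`: no transformer, no time input. Categorical codes
#' enter as (internally standardized) numeric columns, so the model is
#' linear-in-codes, playing the role a classical Cox fit plays in model
#' comparisons.
#'
#' @param schema A [feature_schema()].
#' @param seed Seed for initialization.
#' @return An object of class `c("linear_risk_model", "risk_model")`.
#' @export
linear_risk_model <- function(schema, seed = 1) {
  p <- nrow(schema_cont(schema)) + nrow(schema_cat(schema))
  nms <- c(schema_cont(schema)$name, schema_cat(schema)$name)
  structure(
    list(type = "linear", schema = schema,
         params = list(beta = setNames(numeric(p), nms)),
         code_center = setNames(numeric(p), nms),
         code_scale = setNames(rep(1, p), nms),
         time_mu = 0, time_sd = 1),
    class = c("linear_risk_model", "risk_model")
  )
}

scale_time <- function(model, t) (t - model$time_mu) / model$time_sd

# Design matrix of the linear model: continuous columns followed by the
# categorical codes, both shifted/scaled by the centering fitted in train().
linear_design <- function(model, data) {
  X <- cbind(data$x_cont, data$x_cat)
  colnames(X) <- names(model$params$beta)
  sweep(sweep(X, 2, model$code_center), 2, model$code_scale, "/")
}

# Encode the covariate part shared by all (t, x) pairs of one dataset:
# Z = [flatten(encoder feature tokens), x_cont], one row per patient.
encode_covariates <- function(model, data, keep_cache = FALSE) {
  eb <- embed_batch(data$x_cat, model$params$emb, model$offsets,
                    model$config$t_tokens)
  ef <- encoder_fwd(eb$X, model$params$enc, model$config, eb$B, eb$m,
                    keep_cache = keep_cache)
  B <- eb$B
  z_cat <- do.call(cbind, purrr::map(seq_len(model$N), function(i) {
    ef$out[tok_rows(i, B), , drop = FALSE]
  }))
  Z <- cbind(z_cat, data$x_cont)
  list(Z = Z, eb = eb, ef = ef, B = B)
}

# g for pairs (anchor time t[pair_t_of], covariates of row pair_j).
pairs_g <- function(model, enc, t_scaled_pairs, pair_j, keep_cache = FALSE) {
  U <- cbind(enc$Z[pair_j, , drop = FALSE], t_scaled_pairs)
  hf <- head_fwd(U, model$params$head, keep_cache = keep_cache)
  list(g = hf$g, hf = hf)
}

#' Evaluate the time-dependent log relative risk g(t, x)
#'
#' Computes `g(t_i, x_i)` for every patient of `data` at the supplied times.
#' Deterministic given the model parameters; batched evaluation matches
#' per-row evaluation.
#'
#' @param model A fitted or fresh `risk_model`.
#' @param data A preprocessed `survival_dataset`.
#' @param t Times (days) at which to evaluate; defaults to each patient's own
#'   observed time. Either length 1 (recycled) or `data$n`.
#' @return Numeric vector of length `data$n`.
#' @export
forward_risk <- function(model, data, t = data$t) {
  if (any(!is.finite(data$x_cont)) || any(!is.finite(t))) {
    abort("non-finite input to forward_risk")
  }
  t <- rep_len(t, data$n)
  if (model$type == "linear") {
    return(as.vector(linear_design(model, data) %*% model$params$beta))
  }
  enc <- encode_covariates(model, data)
  pairs_g(model, enc, scale_time(model, t), seq_len(data$n))$g
}

# ---- partial likelihood -----------------------------------------------------

# Build the (anchor, comparator) pair list for the sampled-risk-set loss.
# Each event i anchors one group: itself first, then `sampled_controls`
# uniform draws from its risk set {j : t_j >= t_i} \ {i} (fewer when the risk
# set is small), or the full risk set when sampled_controls is NULL.
build_pairs <- function(data, sampled_controls = NULL) {
  ev <- which(data$d == 1L)
  if (!length(ev)) abort("no events in batch: partial likelihood undefined")
  pair_i <- integer(0); pair_j <- integer(0); pair_grp <- integer(0)
  for (k in seq_along(ev)) {
    i <- ev[k]
    rs <- which(data$t >= data$t[i])
    rs <- rs[rs != i]
    if (!is.null(sampled_controls)) {
      take <- min(sampled_controls, length(rs))
      rs <- if (take > 0) rs[sample.int(length(rs), take)] else integer(0)
    }
    js <- c(i, rs)
    pair_i <- c(pair_i, rep(i, length(js)))
    pair_j <- c(pair_j, js)
    pair_grp <- c(pair_grp, rep(k, length(js)))
  }
  list(events = ev, pair_i = pair_i, pair_j = pair_j, pair_grp = pair_grp,
       self = !duplicated(pair_grp))
}

# loss = mean over events of [logsumexp_j g(t_i, x_j) - g(t_i, x_i)]
# with the self term always present, so every group's loss is >= 0.
loss_from_g <- function(g, pairs) {
  n_ev <- length(pairs$events)
  gmax <- tapply(g, pairs$pair_grp, max)[as.character(seq_len(n_ev))]
  e <- exp(g - gmax[pairs$pair_grp])
  ssum <- as.vector(rowsum(e, pairs$pair_grp))
  lse <- log(ssum) + gmax
  g_self <- g[pairs$self]
  loss <- mean(lse - g_self)
  dg <- e / ssum[pairs$pair_grp] / n_ev
  dg[pairs$self] <- dg[pairs$self] - 1 / n_ev
  list(loss = loss, dg = dg)
}

#' Sampled-risk-set time-dependent Cox partial likelihood
#'
#' For every event i the loss accumulates
#' `log sum_{j in R_i} exp(g(t_i, x_j) - g(t_i, x_i))`, averaged over events,
#' where the comparison set `R_i` always contains i itself plus
#' `sampled_controls` members drawn uniformly from the risk set
#' `{j : t_j >= t_i}` (ties included, right-continuous convention), or the
#' full risk set when `sampled_controls = NULL`. The self term contributes
#' `exp(0) = 1`, so the loss is non-negative, and adding any constant to `g`
#' leaves it exactly unchanged. No baseline hazard is needed during training;
#' the Breslow step comes afterwards.
#'
#' @param model A `risk_model`.
#' @param data A preprocessed `survival_dataset` containing at least one
#'   event; risk sets are formed within it.
#' @param sampled_controls Number of sampled comparators per event, or `NULL`
#'   for the exact full-risk-set loss.
#' @param seed Seed for control sampling (ignored when `sampled_controls`
#'   is `NULL`).
#' @return A single non-negative number.
#' @export
partial_likelihood_loss <- function(model, data, sampled_controls = NULL,
                                    seed = 1) {
  if (is.null(sampled_controls)) return(exact_pll(model, data))
  pairs <- withr::with_seed(seed, build_pairs(data, sampled_controls))
  g <- model_pairs_forward(model, data, pairs, keep_cache = FALSE)$g
  loss_from_g(g, pairs)$loss
}

# Exact full-risk-set loss, evaluated event-block by event-block so the
# (event, at-risk subject) pair matrix never exceeds ~`chunk` rows.
exact_pll <- function(model, data, chunk = 5e4) {
  ev <- which(data$d == 1L)
  if (!length(ev)) abort("no events in batch: partial likelihood undefined")
  if (model$type == "linear") {
    r <- as.vector(linear_design(model, data) %*% model$params$beta)
    terms <- vapply(ev, function(i) {
      rs <- data$t >= data$t[i]
      m <- max(r[rs])
      log(sum(exp(r[rs] - m))) + m - r[i]
    }, numeric(1))
    return(mean(terms))
  }
  enc <- encode_covariates(model, data)
  fh <- fast_head_prepare(enc$Z, model$params$head)
  ord <- order(data$t)
  t_sorted <- data$t[ord]
  # at-risk set of event i is a suffix of the time-ordered subjects
  first_at_risk <- findInterval(data$t[ev] - 1e-12, t_sorted) + 1L
  sizes <- data$n - first_at_risk + 1L
  total <- 0
  k <- 1L
  while (k <= length(ev)) {
    kk <- k
    acc <- 0
    while (kk <= length(ev) && (acc + sizes[kk] <= chunk || kk == k)) {
      acc <- acc + sizes[kk]
      kk <- kk + 1L
    }
    block <- k:(kk - 1L)
    pair_j <- unlist(purrr::map(block, function(b) {
      ord[first_at_risk[b]:data$n]
    }))
    pair_grp <- rep.int(seq_along(block), sizes[block])
    ts <- scale_time(model, data$t[ev[block]])[pair_grp]
    g <- fast_head_g(fh, pair_j, ts)
    gmax <- vapply(split(g, pair_grp), max, numeric(1))
    e <- exp(g - gmax[pair_grp])
    lse <- log(as.vector(rowsum(e, pair_grp))) + gmax
    g_self <- vapply(seq_along(block), function(b) {
      forwarded <- which(pair_grp == b & pair_j == ev[block[b]])
      g[forwarded[1]]
    }, numeric(1))
    total <- total + sum(lse - g_self)
    k <- kk
  }
  total / length(ev)
}

model_pairs_forward <- function(model, data, pairs, keep_cache = FALSE) {
  if (model$type == "linear") {
    X <- linear_design(model, data)
    r <- as.vector(X %*% model$params$beta)
    return(list(g = r[pairs$pair_j], X = X))
  }
  enc <- encode_covariates(model, data, keep_cache = keep_cache)
  ts <- scale_time(model, data$t[pairs$pair_i])
  pg <- pairs_g(model, enc, ts, pairs$pair_j, keep_cache = keep_cache)
  list(g = pg$g, enc = enc, hf = pg$hf)
}

# Loss + parameter gradients (same tree shape as model$params).
loss_and_grad <- function(model, data, pairs) {
  fw <- model_pairs_forward(model, data, pairs, keep_cache = TRUE)
  lf <- loss_from_g(fw$g, pairs)
  if (model$type == "linear") {
    dbeta <- as.vector(crossprod(fw$X[pairs$pair_j, , drop = FALSE], lf$dg))
    return(list(loss = lf$loss, grads = list(beta = dbeta)))
  }
  hb <- head_bwd(lf$dg, fw$hf, model$params$head)
  zdim <- ncol(fw$enc$Z)
  dZpairs <- hb$dU[, seq_len(zdim), drop = FALSE]
  dZ <- matrix(0, data$n, zdim)
  agg <- rowsum(dZpairs, pairs$pair_j)
  dZ[as.integer(rownames(agg)), ] <- agg
  d <- model$config$d_embed
  B <- fw$enc$B
  m <- fw$enc$eb$m
  dTok <- matrix(0, m * B, d)
  for (i in seq_len(model$N)) {
    dTok[tok_rows(i, B), ] <- dZ[, ((i - 1) * d + 1):(i * d), drop = FALSE]
  }
  eb <- encoder_bwd(dTok, fw$enc$ef, model$params$enc, model$config, B, m)
  demb <- embed_batch_bwd(eb$dX, fw$enc$eb, model$params$emb,
                          model$config$t_tokens)
  list(loss = lf$loss,
       grads = list(emb = demb, enc = eb$grads, head = hb$grads))
}
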