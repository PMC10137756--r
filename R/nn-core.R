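# Hand-rolled reverse-mode engine for the specific architecture used here.
# Tokens for a batch of B samples and m sequence positions are stored
# token-major: an (m*B) x d matrix whose rows ((i-1)*B+1):(i*B) hold token i
# for every sample. Token slices are then contiguous row ranges and all the
# heavy lifting happens in BLAS matmuls vectorized over the batch.

tok_rows <- function(i, B) ((i - 1L) * B + 1L):(i * B)

addb <- function(M, b) sweep(M, 2, b, "+")

xavier <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

#' Transformer encoder configuration
#'
#' Hyperparameters of the categorical branch. The key/query dimension per
#' head is `d_embed / n_heads` (concatenated-heads convention); head outputs
#' are concatenated and linearly projected back to `d_embed`. Defaults are
#' sized for CPU training on cohorts of a few hundred to a few thousand
#' patients.
#'
#' @param d_embed Embedding dimension of every token.
#' @param n_layers Number of encoder layers; 0 gives the identity encoder.
#' @param n_heads Attention heads; must divide `d_embed`.
#' @param mlp_hidden Hidden width of the per-layer MLP.
#' @param t_tokens Number of special tokens appended to the feature tokens.
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(d_embed = 32, n_layers = 2, n_heads = 4,
                           mlp_hidden = 64, t_tokens = 1) {
  stopifnot(d_embed >= 1, n_layers >= 0, n_heads >= 1, mlp_hidden >= 1,
            t_tokens >= 0)
  if (d_embed %% n_heads != 0) abort("d_embed must be divisible by n_heads")
  structure(list(d_embed = d_embed, n_layers = n_layers, n_heads = n_heads,
                 mlp_hidden = mlp_hidden, t_tokens = t_tokens),
            class = "encoder_config")
}

#' Column-embedding table for categorical covariates
#'
#' One learned `d_embed`-vector per (feature, level) pair — `sum(c_i)` in
#' total — plus `t_tokens` special-token vectors and one column-identifier
#' vector per categorical feature. The column identifier is added to each
#' feature's level vectors so that the same code in different columns embeds
#' differently; it plays the role positional encoding plays in sequence
#' transformers. The total learned-vector count is `sum(c_i) + t + N`.
#'
#' @param schema A [feature_schema()].
#' @param d_embed Embedding dimension.
#' @param t_tokens Number of special tokens.
#' @param seed Seed for the random initialization.
#' @return A `column_embedding_table`: list with matrices `levels`
#'   (`sum(c_i) x d`), `cols` (`N x d`), `special` (`t x d`) and the integer
#'   `offsets` locating each feature's level block.
#' @export
column_embedding_table <- function(schema, d_embed = 32, t_tokens = 1,
                                   seed = 1) {
  card <- schema_cardinalities(schema)
  N <- length(card)
  withr::with_seed(seed, {
    tab <- list(
      levels = matrix(rnorm(sum(card) * d_embed, sd = 0.1), sum(card), d_embed),
      cols = matrix(rnorm(N * d_embed, sd = 0.1), N, d_embed),
      special = matrix(rnorm(max(1, t_tokens) * d_embed, sd = 0.1),
                       t_tokens, d_embed)[seq_len(t_tokens), , drop = FALSE]
    )
    tab$offsets <- c(0L, cumsum(card))[seq_len(N)]
    tab$cardinalities <- card
    tab$d_embed <- d_embed
    class(tab) <- "column_embedding_table"
    tab
  })
}

#' Embed one row of categorical codes
#'
#' Returns the `N` token vectors for a single patient: the level vector of
#' each feature's observed code plus that feature's column identifier. Two
#' features holding the same code therefore produce different tokens.
#'
#' @param codes Integer vector of `N` level codes (0-based, schema order).
#' @param table A [column_embedding_table()].
#' @return An `N x d_embed` matrix, one token per row.
#' @export
embed_categorical <- function(codes, table) {
  N <- length(table$cardinalities)
  if (length(codes) != N) abort("expected one code per categorical feature")
  if (any(codes < 0) || any(codes >= table$cardinalities)) {
    bad <- which(codes < 0 | codes >= table$cardinalities)[1]
    abort(paste0("code out of range for feature ",
                 names(table$cardinalities)[bad]))
  }
  table$levels[table$offsets + codes + 1L, , drop = FALSE] + table$cols
}

# Batched embedding: x_cat is B x N (0-based codes). Output token-major
# (m*B) x d with m = N + t_tokens; special tokens occupy the trailing slots.
# `emb` holds only the learned matrices (levels/cols/special); `offsets`
# locates each feature's level block inside `emb$levels`.
embed_batch <- function(x_cat, emb, offsets, t_tokens) {
  B <- nrow(x_cat)
  N <- ncol(x_cat)
  d <- ncol(emb$levels)
  m <- N + t_tokens
  X <- matrix(0, m * B, d)
  idx <- integer(N * B)
  for (i in seq_len(N)) {
    ii <- offsets[i] + x_cat[, i] + 1L
    idx[tok_rows(i, B)] <- ii
    X[tok_rows(i, B), ] <- emb$levels[ii, , drop = FALSE] +
      rep(1, B) %o% emb$cols[i, ]
  }
  if (t_tokens > 0) {
    for (s in seq_len(t_tokens)) {
      X[tok_rows(N + s, B), ] <- rep(1, B) %o% emb$special[s, ]
    }
  }
  list(X = X, idx = idx, B = B, m = m, N = N)
}

embed_batch_bwd <- function(dX, ecache, emb, t_tokens) {
  B <- ecache$B; N <- ecache$N
  dlev <- matrix(0, nrow(emb$levels), ncol(emb$levels))
  feat_rows <- seq_len(N * B)
  agg <- rowsum(dX[feat_rows, , drop = FALSE], group = ecache$idx)
  dlev[as.integer(rownames(agg)), ] <- agg
  dcols <- do.call(rbind, purrr::map(seq_len(N), function(i) {
    colSums(dX[tok_rows(i, B), , drop = FALSE])
  }))
  dspec <- matrix(0, t_tokens, ncol(dX))
  if (t_tokens > 0) {
    for (s in seq_len(t_tokens)) {
      dspec[s, ] <- colSums(dX[tok_rows(N + s, B), , drop = FALSE])
    }
  }
  list(levels = dlev, cols = dcols, special = dspec)
}

# ---- layer normalization over the feature dimension -------------------------

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(Y = addb(sweep(xhat, 2, g, "*"), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  h1 <- rowMeans(dxhat)
  h2 <- rowMeans(dxhat * cache$xhat)
  list(dX = (dxhat - h1 - cache$xhat * h2) * cache$inv,
       dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# ---- multi-head self-attention ----------------------------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(k)) V` for a single token sequence: the attention
#' weight of query row i on key row j is `exp(Q_i . K_j / sqrt(k))`
#' normalized over j, and the output row i is the weight-averaged value rows.
#' Every weight row is a probability vector.
#'
#' @param Q,K Query and key matrices, `m x k`.
#' @param V Value matrix, `m x v`.
#' @return An `m x v` matrix.
#' @export
attention <- function(Q, K, V) {
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V)) {
    abort("Q, K, V must have equal row counts")
  }
  if (ncol(Q) != ncol(K)) abort("Q and K must have equal column counts")
  S <- tcrossprod(Q, K) / sqrt(ncol(K))
  S <- S - apply(S, 1, max)
  W <- exp(S) / rowSums(exp(S))
  W %*% V
}

attention_weights <- function(Q, K) {
  S <- tcrossprod(Q, K) / sqrt(ncol(K))
  S <- S - apply(S, 1, max)
  exp(S) / rowSums(exp(S))
}

# Attention probabilities are stored per (head, query token) as B x m
# matrices (lists, not 3D arrays: array slicing would aperm-copy in the hot
# loop). All loops run over token pairs (m <= ~10); everything inside is
# vectorized over the batch.
mha_fwd <- function(X, prm, cfg, B, m) {
  d <- cfg$d_embed; Hn <- cfg$n_heads; kh <- d %/% Hn
  Q <- addb(X %*% prm$Wq, prm$bq)
  K <- addb(X %*% prm$Wk, prm$bk)
  V <- addb(X %*% prm$Wv, prm$bv)
  O <- matrix(0, m * B, d)
  Plist <- vector("list", Hn)
  sc <- 1 / sqrt(kh)
  for (h in seq_len(Hn)) {
    cols <- ((h - 1L) * kh + 1L):(h * kh)
    Qs <- purrr::map(seq_len(m), ~ Q[tok_rows(.x, B), cols, drop = FALSE])
    Ks <- purrr::map(seq_len(m), ~ K[tok_rows(.x, B), cols, drop = FALSE])
    Vs <- purrr::map(seq_len(m), ~ V[tok_rows(.x, B), cols, drop = FALSE])
    P <- vector("list", m)
    for (i in seq_len(m)) {
      Qi <- Qs[[i]]
      S <- matrix(0, B, m)
      for (j in seq_len(m)) S[, j] <- rowSums(Qi * Ks[[j]]) * sc
      mx <- S[, 1]
      for (j in seq_len(m)[-1]) mx <- pmax(mx, S[, j])
      E <- exp(S - mx)
      P[[i]] <- E / rowSums(E)
    }
    for (i in seq_len(m)) {
      acc <- P[[i]][, 1] * Vs[[1]]
      for (j in seq_len(m)[-1]) acc <- acc + P[[i]][, j] * Vs[[j]]
      O[tok_rows(i, B), cols] <- acc
    }
    Plist[[h]] <- P
  }
  out <- addb(O %*% prm$Wo, prm$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, Plist = Plist)
}

mha_bwd <- function(dout, X, cache, prm, cfg, B, m) {
  d <- cfg$d_embed; Hn <- cfg$n_heads; kh <- d %/% Hn
  sc <- 1 / sqrt(kh)
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- tcrossprod(dout, prm$Wo)
  dQ <- matrix(0, m * B, d); dK <- dQ; dV <- dQ
  for (h in seq_len(Hn)) {
    cols <- ((h - 1L) * kh + 1L):(h * kh)
    Qs <- purrr::map(seq_len(m),
                     ~ cache$Q[tok_rows(.x, B), cols, drop = FALSE])
    Ks <- purrr::map(seq_len(m),
                     ~ cache$K[tok_rows(.x, B), cols, drop = FALSE])
    Vs <- purrr::map(seq_len(m),
                     ~ cache$V[tok_rows(.x, B), cols, drop = FALSE])
    dOs <- purrr::map(seq_len(m), ~ dO[tok_rows(.x, B), cols, drop = FALSE])
    P <- cache$Plist[[h]]
    dVs <- purrr::map(seq_len(m), ~ matrix(0, B, kh))
    dKs <- purrr::map(seq_len(m), ~ matrix(0, B, kh))
    for (i in seq_len(m)) {
      dOi <- dOs[[i]]
      Pi <- P[[i]]
      dPi <- matrix(0, B, m)
      for (j in seq_len(m)) {
        dPi[, j] <- rowSums(dOi * Vs[[j]])
        dVs[[j]] <- dVs[[j]] + Pi[, j] * dOi
      }
      dSi <- Pi * (dPi - rowSums(dPi * Pi))
      acc_q <- dSi[, 1] * Ks[[1]]
      for (j in seq_len(m)[-1]) acc_q <- acc_q + dSi[, j] * Ks[[j]]
      dQ[tok_rows(i, B), cols] <- acc_q * sc
      Qi <- Qs[[i]]
      for (j in seq_len(m)) dKs[[j]] <- dKs[[j]] + dSi[, j] * Qi
    }
    for (j in seq_len(m)) {
      jr <- tok_rows(j, B)
      dV[jr, cols] <- dVs[[j]]
      dK[jr, cols] <- dKs[[j]] * sc
    }
  }
  list(
    dX = dQ %*% t(prm$Wq) + dK %*% t(prm$Wk) + dV %*% t(prm$Wv),
    Wq = crossprod(X, dQ), bq = colSums(dQ),
    Wk = crossprod(X, dK), bk = colSums(dK),
    Wv = crossprod(X, dV), bv = colSums(dV),
    Wo = dWo, bo = dbo
  )
}

# ---- encoder stack (post-norm: residual then LayerNorm) ---------------------

init_encoder_params <- function(cfg, seed) {
  d <- cfg$d_embed; mh <- cfg$mlp_hidden
  withr::with_seed(seed, {
    purrr::map(seq_len(cfg$n_layers), function(l) {
      list(
        Wq = xavier(d, d), bq = numeric(d),
        Wk = xavier(d, d), bk = numeric(d),
        Wv = xavier(d, d), bv = numeric(d),
        Wo = xavier(d, d), bo = numeric(d),
        g1 = rep(1, d), b1 = numeric(d),
        W1 = xavier(d, mh), b1m = numeric(mh),
        W2 = xavier(mh, d), b2m = numeric(d),
        g2 = rep(1, d), b2 = numeric(d)
      )
    })
  })
}

encoder_fwd <- function(X, enc_params, cfg, B, m, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(enc_params)) else NULL
  for (l in seq_along(enc_params)) {
    prm <- enc_params[[l]]
    att <- mha_fwd(X, prm, cfg, B, m)
    R1 <- X + att$out
    l1 <- ln_fwd(R1, prm$g1, prm$b1)
    X1 <- l1$Y
    A1 <- addb(X1 %*% prm$W1, prm$b1m)
    Hh <- pmax(A1, 0)
    A2 <- addb(Hh %*% prm$W2, prm$b2m)
    R2 <- X1 + A2
    l2 <- ln_fwd(R2, prm$g2, prm$b2)
    if (keep_cache) {
      caches[[l]] <- list(X = X, att = att, l1 = l1, X1 = X1, A1 = A1,
                          Hh = Hh, l2 = l2)
    }
    X <- l2$Y
  }
  list(out = X, caches = caches)
}

encoder_bwd <- function(dX2, fwd, enc_params, cfg, B, m) {
  grads <- vector("list", length(enc_params))
  for (l in rev(seq_along(enc_params))) {
    prm <- enc_params[[l]]
    cc <- fwd$caches[[l]]
    b2 <- ln_bwd(dX2, cc$l2, prm$g2)
    dR2 <- b2$dX
    dA2 <- dR2
    dX1 <- dR2
    dHh <- dA2 %*% t(prm$W2)
    dW2 <- crossprod(cc$Hh, dA2); db2m <- colSums(dA2)
    dA1 <- dHh * (cc$A1 > 0)
    dW1 <- crossprod(cc$X1, dA1); db1m <- colSums(dA1)
    dX1 <- dX1 + dA1 %*% t(prm$W1)
    b1 <- ln_bwd(dX1, cc$l1, prm$g1)
    dR1 <- b1$dX
    mb <- mha_bwd(dR1, cc$X, cc$att, prm, cfg, B, m)
    grads[[l]] <- list(
      Wq = mb$Wq, bq = mb$bq, Wk = mb$Wk, bk = mb$bk,
      Wv = mb$Wv, bv = mb$bv, Wo = mb$Wo, bo = mb$bo,
      g1 = b1$dg, b1 = b1$db,
      W1 = dW1, b1m = db1m, W2 = dW2, b2m = db2m,
      g2 = b2$dg, b2 = b2$db
    )
    dX2 <- dR1 + mb$dX
  }
  list(dX = dX2, grads = grads)
}

#' Run a token sequence through the transformer encoder
#'
#' Each layer applies multi-head self-attention with a residual connection
#' followed by layer normalization, then a two-layer ReLU MLP with a residual
#' connection and a second layer normalization (post-norm order). There is no
#' positional encoding: the encoder is permutation-equivariant over token
#' positions, and column identity is carried by the embeddings themselves.
#'
#' @param tokens An `m x d_embed` matrix, one token per row (`m >= 1`).
#' @param config An [encoder_config()].
#' @param params Encoder parameters; defaults to a fresh seeded
#'   initialization.
#' @param seed Seed used when `params` is `NULL`.
#' @return An `m x d_embed` matrix of context-aware tokens.
#' @export
encoder_forward <- function(tokens, config, params = NULL, seed = 1) {
  if (is.null(dim(tokens)) || nrow(tokens) == 0) {
    abort("token sequence must be a non-empty matrix")
  }
  if (ncol(tokens) != config$d_embed) abort("token dimension must equal d_embed")
  if (is.null(params)) params <- init_encoder_params(config, seed)
  encoder_fwd(tokens, params, config, B = 1L, m = nrow(tokens),
              keep_cache = FALSE)$out
}

# ---- residual dense head ----------------------------------------------------

init_head_params <- function(p_in, width, seed) {
  withr::with_seed(seed, {
    list(
      W1 = xavier(p_in, width), b1 = numeric(width),
      W2 = xavier(width, width), b2 = numeric(width),
      P = xavier(p_in, width),
      wout = matrix(rnorm(width, sd = 0.01), width, 1), bout = 0
    )
  })
}

head_fwd <- function(U, hp, keep_cache = TRUE) {
  A1 <- addb(U %*% hp$W1, hp$b1)
  H1 <- pmax(A1, 0)
  A2 <- addb(H1 %*% hp$W2, hp$b2)
  H2 <- pmax(A2, 0)
  BO <- H2 + U %*% hp$P
  g <- as.vector(BO %*% hp$wout) + hp$bout
  if (!keep_cache) return(list(g = g))
  list(g = g, U = U, A1 = A1, H1 = H1, A2 = A2, BO = BO)
}

head_bwd <- function(dg, cc, hp) {
  dBO <- tcrossprod(dg, hp$wout[, 1])
  dwout <- crossprod(cc$BO, dg)
  dbout <- sum(dg)
  dA2 <- dBO * (cc$A2 > 0)
  dW2 <- crossprod(cc$H1, dA2); db2 <- colSums(dA2)
  dH1 <- dA2 %*% t(hp$W2)
  dA1 <- dH1 * (cc$A1 > 0)
  dW1 <- crossprod(cc$U, dA1); db1 <- colSums(dA1)
  dU <- dA1 %*% t(hp$W1) + dBO %*% t(hp$P)
  dP <- crossprod(cc$U, dBO)
  list(dU = dU,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, P = dP,
                    wout = dwout, bout = dbout))
}

# Forward-only factored head: for pair evaluation g(t_i, x_j) the input
# [Z_j, t_i] never needs materializing — Z %*% W1 and Z %*% P are computed
# once per parameter state, and each pair adds only a rank-1 time term.
fast_head_prepare <- function(Z, hp) {
  zd <- ncol(Z)
  list(
    ZW1 = Z %*% hp$W1[seq_len(zd), , drop = FALSE],
    ZP = Z %*% hp$P[seq_len(zd), , drop = FALSE],
    T1 = rbind(hp$W1[zd + 1L, ], hp$b1),
    T2 = rbind(numeric(ncol(hp$W2)), hp$b2),
    TP = rbind(hp$P[zd + 1L, ], numeric(ncol(hp$P))),
    hp = hp
  )
}

fast_head_g <- function(fh, pair_j, ts) {
  TS <- cbind(ts, 1)
  A1 <- fh$ZW1[pair_j, , drop = FALSE] + TS %*% fh$T1
  H1 <- pmax(A1, 0)
  H2 <- pmax(H1 %*% fh$hp$W2 + TS %*% fh$T2, 0)
  BO <- H2 + fh$ZP[pair_j, , drop = FALSE] + TS %*% fh$TP
  as.vector(BO %*% fh$hp$wout) + fh$hp$bout
}

# ---- flat-vector Adam -------------------------------------------------------

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}
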