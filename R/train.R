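#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Patients per mini-batch.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without validation-loss improvement. Must be smaller
#'   than `max_epochs`.
#' @param sampled_controls Comparators sampled per event during training
#'   steps; validation loss always uses full risk sets so model selection is
#'   deterministic.
#' @param lr_decay Multiplicative learning-rate decay applied after
#'   `lr_patience` consecutive epochs without validation improvement
#'   (set to 1 to disable).
#' @param lr_patience Epochs without improvement before one decay step.
#' @param seed Seed governing shuffling, control sampling and initialization
#'   during training.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 256,
                            max_epochs = 100, patience = 10,
                            sampled_controls = 4, lr_decay = 0.5,
                            lr_patience = 3, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1,
            patience >= 1, patience < max_epochs, sampled_controls >= 1,
            lr_decay > 0, lr_decay <= 1, lr_patience >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 sampled_controls = sampled_controls, lr_decay = lr_decay,
                 lr_patience = lr_patience, seed = seed),
            class = "training_config")
}

#' Train a risk model by sampled-risk-set partial likelihood
#'
#' Mini-batch Adam on [partial_likelihood_loss()]: each epoch shuffles the
#' training set into batches and, within every batch, anchors one loss term
#' per event with `sampled_controls` comparators drawn from the within-batch
#' risk set. After each epoch the exact full-risk-set loss on `valid` is
#' computed; the returned model carries the parameters of the epoch with the
#' lowest validation loss ("best weights"). Training stops after `patience`
#' epochs without improvement or at `max_epochs`. The run is fully
#' reproducible given `config$seed`.
#'
#' The time input to `g` is standardized by the mean and standard deviation
#' of the training event times, fixed here and reused at prediction time.
#'
#' @param model An untrained (or warm) `risk_model`.
#' @param train Preprocessed training `survival_dataset` (>= 1 event).
#' @param valid Preprocessed validation `survival_dataset` (>= 1 event).
#' @param config A [training_config()].
#' @return The model with trained parameters plus fields `history` (tibble of
#'   per-epoch train/validation losses) and `best_epoch`.
#' @export
train <- function(model, train, valid, config = training_config()) {
  if (!sum(train$d) || !sum(valid$d)) {
    abort("both training and validation sets must contain events")
  }
  model <- set_time_scale(model, train)
  theta <- unlist(model$params)
  skel <- model$params
  st <- adam_init(theta)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  hist <- list()
  bad <- 0L
  lr <- config$learning_rate
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(train$n)
      nb <- max(1L, floor(train$n / config$batch_size))
      batch_of <- rep_len(seq_len(nb), train$n)
      ep_losses <- c()
      for (b in seq_len(nb)) {
        idx <- ord[batch_of == b]
        bd <- dataset_subset(train, idx)
        if (!sum(bd$d)) next
        pairs <- build_pairs(bd, config$sampled_controls)
        model$params <- utils::relist(theta, skel)
        lg <- loss_and_grad(model, bd, pairs)
        if (!is.finite(lg$loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        upd <- adam_step(theta, unlist(lg$grads), st, lr)
        theta <- upd$theta
        st <- upd$state
        ep_losses <- c(ep_losses, lg$loss)
      }
      model$params <- utils::relist(theta, skel)
      vloss <- exact_pll(model, valid)
      if (!is.finite(vloss)) {
        abort(paste0("training diverged (non-finite validation loss) at epoch ",
                     epoch))
      }
      hist[[epoch]] <- tibble(epoch = epoch,
                              train_loss = mean(ep_losses),
                              valid_loss = vloss, learning_rate = lr)
      if (vloss < best$loss - 1e-12) {
        best <- list(loss = vloss, theta = theta, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
        if (config$lr_decay < 1 && bad %% config$lr_patience == 0) {
          lr <- lr * config$lr_decay
        }
      }
    }
  })
  model$params <- utils::relist(best$theta, skel)
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_valid_loss <- best$loss
  model$trained <- TRUE
  model
}

set_time_scale <- function(model, train) {
  if (model$type == "linear") {
    # the linear baseline is time-free; center/scale its design instead
    X <- cbind(train$x_cont, train$x_cat)
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl <= 0] <- 1
    model$code_center <- setNames(ctr, names(model$params$beta))
    model$code_scale <- setNames(scl, names(model$params$beta))
    return(model)
  }
  et <- train$t[train$d == 1L]
  model$time_mu <- mean(et)
  model$time_sd <- if (length(et) > 1 && stats::sd(et) > 0) stats::sd(et) else 1
  model
}

#' Train the linear sanity baseline
#'
#' Fits [linear_risk_model()] — `g(t, x) = beta' x`, no transformer, no time
#' input — with the same loss machinery and early-stopping protocol as
#' [train()]. It stands in for a classical linear Cox fit in model
#' comparisons.
#'
#' @inheritParams train
#' @param schema Schema of the (preprocessed) data; defaults to `train`'s.
#' @return A trained `linear_risk_model` with `history` and coefficients
#'   accessible via [tidy()].
#' @export
linear_baseline <- function(train, valid, config = training_config(),
                            schema = NULL) {
  sch <- schema %||% train$schema
  model <- linear_risk_model(sch, seed = config$seed)
  ttsurv::train(model, train, valid, config)
}

#' Coefficients of a linear risk model on the raw code scale
#'
#' Rescales the internally standardized coefficients back to one unit of the
#' original covariate (one year, one ordinal step, ...), the scale on which
#' simulator effect sizes are declared.
#'
#' @param model A trained `linear_risk_model`.
#' @return Named numeric vector.
#' @export
linear_coefficients <- function(model) {
  model$params$beta / model$code_scale
}
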