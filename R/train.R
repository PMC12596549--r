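# Training loop -------------------------------------------------------------

#' Run configuration
#'
#' Defaults follow the tuned configuration used throughout the package:
#' 128 LSTM units, learning rate 0.001, batch size 32, 100 epochs, Adam,
#' sigmoid final activation.
#'
#' @param lstm_units Hidden units per LSTM direction (64/128/256 are the
#'   grid values; any positive integer is accepted).
#' @param learning_rate Optimizer step size.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (0 returns the initialization unchanged).
#' @param optimizer One of `"adam"`, `"rmsprop"`, `"sgd"`.
#' @param lr_decay Multiplicative per-epoch learning-rate decay in (0, 1];
#'   1 (default) keeps the rate constant.
#' @param weight_decay Decoupled L2 weight decay applied to the weight
#'   matrices (never the biases) at each update; 0 disables it.
#' @param lambda Residual influence coefficient in \\[0, 1\\] (fixed, not
#'   trained).
#' @param seed Integer seed driving initialization and shuffling.
#' @param k Cross-validation fold count.
#' @param fairness_reweighting Use inverse-frequency demographic weights in
#'   the loss.
#' @param transfer_checkpoint Path to a pretraining checkpoint, or `NULL`
#'   for fresh initialization.
#' @param residual_attention Enable the residual-attention track.
#' @param pool `"last"` or `"mean"` summary fed to the output head.
#' @return A `run_config` list.
#' @export
run_config <- function(lstm_units = 128L, learning_rate = 0.001,
                       batch_size = 32L, epochs = 100L,
                       optimizer = c("adam", "rmsprop", "sgd"),
                       lr_decay = 1, weight_decay = 0,
                       lambda = 0.5, seed = 1L, k = 10L,
                       fairness_reweighting = TRUE,
                       transfer_checkpoint = NULL,
                       residual_attention = TRUE,
                       pool = c("last", "mean")) {
  optimizer <- match.arg(optimizer)
  pool <- match.arg(pool)
  stopifnot(lstm_units >= 1, learning_rate > 0, batch_size >= 1,
            epochs >= 0, lambda >= 0, lambda <= 1, k >= 2,
            lr_decay > 0, lr_decay <= 1, weight_decay >= 0)
  cfg <- list(lstm_units = as.integer(lstm_units),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), optimizer = optimizer,
              lr_decay = lr_decay, weight_decay = weight_decay,
              lambda = lambda, seed = as.integer(seed), k = as.integer(k),
              fairness_reweighting = fairness_reweighting,
              transfer_checkpoint = transfer_checkpoint,
              residual_attention = residual_attention, pool = pool)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: H=%d lr=%g batch=%d epochs=%d %s lambda=%.2f k=%d\n",
    x$lstm_units, x$learning_rate, x$batch_size, x$epochs, x$optimizer,
    x$lambda, x$k))
  cat(sprintf("  reweighting=%s transfer=%s residual_attention=%s pool=%s\n",
              x$fairness_reweighting,
              if (is.null(x$transfer_checkpoint)) "none" else x$transfer_checkpoint,
              x$residual_attention, x$pool))
  invisible(x)
}

# first-order optimizers with state kept in a closure
make_optimizer <- function(name, lr, par) {
  zeros <- lapply(par, function(p) p * 0)
  env <- new.env(parent = emptyenv())
  env$m <- zeros; env$v <- zeros; env$t <- 0L; env$lr <- lr
  if (name == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(par, grads) {
      env$t <- env$t + 1L
      for (nm in names(par)) {
        env$m[[nm]] <- b1 * env$m[[nm]] + (1 - b1) * grads[[nm]]
        env$v[[nm]] <- b2 * env$v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- env$m[[nm]] / (1 - b1^env$t)
        vhat <- env$v[[nm]] / (1 - b2^env$t)
        par[[nm]] <- par[[nm]] - env$lr * mhat / (sqrt(vhat) + eps)
      }
      par
    }
  } else if (name == "rmsprop") {
    rho <- 0.9; eps <- 1e-8
    function(par, grads) {
      for (nm in names(par)) {
        env$v[[nm]] <- rho * env$v[[nm]] + (1 - rho) * grads[[nm]]^2
        par[[nm]] <- par[[nm]] - env$lr * grads[[nm]] / (sqrt(env$v[[nm]]) + eps)
      }
      par
    }
  } else {
    function(par, grads) {
      for (nm in names(par)) par[[nm]] <- par[[nm]] - env$lr * grads[[nm]]
      par
    }
  }
}

#' Train the model on an encoded partition
#'
#' Minibatch gradient training of the full reweighted binary cross-entropy
#' for `config$epochs` epochs with seeded shuffling. Gradients are exact
#' backpropagation through time; the per-epoch loss trace is the
#' sample-size-weighted mean per-record loss over minibatches.
#'
#' @param encoded An `encoded_matrix` of the (imputed, scaled) training
#'   partition, carrying its `y`.
#' @param config A [run_config()].
#' @param weights Per-sample loss weights: a numeric vector, a
#'   `group_weight_table` (requires `groups`), or `NULL` for uniform.
#' @param groups Per-record demographic keys, needed when `weights` is a
#'   `group_weight_table`.
#' @param init Optional initial `model_state` (e.g. from
#'   [transfer_init()]); default is a fresh seeded initialization.
#' @param clip_norm Global gradient-norm clip (standard recurrent-network
#'   safeguard); `Inf` disables clipping.
#' @param n_starts Number of independent restarts (seeds derived from
#'   `config$seed`); the run with the lowest final-epoch training loss is
#'   returned. Restarts are the usual remedy for the occasional bad basin
#'   of non-convex recurrent fitting; selection sees only the training
#'   loss.
#' @return List with `model` (the trained `model_state`), `loss_trace`
#'   (numeric, one mean loss per epoch) and `start_seed` (the restart that
#'   won).
#' @export
train_model <- function(encoded, config = run_config(), weights = NULL,
                        groups = NULL, init = NULL, clip_norm = 5,
                        n_starts = 1L) {
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts), function(r) {
      cfg <- config
      cfg$seed <- (config$seed + 7717L * (r - 1L)) %% .Machine$integer.max
      train_model(encoded, cfg, weights = weights, groups = groups,
                  init = init, clip_norm = clip_norm, n_starts = 1L)
    })
    final <- vapply(fits, function(f)
      if (length(f$loss_trace)) utils::tail(f$loss_trace, 1) else Inf,
      numeric(1))
    return(fits[[which.min(final)]])
  }
  X <- encoded$values
  y <- encoded$y
  n <- nrow(X)
  if (is.null(y) || length(y) != n) stop("encoded matrix must carry labels")
  if (inherits(weights, "group_weight_table")) {
    if (is.null(groups)) stop("group weights need per-record group keys")
    weights <- sample_weights(weights, groups)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("one weight per record required")

  model <- if (is.null(init)) {
    new_model(d = ncol(X), lstm_units = config$lstm_units,
              lambda = config$lambda,
              residual_attention = config$residual_attention,
              pool = config$pool, seed = config$seed,
              feature_names = colnames(X))
  } else init
  if (model$meta$T != ncol(X)) stop("model/input width mismatch")

  if (config$epochs == 0L)
    return(list(model = model, loss_trace = numeric(0)))

  step <- make_optimizer(config$optimizer, config$learning_rate, model$par)
  decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  wd <- if (is.null(config$weight_decay)) 0 else config$weight_decay
  wd_params <- setdiff(names(model$par), c("bf", "bb", "bm", "bo"))
  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    environment(step)$env$lr <- config$learning_rate * decay^(epoch - 1)
    ord <- with_seed((config$seed + 7919 * epoch) %% .Machine$integer.max,
                     sample(n))
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      nb <- length(idx)
      fwd <- model_forward_impl(model, X[idx, , drop = FALSE], keep = TRUE)
      loss <- reweighted_bce(y[idx], fwd$yhat, weights[idx])
      if (!is.finite(loss))
        stop("non-finite loss encountered; consider a smaller learning rate")
      ep_loss <- ep_loss + loss
      dlogit <- weights[idx] * (fwd$yhat - y[idx]) / nb
      grads <- model_backward(model, fwd$cache, dlogit)
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(gnorm) && gnorm > clip_norm)
        grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
      model$par <- step(model$par, grads)
      if (wd > 0) {
        sh <- 1 - config$learning_rate * decay^(epoch - 1) * wd
        for (nm in wd_params) model$par[[nm]] <- model$par[[nm]] * sh
      }
    }
    loss_trace[epoch] <- ep_loss / n
  }
  list(model = model, loss_trace = loss_trace, start_seed = config$seed)
}

#' Pretrain a source-domain checkpoint
#'
#' Generates (or accepts) a source-domain corpus, trains the model on it
#' with uniform weights, and writes a transfer checkpoint.
#'
#' @param spec A [cohort_spec()] for the source corpus (default 3030
#'   records, ten times a typical target cohort).
#' @param shift Source-domain shift, see [pretrain_shift()].
#' @param config A [run_config()] for the pretraining run.
#' @param path Output checkpoint path (`.json`).
#' @param corpus Optional ready-made source `ihd_cohort` (overrides
#'   `spec`/`shift`).
#' @return The checkpoint path, invisibly; the trained source model as
#'   attribute `"model"`.
#' @export
pretrain_checkpoint <- function(spec = cohort_spec(n = 3030L, seed = 2024L),
                                shift = pretrain_shift(),
                                config = run_config(), path, corpus = NULL) {
  if (is.null(corpus)) corpus <- generate_pretrain_corpus(spec, shift)
  corpus <- fuzzy_impute(corpus, imputation_config(seed = config$seed))
  num <- uci_numeric_fields()
  sc <- fit_minmax(as.matrix(as.data.frame(corpus)[, num]))
  enc <- one_hot_encode(corpus, scaling = sc)
  fit <- train_model(enc, config)
  save_checkpoint(fit$model, path,
                  provenance = sprintf("synthetic source corpus n=%d seed=%d",
                                       nrow(corpus), spec$seed))
  out <- path
  attr(out, "model") <- fit$model
  invisible(out)
}
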