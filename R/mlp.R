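# Single shift-regressor members: seeded initialization, Adam training with
# optional early stopping, and warm-started continued training (fine-tuning).

#' Configuration of one shift-regressor member
#'
#' Hyperparameters for the fully connected regression networks that map a
#' per-residue embedding vector to a pKa shift (pH units). Defaults target
#' small-n tabular regression on wide embedding features: two hidden layers,
#' rectified-linear activation, Adam with minibatches, early stopping on a
#' 10% validation split. Fine-tuning continues optimization of pretrained
#' weights for `finetune_epochs` at `lr * finetune_lr_factor`.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (from-scratch and pretraining stages).
#' @param batch_size Minibatch size (capped at the number of training rows).
#' @param weight_decay L2 penalty coefficient on weights (not biases).
#' @param validation_fraction Fraction of rows held out for early stopping;
#'   0 disables the split.
#' @param patience Early-stopping patience in epochs; 0 disables early
#'   stopping and trains for the full epoch budget.
#' @param finetune_epochs Epochs for the fine-tuning stage (0 = no update).
#' @param finetune_lr_factor Learning-rate multiplier during fine-tuning.
#' @param bootstrap If `TRUE`, each ensemble member resamples its training
#'   rows with replacement; by default diversity comes from seed offsets
#'   (initialization + data order) only.
#' @return An object of class `pka_config`.
#' @export
regressor_config <- function(hidden = c(256, 64), activation = c("relu", "tanh"),
                             lr = 1e-3, epochs = 150, batch_size = 128,
                             weight_decay = 1e-4, validation_fraction = 0.1,
                             patience = 20, finetune_epochs = 100,
                             finetune_lr_factor = 0.1, bootstrap = FALSE) {
  activation <- match.arg(activation)
  stopifnot(all(hidden >= 1), lr > 0, epochs >= 1, batch_size >= 1,
            weight_decay >= 0, validation_fraction >= 0, validation_fraction < 1,
            patience >= 0, finetune_epochs >= 0, finetune_lr_factor > 0)
  structure(
    list(hidden = as.integer(hidden), activation = activation, lr = lr,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         weight_decay = weight_decay, validation_fraction = validation_fraction,
         patience = as.integer(patience), finetune_epochs = as.integer(finetune_epochs),
         finetune_lr_factor = finetune_lr_factor, bootstrap = isTRUE(bootstrap)),
    class = "pka_config"
  )
}

# He-style initialization drawn from the current RNG state.
init_weights <- function(d, hidden) {
  dims <- c(d, hidden, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(rnorm(fan_in * dims[l + 1L]) * sqrt(2 / fan_in),
                     fan_in, dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

run_fit <- function(X, y, W, b, config, lr, epochs) {
  n <- nrow(X)
  n_val <- 0L
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && config$patience > 0) {
    n_val <- floor(n * config$validation_fraction)
    if (n_val >= 1 && n - n_val >= 2) {
      val_idx <- sample.int(n, n_val)
    } else {
      n_val <- 0L
    }
  }
  train_idx <- if (n_val > 0) setdiff(seq_len(n), val_idx) else seq_len(n)
  Xt <- X[train_idx, , drop = FALSE]
  yt <- y[train_idx]
  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]
  nt <- length(train_idx)
  order <- vapply(seq_len(epochs), function(e) sample.int(nt), integer(nt))
  if (!is.matrix(order)) order <- matrix(order, nrow = nt)
  fit <- mlp_fit_cpp(Xt, yt, W, b, Xv, as.numeric(yv), order,
                     min(config$batch_size, nt), lr, config$weight_decay,
                     if (n_val > 0) config$patience else 0L, config$activation)
  fit
}

#' Train one ensemble member
#'
#' Trains a single shift regressor on `(features, shifts)` pairs. The result
#' is a deterministic function of the inputs, configuration and seed: the
#' seed drives weight initialization, the optional bootstrap resample, the
#' validation split and every minibatch shuffle.
#'
#' @param features `n x d` numeric matrix of per-residue embedding vectors.
#' @param shifts Length-`n` numeric vector of pKa shifts (pH units).
#' @param config A [regressor_config()].
#' @param seed Integer seed (mandatory).
#' @return An object of class `pka_mlp` with the fitted weights and the
#'   training/validation loss traces.
#' @export
train_member <- function(features, shifts, config = regressor_config(), seed) {
  stopifnot(is.matrix(features), is.numeric(shifts))
  if (nrow(features) != length(shifts)) abort("features and shifts disagree in length")
  if (nrow(features) < 2) abort("need at least 2 training rows")
  if (!all(is.finite(features)) || !all(is.finite(shifts))) {
    abort("features and shifts must be finite")
  }
  if (missing(seed)) abort("seed is mandatory for reproducibility")
  withr::with_seed(as.integer(seed), {
    if (config$bootstrap) {
      idx <- sample.int(nrow(features), replace = TRUE)
      features <- features[idx, , drop = FALSE]
      shifts <- shifts[idx]
    }
    init <- init_weights(ncol(features), config$hidden)
    fit <- run_fit(features, shifts, init$W, init$b, config,
                   config$lr, config$epochs)
  })
  structure(
    list(W = fit$W, b = fit$b, d = ncol(features), hidden = config$hidden,
         activation = config$activation, seed = as.integer(seed),
         train_mse = as.numeric(fit$train_mse), val_mse = as.numeric(fit$val_mse),
         best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
         finetuned = FALSE),
    class = "pka_mlp"
  )
}

#' Continue training a fitted member on new data (fine-tuning)
#'
#' Warm-starts from the member's current weights and optimizes for
#' `config$finetune_epochs` epochs at `config$lr * config$finetune_lr_factor`.
#' With `finetune_epochs = 0` the member is returned unchanged.
#'
#' @inheritParams train_member
#' @param member A fitted `pka_mlp`.
#' @export
finetune_member <- function(member, features, shifts, config = regressor_config(),
                            seed) {
  stopifnot(inherits(member, "pka_mlp"), is.matrix(features))
  if (ncol(features) != member$d) {
    abort(sprintf("feature width %d does not match member input width %d",
                  ncol(features), member$d))
  }
  if (missing(seed)) abort("seed is mandatory for reproducibility")
  if (config$finetune_epochs == 0) return(member)
  if (nrow(features) < 2) abort("need at least 2 fine-tuning rows")
  cfg <- config
  cfg$activation <- member$activation  # architecture is fixed by the member
  withr::with_seed(as.integer(seed), {
    fit <- run_fit(features, shifts, member$W, member$b, cfg,
                   cfg$lr * cfg$finetune_lr_factor, cfg$finetune_epochs)
  })
  member$W <- fit$W
  member$b <- fit$b
  member$train_mse <- as.numeric(fit$train_mse)
  member$val_mse <- as.numeric(fit$val_mse)
  member$best_epoch <- fit$best_epoch
  member$epochs_run <- fit$epochs_run
  member$finetuned <- TRUE
  member
}

#' Predict shifts with one member
#'
#' @param object A `pka_mlp`.
#' @param features `n x d` matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted shifts.
#' @export
predict.pka_mlp <- function(object, features, ...) {
  stopifnot(is.matrix(features), ncol(features) == object$d)
  if (nrow(features) == 0) return(numeric(0))
  as.numeric(mlp_forward_cpp(features, object$W, object$b, object$activation))
}

#' @export
print.pka_mlp <- function(x, ...) {
  cat(sprintf("<pka_mlp> %d-%s-1 | seed %d | %d epoch(s) | final train MSE %.4g\n",
              x$d, paste(x$hidden, collapse = "-"), x$seed, x$epochs_run,
              x$train_mse[length(x$train_mse)]))
  invisible(x)
}
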