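#' Training configuration
#'
#' The training protocol: MSE loss in years^2, Adam, a fixed epoch budget
#' with no early halting, and a checkpoint overwritten every time the
#' validation loss reaches a new minimum (the saved model is the "early
#' stopping" readout while training still runs to `epochs`).
#'
#' @param learning_rate Adam learning rate (default 0.003).
#' @param epochs fixed number of full passes (default 400).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed covering shuffling and dropout.
#' @param shuffle_each_epoch reshuffle the training order every epoch.
#' @param checkpoint_path where the best-validation weights are written;
#'   defaults to a temporary file.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.003, epochs = 400L,
                         batch_size = 32L, seed = 1L,
                         shuffle_each_epoch = TRUE,
                         checkpoint_path = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 checkpoint_path = checkpoint_path %||%
                   tempfile("projage-ckpt-", fileext = ".rds")),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_channels_match <- function(net, packed) {
  if (!identical(net$spec$channels, packed$channels))
    stop("channel mismatch: model expects [",
         paste(net$spec$channels, collapse = ", "), "] but dataset has [",
         paste(packed$channels, collapse = ", "), "]")
}

# slice a batch of subjects out of a packed split, per plane, keeping dims
get_batch <- function(split_data, planes, idx) {
  lapply(planes, function(pl) split_data$x[[pl]][, , , idx, drop = FALSE])
}

forward_split <- function(net, split_data, planes, batch_size = 64L) {
  n <- length(split_data$ages)
  preds <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    res <- model_forward(net, get_batch(split_data, planes, idx),
                         training = FALSE)
    preds[idx] <- res$preds
  }
  preds
}

#' Train a projection network
#'
#' Full-epoch passes in (re)shuffled order with minibatch Adam updates;
#' after each epoch the validation MSE is computed in inference mode and
#' the checkpoint is overwritten whenever it strictly decreases. Training
#' always runs to `config$epochs`. The packed dataset is held resident and
#' reused across epochs -- no files are touched during the epoch loop.
#' Deterministic given `config$seed` on one device.
#'
#' @param net a `projage_model` from [build_model()].
#' @param packed a `packed_projections` with `train` and `val` splits whose
#'   channels match the model spec.
#' @param config a [train_config()].
#' @return an object of class `train_result`: per-epoch `train_loss` and
#'   `val_loss` (years^2), `best_epoch`, `best_val_loss`, `checkpoint`
#'   (path of the best-validation weights), `best_model`, `final_model`,
#'   and `wall_time` in seconds.
#' @export
train <- function(net, packed, config = train_config()) {
  stopifnot(inherits(net, "projage_model"),
            inherits(packed, "packed_projections"),
            inherits(config, "train_config"))
  check_channels_match(net, packed)
  for (sp in c("train", "val")) {
    if (is.null(packed$splits[[sp]]) || length(packed$splits[[sp]]$ages) == 0L)
      stop("empty split: '", sp, "'")
  }
  planes <- net$spec$planes
  tr <- packed$splits$train
  va <- packed$splits$val
  n <- length(tr$ages)
  t0 <- proc.time()[["elapsed"]]

  theta <- net$theta
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  train_loss <- val_loss <- numeric(config$epochs)
  best_val <- Inf; best_epoch <- NA_integer_
  best_theta <- NULL; best_state <- NULL

  with_local_seed(mix_seed(config$seed, 90001L), {
    order_idx <- seq_len(n)
    for (epoch in seq_len(config$epochs)) {
      if (config$shuffle_each_epoch || epoch == 1L) order_idx <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- order_idx[start:min(start + config$batch_size - 1L, n)]
        net$theta <- theta
        res <- model_forward(net, get_batch(tr, planes, idx), y = tr$ages[idx],
                             training = TRUE, want_grad = TRUE,
                             dropout_seed = mix_seed(config$seed, epoch, start))
        net$state <- res$state
        g <- res$grad
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        ep_loss <- ep_loss + res$loss * length(idx)
      }
      train_loss[epoch] <- ep_loss / n
      net$theta <- theta
      vp <- forward_split(net, va, planes)
      val_loss[epoch] <- mean((vp - va$ages)^2)
      if (val_loss[epoch] < best_val) {
        best_val <- val_loss[epoch]
        best_epoch <- epoch
        best_theta <- theta
        best_state <- net$state
        save_weights(net, config$checkpoint_path)
      }
    }
  })

  final_model <- net
  final_model$theta <- theta
  best_model <- net
  best_model$theta <- best_theta
  best_model$state <- best_state
  save_weights(best_model, config$checkpoint_path)
  structure(list(train_loss = train_loss, val_loss = val_loss,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 checkpoint = config$checkpoint_path,
                 best_model = best_model, final_model = final_model,
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat("train_result:", length(x$train_loss), "epochs; best validation MSE",
      round(x$best_val_loss, 3), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict ages for one split of a packed dataset
#'
#' @param net a `projage_model` (typically the best-validation checkpoint).
#' @param packed a `packed_projections` whose channels match the model.
#' @param split which split to score (default `"test"`).
#' @param batch_size forward batch size.
#' @return numeric vector of predicted ages (years), in manifest order.
#' @export
predict_ages <- function(net, packed, split = "test", batch_size = 64L) {
  stopifnot(inherits(net, "projage_model"),
            inherits(packed, "packed_projections"))
  check_channels_match(net, packed)
  sd_ <- packed$splits[[split]]
  if (is.null(sd_) || length(sd_$ages) == 0L) stop("empty split: '", split, "'")
  preds <- forward_split(net, sd_, net$spec$planes, batch_size)
  if (any(!is.finite(preds))) stop("non-finite predictions")
  preds
}
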