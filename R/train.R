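#' Training configuration
#'
#' Houses the experimental constants of the segmentation stage: Adam with
#' learning rate 1e-4, 100 epochs, mini-batches of 8, and the weighted
#' Dice/IoU loss.
#'
#' @param learning_rate Adam learning rate (> 0, or 0 for a frozen
#'   sanity-check run).
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param loss_weights a [loss_weights()].
#' @param seed seed for shuffling (weight init is seeded by
#'   [build_model()]).
#' @param checkpoint_dir optional directory for best/final checkpoints.
#' @param max_steps optional cap on total optimization steps (the run stops
#'   mid-epoch when reached); `NULL` for `epochs` full passes.
#' @param smooth loss stabilizer added to numerator and denominator.
#' @param beta1,beta2,adam_eps Adam moment decays and epsilon (framework
#'   defaults).
#' @param verbose print per-epoch progress lines.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4,
                            epochs = 100L,
                            batch_size = 8L,
                            loss_weights = mammoseg::loss_weights(),
                            seed = 1L,
                            checkpoint_dir = NULL,
                            max_steps = NULL,
                            smooth = 1,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                            verbose = FALSE) {
  if (learning_rate < 0) config_error("learning_rate must be >= 0")
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 1L) config_error("epochs must be >= 1")
  if (batch_size < 1L) config_error("batch_size must be >= 1")
  stopifnot(inherits(loss_weights, "loss_weights"))
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, loss_weights = loss_weights,
         seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
         max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
         smooth = smooth, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
         verbose = isTRUE(verbose)),
    class = "training_config"
  )
}

adam_step <- function(params, lr, beta1, beta2, eps, t) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

samples_to_batch <- function(samples, idx) {
  n <- length(idx)
  d <- dim(samples[[idx[1L]]]$image)
  x <- array(0, c(n, d[1L], d[2L], 1L))
  y <- array(0, c(n, d[1L], d[2L], 1L))
  for (i in seq_len(n)) {
    x[i, , , 1L] <- samples[[idx[i]]]$image
    y[i, , , 1L] <- samples[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

# mean evaluation Dice (binarized at 0.5, smooth 0) over a sample list
eval_mean_dice <- function(model, samples, batch_size = 8L) {
  if (length(samples) == 0L) return(NA_real_)
  ds <- numeric(length(samples))
  for (start in seq(1L, length(samples), by = batch_size)) {
    idx <- start:min(length(samples), start + batch_size - 1L)
    b <- samples_to_batch(samples, idx)
    p <- forward_pass(model, b$x)
    for (i in seq_along(idx)) {
      ds[idx[i]] <- dice_score((p[i, , , 1L] >= 0.5) * 1, b$y[i, , , 1L])
    }
  }
  mean(ds)
}

eval_mean_loss <- function(model, samples, config, batch_size = 8L) {
  if (length(samples) == 0L) return(NA_real_)
  tot <- 0
  for (start in seq(1L, length(samples), by = batch_size)) {
    idx <- start:min(length(samples), start + batch_size - 1L)
    b <- samples_to_batch(samples, idx)
    p <- forward_pass(model, b$x)
    r <- seg_loss_batch(p, b$y, config$loss_weights, config$smooth)
    tot <- tot + r$loss * length(idx)
  }
  tot / length(samples)
}

#' Train a segmentation model
#'
#' Runs mini-batch Adam on the weighted Dice/IoU loss. The model's
#' parameter stores are updated in place; per-epoch training/validation
#' loss and Dice are logged in the returned history. With a
#' `checkpoint_dir` the best-validation-loss and final weights are saved.
#' The run is reproducible given the model's init seed and the config seed.
#'
#' @param model a `mammoseg_model` from [build_model()].
#' @param data training data: a list of `roi_sample` objects, or a manifest
#'   data.frame (samples with `partition == "train"` are used, and
#'   `"validation"` ones become the validation set unless `validation` is
#'   given).
#' @param config a [training_config()].
#' @param validation optional list of `roi_sample` objects monitored after
#'   each epoch; when absent, validation metrics are `NA`.
#' @return list with `model` and `history` (data.frame of epoch, step,
#'   train_loss, train_dice, val_loss, val_dice).
#' @export
train <- function(model, data, config = training_config(), validation = NULL) {
  stopifnot(inherits(model, "mammoseg_model"), inherits(config, "training_config"))
  if (is.data.frame(data)) {
    manifest <- data
    samples <- load_samples(manifest, partition = "train")
    if (is.null(validation) && "partition" %in% names(manifest)) {
      validation <- load_samples(manifest, partition = "validation")
    }
  } else {
    samples <- data
  }
  if (length(samples) == 0L) config_error("training set is empty")

  steps_per_epoch <- ceiling(length(samples) / config$batch_size)
  total_steps <- if (is.null(config$max_steps)) {
    config$epochs * steps_per_epoch
  } else {
    config$max_steps
  }
  history <- data.frame(epoch = integer(), step = integer(),
                        train_loss = numeric(), train_dice = numeric(),
                        val_loss = numeric(), val_dice = numeric())
  best_val <- Inf
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      if (step >= total_steps) break
      ord <- sample.int(length(samples))
      ep_loss <- 0
      ep_n <- 0L
      for (start in seq(1L, length(samples), by = config$batch_size)) {
        if (step >= total_steps) break
        idx <- ord[start:min(length(samples), start + config$batch_size - 1L)]
        b <- samples_to_batch(samples, idx)
        ctx <- ag_ctx(training = TRUE, grad = TRUE)
        pred <- model$forward(b$x, ctx)
        lr <- seg_loss_batch(pred$value, b$y, config$loss_weights, config$smooth)
        if (!is.finite(lr$loss)) {
          stopf("non-finite training loss at step %d (loss = %s); aborting",
                step + 1L, format(lr$loss))
        }
        ag_backward(ctx, pred, lr$grad)
        step <- step + 1L
        adam_step(model$params, config$learning_rate,
                  config$beta1, config$beta2, config$adam_eps, step)
        ep_loss <- ep_loss + lr$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      train_dice <- eval_mean_dice(model, samples, config$batch_size)
      val_loss <- if (length(validation)) {
        eval_mean_loss(model, validation, config, config$batch_size)
      } else NA_real_
      val_dice <- if (length(validation)) {
        eval_mean_dice(model, validation, config$batch_size)
      } else NA_real_
      history[nrow(history) + 1L, ] <- list(epoch, step, ep_loss / ep_n,
                                            train_dice, val_loss, val_dice)
      if (config$verbose) {
        message(sprintf("epoch %3d | step %5d | loss %.4f | dice %.4f | val loss %s | val dice %s",
                        epoch, step, ep_loss / ep_n, train_dice,
                        format(round(val_loss, 4)), format(round(val_dice, 4))))
      }
      if (!is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_model(model, file.path(config$checkpoint_dir, "final.rds"))
        if (!is.na(val_loss) && val_loss < best_val) {
          best_val <- val_loss
          save_model(model, file.path(config$checkpoint_dir, "best.rds"))
        }
      }
      if (step >= total_steps) break
    }
  })
  list(model = model, history = history)
}
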