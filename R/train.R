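#' Training configuration
#'
#' Defaults mirror the optimisation setup used throughout: Adam with
#' learning rate 1e-4 and weight decay 2e-3, batch size 5, up to 500 epochs,
#' and a reduce-on-plateau schedule that cuts the learning rate to one tenth
#' after 20 validation epochs without improvement.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay L2 penalty added to the gradient (classic Adam
#'   convention, not decoupled).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param patience Validation epochs without improvement before the learning
#'   rate is decayed.
#' @param lr_decay_factor Multiplicative decay (0.1 = one tenth).
#' @param seed Seed fixing data order.
#' @param loss A [loss_spec()]; the training objective.
#' @param monitor `"loss"` (default; plateau detection on validation loss)
#'   or `"dice"`.
#' @param stop_dice Optional early-exit target: stop once the best validation
#'   Dice reaches this value (NULL = train the full budget).
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 2e-3,
                         batch_size = 5L, max_epochs = 500L, patience = 20L,
                         lr_decay_factor = 0.1, seed = 1L,
                         loss = loss_spec("CE"), monitor = c("loss", "dice"),
                         stop_dice = NULL) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            lr_decay_factor > 0, lr_decay_factor < 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed),
                 loss = loss, monitor = monitor, stop_dice = stop_dice),
            class = "train_config")
}

## learning-rate trace implied by a sequence of monitored values:
## reduce by lr_decay_factor after `patience` consecutive epochs without
## improvement over the running best; the stall counter resets on the drop,
## the running best is kept.
lr_trace <- function(metric, cfg, higher_better = FALSE) {
  lr <- cfg$learning_rate
  best <- if (higher_better) -Inf else Inf
  stall <- 0L
  out <- numeric(length(metric))
  for (e in seq_along(metric)) {
    improved <- if (higher_better) metric[e] > best else metric[e] < best
    if (improved) {
      best <- metric[e]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
    out[e] <- lr
  }
  out
}

#' Learning rate after the recorded history
#'
#' Replays the reduce-on-plateau rule over a training history and returns
#' the learning rate in force after its last epoch: one tenth of the
#' previous value for every completed stall of `patience` validation epochs
#' without improvement.
#'
#' @param history A `"train_history"` (or a data.frame with the monitored
#'   column `val_loss` or `val_dice`).
#' @param cfg A [train_config()].
#' @return The updated learning rate.
#' @export
lr_schedule_step <- function(history, cfg) {
  h <- if (inherits(history, "train_history")) history$epochs else history
  if (NROW(h) == 0L) stop("history is empty")
  if (cfg$monitor == "dice")
    utils::tail(lr_trace(h$val_dice, cfg, higher_better = TRUE), 1)
  else
    utils::tail(lr_trace(h$val_loss, cfg, higher_better = FALSE), 1)
}

## stack dataset samples idx into arrays c(H,W,C,n) / c(H,W,n)
stack_batch <- function(dataset, idx) {
  d <- dim(dataset$samples[[idx[1]]]$image)
  x <- array(0, dim = c(d, length(idx)))
  y <- array(0L, dim = c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- dataset$samples[[idx[j]]]$image
    y[, , j] <- dataset$samples[[idx[j]]]$label
  }
  list(x = x, y = y)
}

## loss value and gradient w.r.t. logits; BCE is fed softmax probabilities
score_loss <- function(spec, logits, y) {
  tot <- 0; grad <- 0
  p <- NULL
  for (j in seq_along(spec$components)) {
    nm <- spec$components[j]; w <- spec$weights[j]
    if (nm == "BCE") {
      if (is.null(p)) p <- pmin(pmax(softmax4(logits), 1e-7), 1 - 1e-7)
      tot <- tot + w * compute_loss("BCE", p, y, spec)
      dLdp <- loss_grad("BCE", p, y, spec)
      grad <- grad + w * chain_softmax(p, dLdp)
    } else {
      tot <- tot + w * compute_loss(nm, logits, y, spec)
      grad <- grad + w * loss_grad(nm, logits, y, spec)
    }
  }
  list(loss = tot, grad = grad)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (wd > 0) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

## mean foreground Dice of a model on a dataset (per-slice, classes pooled
## for binary; class-averaged for multi-class via the nested regions)
validation_metrics <- function(model, dataset, spec, batch_size) {
  n <- length(dataset$samples)
  loss <- 0; nb <- 0
  preds <- NULL; truths <- NULL
  for (at in seq(1, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, n)
    b <- stack_batch(dataset, idx)
    logits <- unet_forward(model, b$x, training = FALSE)$logits$value
    loss <- loss + score_loss(spec, logits, b$y)$loss * length(idx)
    pc <- apply(softmax4(logits), c(1, 2, 4), which.max) - 1L
    preds <- if (is.null(preds)) pc else
      array(c(preds, pc), dim = c(dim(pc)[1:2], dim(preds)[3] + dim(pc)[3]))
    truths <- if (is.null(truths)) b$y else
      array(c(truths, b$y), dim = c(dim(b$y)[1:2], dim(truths)[3] + dim(b$y)[3]))
    nb <- nb + length(idx)
  }
  if (dataset$classes > 2L) {
    ev <- evaluate_brats(preds, truths)
    list(loss = loss / nb, dice = unname(ev["mean"]),
         regions = ev[c("wt", "tc", "et")])
  } else {
    ev <- evaluate_binary(preds, truths)
    list(loss = loss / nb, dice = ev$mean, regions = NULL)
  }
}

#' Train an LFE-UNet
#'
#' Runs mini-batch Adam with the reduce-on-plateau schedule: each epoch
#' shuffles the training set (seeded), takes optimiser steps under the
#' configured loss, then scores validation loss and Dice without touching
#' gradients. The best-Dice weights are kept as the checkpoint.
#'
#' @param model An initialised `"lfe_unet"`.
#' @param train_set,val_set `"seg_dataset"`s with channel and class counts
#'   matching the model.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch?
#' @return Object of class `"unet_fit"`: the trained model (`model`), the
#'   best checkpoint (`best_params`, `best_dice`, `best_epoch`) and a
#'   `"train_history"` (`history`) with per-epoch train loss, validation
#'   loss, validation Dice and learning rate.
#' @export
fit_unet <- function(model, train_set, val_set, cfg = train_config(),
                     verbose = FALSE) {
  stopifnot(inherits(model, "lfe_unet"), inherits(train_set, "seg_dataset"),
            inherits(val_set, "seg_dataset"), inherits(cfg, "train_config"))
  d <- dim(train_set$samples[[1]]$image)
  if (d[3] != model$config$in_channels)
    stop("dataset has ", d[3], " channels, model expects ",
         model$config$in_channels)
  if (train_set$classes != model$config$classes)
    stop("dataset has ", train_set$classes, " classes, model expects ",
         model$config$classes)
  ntr <- length(train_set$samples)
  state <- adam_init(model$params)
  lr <- cfg$learning_rate
  best <- if (cfg$monitor == "dice") -Inf else Inf
  stall <- 0L
  best_dice <- -Inf; best_params <- NULL; best_epoch <- NA_integer_
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- withr_seed(cfg$seed + epoch, sample.int(ntr))
    tr_loss <- 0
    for (at in seq(1, ntr, by = cfg$batch_size)) {
      idx <- perm[at:min(at + cfg$batch_size - 1, ntr)]
      b <- stack_batch(train_set, idx)
      fw <- unet_forward(model, b$x, training = TRUE)
      sl <- score_loss(cfg$loss, fw$logits$value, b$y)
      grads <- tp_backward(fw$logits, sl$grad)
      upd <- adam_step(model$params, grads, state, lr, cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + sl$loss * length(idx)
    }
    vm <- validation_metrics(model, val_set, cfg$loss, cfg$batch_size)
    rec <- data.frame(epoch = epoch, train_loss = tr_loss / ntr,
                      val_loss = vm$loss, val_dice = vm$dice, lr = lr)
    if (!is.null(vm$regions))
      for (r in names(vm$regions)) rec[[paste0("dice_", r)]] <- vm$regions[[r]]
    hist[[epoch]] <- rec
    if (vm$dice > best_dice) {
      best_dice <- vm$dice
      best_params <- model$params
      best_epoch <- epoch
    }
    metric <- if (cfg$monitor == "dice") vm$dice else vm$loss
    improved <- if (cfg$monitor == "dice") metric > best else metric < best
    if (improved) {
      best <- metric; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f  lr %g",
                      epoch, rec$train_loss, vm$loss, vm$dice, lr))
    if (!is.null(cfg$stop_dice) && best_dice >= cfg$stop_dice) break
  }
  history <- structure(list(epochs = do.call(rbind, hist),
                            best_epoch = best_epoch),
                       class = "train_history")
  structure(list(model = model, best_params = best_params,
                 best_dice = best_dice, best_epoch = best_epoch,
                 history = history, config = cfg),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  h <- x$history$epochs
  cat(sprintf("LFE-UNet fit: %d epochs, best validation Dice %.4f (epoch %d)\n",
              nrow(h), x$best_dice, x$best_epoch))
  cat(sprintf("final: train loss %.4f, val loss %.4f, lr %g\n",
              utils::tail(h$train_loss, 1), utils::tail(h$val_loss, 1),
              utils::tail(h$lr, 1)))
  invisible(x)
}

#' @export
plot.unet_fit <- function(x, ...) {
  h <- x$history$epochs
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict with the best checkpoint of a fit
#'
#' @param object A `"unet_fit"`.
#' @param newdata Image array `c(H, W, C[, batch])`.
#' @param ... Passed to [predict.lfe_unet()] (e.g. `type = "class"`).
#' @export
predict.unet_fit <- function(object, newdata, ...) {
  m <- object$model
  if (!is.null(object$best_params)) m$params <- object$best_params
  predict(m, newdata, ...)
}

#' Write per-epoch TSV and a JSON summary of a fit
#'
#' @param fit A `"unet_fit"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_history <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fit$history$epochs, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(best_dice = fit$best_dice,
                            best_epoch = fit$best_epoch,
                            epochs = nrow(fit$history$epochs)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
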