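## Nine segmentation losses and weighted combinations.
##
## Conventions. Predictions arrive as an array dim c(H, W, C, batch). All
## losses except BCE accept raw scores: CE, L2, SF, DL, TL, FL and KL apply a
## class-wise softmax internally, BCL applies an elementwise sigmoid; BCE
## requires probabilities in (0, 1). Targets are integer label maps
## (c(H, W, batch), values 0..C-1) or one-hot arrays of the prediction shape.
## Reductions: CE/FL/KL average over pixels and batch; BCE/BCL/L2 average
## over every element; DL/TL average the per-sample per-class overlap terms;
## SF averages a per-class soft F1 computed over the whole batch.

LOSS_NAMES <- c("CE", "L2", "SF", "BCE", "BCL", "DL", "TL", "FL", "KL")
.dice_smooth <- 1e-6
.kl_eps <- 1e-8
.log_clamp <- 1e-12

#' Loss specification
#'
#' @param components Character vector of loss names among
#'   `CE, L2, SF, BCE, BCL, DL, TL, FL, KL`.
#' @param weights Numeric combination weights (default all 1).
#' @param alpha,beta Tversky false-positive / false-negative weights
#'   (defaults 0.3 and 0.7).
#' @param lambda,gamma Focal-loss balance factor and exponent (defaults 0.25
#'   and 2).
#' @param include_background Include the background class in the
#'   class-averaged overlap losses (DL, TL, SF)? Default TRUE.
#' @return An object of class `"loss_spec"`.
#' @export
loss_spec <- function(components = "CE", weights = NULL, alpha = 0.3,
                      beta = 0.7, lambda = 0.25, gamma = 2,
                      include_background = TRUE) {
  components <- toupper(components)
  bad <- setdiff(components, LOSS_NAMES)
  if (length(bad))
    stop("unknown loss component(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(LOSS_NAMES, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(components))
  if (length(weights) != length(components))
    stop("weights must have one entry per component")
  stopifnot(alpha > 0, beta > 0, gamma >= 0)
  structure(list(components = components, weights = weights, alpha = alpha,
                 beta = beta, lambda = lambda, gamma = gamma,
                 include_background = include_background),
            class = "loss_spec")
}

#' The DFK loss: Dice + focal + Kullback-Leibler
#'
#' Unweighted sum of the Dice, focal and KL-divergence losses, the
#' combination used for the headline segmentation results.
#' @inheritParams loss_spec
#' @return A [loss_spec()].
#' @export
dfk_loss <- function(alpha = 0.3, beta = 0.7, lambda = 0.25, gamma = 2)
  loss_spec(c("DL", "FL", "KL"), alpha = alpha, beta = beta,
            lambda = lambda, gamma = gamma)

## coerce target to one-hot of shape dim(y_pred)
as_one_hot <- function(y_true, pred_dim) {
  C <- pred_dim[3]
  if (length(dim(y_true)) == 4L && all(dim(y_true) == pred_dim)) {
    if (any(y_true < 0 | y_true > 1))
      stop("one-hot target has entries outside [0, 1]")
    return(y_true)
  }
  if (is.null(dim(y_true))) dim(y_true) <- pred_dim[c(1, 2, 4)]
  if (length(dim(y_true)) == 2L) dim(y_true) <- c(dim(y_true), 1L)
  if (!all(dim(y_true) == pred_dim[c(1, 2, 4)]))
    stop("label map dims ", paste(dim(y_true), collapse = "x"),
         " do not match prediction ", paste(pred_dim, collapse = "x"))
  if (any(y_true < 0 | y_true > C - 1 | y_true != round(y_true)))
    stop("label values must be integers in 0..", C - 1)
  oh <- array(0, dim = pred_dim)
  for (c in seq_len(C))
    oh[, , c, ] <- (y_true == c - 1L)
  oh
}

check_pred <- function(y_pred) {
  d <- dim(y_pred)
  if (is.null(d) || length(d) < 3L)
    stop("y_pred must be an array dim c(H, W, classes[, batch])")
  if (length(d) == 3L) dim(y_pred) <- c(d, 1L)
  y_pred
}

## per-class index set honouring include_background (class 1 = background)
class_set <- function(C, spec) {
  if (isTRUE(spec$include_background) || C == 1L) seq_len(C) else 2:C
}

## sum over H, W for each (class, sample): returns C x N matrix
cls_sum <- function(x) apply(x, c(3, 4), sum)

#' Compute a single segmentation loss
#'
#' @param name One of `CE, L2, SF, BCE, BCL, DL, TL, FL, KL`.
#' @param y_pred Array dim `c(H, W, C, batch)` (or without the batch margin).
#'   Raw scores for every loss except BCE, which requires probabilities.
#' @param y_true Integer label map `c(H, W, batch)` (values 0..C-1) or a
#'   one-hot array of the prediction shape.
#' @param spec A [loss_spec()] carrying the hyperparameters.
#' @return A non-negative scalar.
#' @examples
#' p <- array(c(5, -5, -5, 5), dim = c(1, 2, 2, 1))  # confident, correct
#' compute_loss("DL", p, array(c(0, 1), dim = c(1, 2, 1)))
#' @export
compute_loss <- function(name, y_pred, y_true, spec = loss_spec()) {
  name <- toupper(name)
  if (!name %in% LOSS_NAMES)
    stop("unknown loss ", name, "; valid names: ",
         paste(LOSS_NAMES, collapse = ", "))
  y_pred <- check_pred(y_pred)
  t <- as_one_hot(y_true, dim(y_pred))
  d <- dim(y_pred)
  npix <- d[1] * d[2] * d[4]
  switch(name,
    CE = {
      p <- pmax(softmax4(y_pred), .log_clamp)
      -sum(t * log(p)) / npix
    },
    FL = {
      p <- pmax(softmax4(y_pred), .log_clamp)
      pt <- pmin(apply(p * t, c(1, 2, 4), sum), 1)
      -spec$lambda * sum((1 - pt)^spec$gamma * log(pmax(pt, .log_clamp))) / npix
    },
    KL = {
      p <- pmax(softmax4(y_pred), .log_clamp)
      ts <- smooth_target(t)
      sum(ts * (log(ts) - log(p))) / npix
    },
    L2 = {
      p <- softmax4(y_pred)
      mean((p - t)^2)
    },
    BCE = {
      if (any(y_pred <= 0 | y_pred >= 1))
        stop("BCE requires probabilities strictly inside (0, 1); ",
             "got values outside that range")
      -mean(t * log(y_pred) + (1 - t) * log(1 - y_pred))
    },
    BCL = {
      p <- 1 / (1 + exp(-y_pred))
      p <- pmin(pmax(p, .log_clamp), 1 - .log_clamp)
      -mean(t * log(p) + (1 - t) * log(1 - p))
    },
    DL = {
      p <- softmax4(y_pred)
      ps <- cls_sum(p); ts_ <- cls_sum(t); is_ <- cls_sum(p * t)
      cs <- class_set(d[3], spec)
      dice <- (2 * is_[cs, , drop = FALSE] + .dice_smooth) /
        (ps[cs, , drop = FALSE] + ts_[cs, , drop = FALSE] + .dice_smooth)
      1 - mean(dice)
    },
    TL = {
      p <- softmax4(y_pred)
      tp <- cls_sum(p * t); fp <- cls_sum(p * (1 - t)); fn <- cls_sum((1 - p) * t)
      cs <- class_set(d[3], spec)
      ti <- (tp[cs, , drop = FALSE] + .dice_smooth) /
        (tp[cs, , drop = FALSE] + spec$alpha * fp[cs, , drop = FALSE] +
           spec$beta * fn[cs, , drop = FALSE] + .dice_smooth)
      1 - mean(ti)
    },
    SF = {
      p <- softmax4(y_pred)
      tp <- rowSums(cls_sum(p * t)); ps <- rowSums(cls_sum(p))
      ts_ <- rowSums(cls_sum(t))
      cs <- class_set(d[3], spec)
      f1 <- (2 * tp[cs] + .dice_smooth) / (ps[cs] + ts_[cs] + .dice_smooth)
      1 - mean(f1)
    })
}

smooth_target <- function(t) {
  C <- dim(t)[3]
  ts <- t * (1 - C * .kl_eps) + .kl_eps
  ts
}

#' Weighted combination of segmentation losses
#'
#' @param spec A [loss_spec()]; its `components` and `weights` define the
#'   combination. [dfk_loss()] is the Dice + focal + KL preset.
#' @inheritParams compute_loss
#' @return Non-negative scalar: `sum(weights * component losses)`.
#' @export
combine_loss <- function(spec, y_pred, y_true) {
  stopifnot(inherits(spec, "loss_spec"))
  sum(vapply(seq_along(spec$components), function(j)
    spec$weights[j] * compute_loss(spec$components[j], y_pred, y_true, spec),
    0))
}

## ---- gradients (w.r.t. raw scores) for the training engine --------------

## chain a gradient w.r.t. softmax probabilities back to the scores
chain_softmax <- function(p, dLdp) {
  s <- apply(dLdp * p, c(1, 2, 4), sum)
  d <- dim(p)
  p * (dLdp - aperm(array(s, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)))
}

## gradient of a single loss w.r.t. the raw scores y_pred (BCE excluded from
## training use; the engine feeds scores to every loss)
loss_grad <- function(name, y_pred, y_true, spec = loss_spec()) {
  y_pred <- check_pred(y_pred)
  t <- as_one_hot(y_true, dim(y_pred))
  d <- dim(y_pred)
  npix <- d[1] * d[2] * d[4]
  name <- toupper(name)
  if (name %in% c("CE", "KL")) {
    p <- softmax4(y_pred)
    tt <- if (name == "KL") smooth_target(t) else t
    return((p - tt) / npix)
  }
  if (name == "FL") {
    p <- pmax(softmax4(y_pred), .log_clamp)
    pt <- pmin(apply(p * t, c(1, 2, 4), sum), 1 - 1e-9)
    g <- spec$gamma; lam <- spec$lambda
    dLdpt <- lam * (g * (1 - pt)^(g - 1) * log(pmax(pt, .log_clamp)) -
                      (1 - pt)^g / pt) / npix
    dLdp <- t * aperm(array(dLdpt, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    return(chain_softmax(p, dLdp))
  }
  if (name == "L2") {
    p <- softmax4(y_pred)
    return(chain_softmax(p, 2 * (p - t) / length(p)))
  }
  if (name == "BCL") {
    p <- 1 / (1 + exp(-y_pred))
    return((p - t) / length(p))
  }
  if (name == "BCE") {
    p <- pmin(pmax(y_pred, .log_clamp), 1 - .log_clamp)
    return((p - t) / (p * (1 - p)) / length(p))
  }
  p <- softmax4(y_pred)
  C <- d[3]; Nb <- d[4]
  cs <- class_set(C, spec)
  dLdp <- array(0, dim = d)
  if (name == "DL") {
    ps <- cls_sum(p); ts_ <- cls_sum(t); is_ <- cls_sum(p * t)
    denom <- ps + ts_ + .dice_smooth
    num <- 2 * is_ + .dice_smooth
    for (c in cs) for (nn in seq_len(Nb)) {
      tc <- t[, , c, nn]
      dLdp[, , c, nn] <- -(2 * tc * denom[c, nn] - num[c, nn]) /
        denom[c, nn]^2 / (length(cs) * Nb)
    }
  } else if (name == "TL") {
    tp <- cls_sum(p * t); fp <- cls_sum(p * (1 - t)); fn <- cls_sum((1 - p) * t)
    denom <- tp + spec$alpha * fp + spec$beta * fn + .dice_smooth
    num <- tp + .dice_smooth
    for (c in cs) for (nn in seq_len(Nb)) {
      tc <- t[, , c, nn]
      dnum <- tc
      dden <- tc * (1 - spec$alpha - spec$beta) + spec$alpha
      dLdp[, , c, nn] <- -(dnum * denom[c, nn] - num[c, nn] * dden) /
        denom[c, nn]^2 / (length(cs) * Nb)
    }
  } else if (name == "SF") {
    tp <- rowSums(cls_sum(p * t)); ps <- rowSums(cls_sum(p))
    ts_ <- rowSums(cls_sum(t))
    denom <- ps + ts_ + .dice_smooth
    num <- 2 * tp + .dice_smooth
    for (c in cs) {
      tc <- t[, , c, , drop = FALSE]
      dLdp[, , c, ] <- -(2 * tc * denom[c] - num[c]) / denom[c]^2 / length(cs)
    }
  } else stop("no gradient for loss ", name)
  chain_softmax(p, dLdp)
}

## combined gradient
combine_grad <- function(spec, y_pred, y_true) {
  g <- 0
  for (j in seq_along(spec$components))
    g <- g + spec$weights[j] *
      loss_grad(spec$components[j], y_pred, y_true, spec)
  g
}
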