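# Brute-force reference implementations, written independently of the package
# internals: plain per-pixel loops, no vectorised shortcuts. These serve as
# oracles for the loss functions and the Dice evaluation.

oracle_softmax_pixel <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# y_pred: c(H, W, C, N) raw scores (probabilities for BCE);
# y_true: c(H, W, N) integer labels. Returns the scalar loss.
oracle_loss <- function(name, y_pred, y_true, alpha = 0.3, beta = 0.7,
                        lambda = 0.25, gamma = 2) {
  d <- dim(y_pred)
  H <- d[1]; W <- d[2]; C <- d[3]; Nb <- d[4]
  smooth <- 1e-6; kl_eps <- 1e-8
  if (name %in% c("CE", "FL", "KL", "L2", "BCL")) {
    tot <- 0
    for (n in seq_len(Nb)) for (i in seq_len(H)) for (j in seq_len(W)) {
      z <- y_pred[i, j, , n]
      tcl <- y_true[i, j, n] + 1
      if (name == "BCL") {
        p <- 1 / (1 + exp(-z))
        for (c in seq_len(C)) {
          t <- as.numeric(c == tcl)
          tot <- tot - (t * log(p[c]) + (1 - t) * log(1 - p[c]))
        }
      } else {
        p <- oracle_softmax_pixel(z)
        if (name == "CE") tot <- tot - log(p[tcl])
        if (name == "FL") tot <- tot - lambda * (1 - p[tcl])^gamma * log(p[tcl])
        if (name == "KL") for (c in seq_len(C)) {
          t <- as.numeric(c == tcl) * (1 - C * kl_eps) + kl_eps
          tot <- tot + t * (log(t) - log(p[c]))
        }
        if (name == "L2") for (c in seq_len(C))
          tot <- tot + (p[c] - as.numeric(c == tcl))^2
      }
    }
    denom <- if (name %in% c("L2", "BCL")) H * W * C * Nb else H * W * Nb
    return(tot / denom)
  }
  if (name == "BCE") {
    tot <- 0
    for (n in seq_len(Nb)) for (i in seq_len(H)) for (j in seq_len(W))
      for (c in seq_len(C)) {
        t <- as.numeric(c == y_true[i, j, n] + 1)
        p <- y_pred[i, j, c, n]
        tot <- tot - (t * log(p) + (1 - t) * log(1 - p))
      }
    return(tot / (H * W * C * Nb))
  }
  # overlap losses on softmax probabilities
  P <- array(0, dim = d)
  for (n in seq_len(Nb)) for (i in seq_len(H)) for (j in seq_len(W))
    P[i, j, , n] <- oracle_softmax_pixel(y_pred[i, j, , n])
  if (name %in% c("DL", "TL")) {
    acc <- 0
    for (n in seq_len(Nb)) for (c in seq_len(C)) {
      tp <- fp <- fn <- ps <- ts <- inter <- 0
      for (i in seq_len(H)) for (j in seq_len(W)) {
        p <- P[i, j, c, n]; t <- as.numeric(y_true[i, j, n] + 1 == c)
        tp <- tp + p * t; fp <- fp + p * (1 - t); fn <- fn + (1 - p) * t
        ps <- ps + p; ts <- ts + t; inter <- inter + p * t
      }
      acc <- acc + if (name == "DL")
        (2 * inter + smooth) / (ps + ts + smooth)
      else
        (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
    }
    return(1 - acc / (C * Nb))
  }
  if (name == "SF") {
    acc <- 0
    for (c in seq_len(C)) {
      inter <- ps <- ts <- 0
      for (n in seq_len(Nb)) for (i in seq_len(H)) for (j in seq_len(W)) {
        p <- P[i, j, c, n]; t <- as.numeric(y_true[i, j, n] + 1 == c)
        inter <- inter + p * t; ps <- ps + p; ts <- ts + t
      }
      acc <- acc + (2 * inter + smooth) / (ps + ts + smooth)
    }
    return(1 - acc / C)
  }
  stop("unknown loss in oracle: ", name)
}

# brute-force Dice by explicit pixel counting
oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (q in seq_along(a)) {
    if (a[q] != 0 && b[q] != 0) inter <- inter + 1
    if (a[q] != 0) na <- na + 1
    if (b[q] != 0) nb <- nb + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# seeded small prediction/label pair shared by loss tests
loss_fixture <- function(seed = 31, H = 2, W = 2, C = 2, Nb = 2) {
  set.seed(seed)
  list(z = array(rnorm(H * W * C * Nb), dim = c(H, W, C, Nb)),
       y = array(sample(0:(C - 1), H * W * Nb, TRUE), dim = c(H, W, Nb)))
}
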