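## Differentiable layer wrappers over the compiled kernels. Each takes and
## returns tape nodes carrying arrays of dim c(H, W, C, N).

ly_conv <- function(tape, x, w, pname, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  wn <- tp_leaf(tape, w, param = pname)
  y <- conv2d_fwd_cpp(x$value, w, as.integer(stride), as.integer(pad))
  xv <- x$value
  tp_node(tape, y, parents = c(x$id, wn$id), bwd = function(g) {
    r <- conv2d_bwd_cpp(xv, w, g, as.integer(stride), as.integer(pad))
    list(r$dx, r$dw)
  })
}

## Batch norm without learnable affine; running statistics live in `model$bn`,
## an environment keyed by layer name, and are updated in training mode.
ly_bn <- function(tape, x, model, name, training) {
  C <- dim(x$value)[3]
  st <- model$bn[[name]]
  if (is.null(st)) {
    st <- list(mean = numeric(C), var = rep(1, C))
    model$bn[[name]] <- st
  }
  r <- batchnorm_fwd_cpp(x$value, st$mean, st$var,
                         momentum = 0.1, eps = 1e-5, training = training)
  if (training) model$bn[[name]] <- list(mean = r$run_mean, var = r$run_var)
  xv <- x$value
  tp_node(tape, r$y, parents = x$id, bwd = function(g) {
    list(batchnorm_bwd_cpp(g, xv, r$mean, r$invstd, training))
  })
}

ly_relu <- function(tape, x) {
  mask <- x$value > 0
  tp_node(tape, x$value * mask, parents = x$id,
          bwd = function(g) list(g * mask))
}

ly_maxpool <- function(tape, x, f) {
  d <- dim(x$value)
  r <- maxpool_fwd_cpp(x$value, as.integer(f))
  tp_node(tape, r$y, parents = x$id, bwd = function(g) {
    list(maxpool_bwd_cpp(g, r$idx, d[1], d[2]))
  })
}

ly_bilinear <- function(tape, x, Ho, Wo) {
  d <- dim(x$value)
  y <- bilinear_fwd_cpp(x$value, as.integer(Ho), as.integer(Wo))
  tp_node(tape, y, parents = x$id, bwd = function(g) {
    list(bilinear_bwd_cpp(g, d[1], d[2]))
  })
}

ly_concat <- function(tape, nodes) {
  vals <- lapply(nodes, `[[`, "value")
  dims <- lapply(vals, dim)
  chans <- vapply(dims, `[`, 0L, 3L)
  d1 <- dims[[1]]
  y <- array(0, dim = c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  tp_node(tape, y, parents = vapply(nodes, `[[`, 0L, "id"), bwd = function(g) {
    out <- vector("list", length(chans))
    at <- 0L
    for (j in seq_along(chans)) {
      out[[j]] <- g[, , at + seq_len(chans[j]), , drop = FALSE]
      at <- at + chans[j]
    }
    out
  })
}

ly_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, parents = c(a$id, b$id),
          bwd = function(g) list(g, g))
}
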