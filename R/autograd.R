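## Minimal reverse-mode tape used by the forward pass.
##
## A tape records operations in execution order; each op stores the ids of its
## parents and a closure computing the vector-Jacobian product. backward()
## sweeps the tape once in reverse and accumulates parameter gradients by name.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- list()
  tp$n <- 0L
  tp
}

#' @noRd
tp_node <- function(tape, value, parents = integer(0), bwd = NULL, param = NULL) {
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$ops[[id]] <- list(id = id, parents = parents, bwd = bwd, param = param)
  list(id = id, value = value, tape = tape)
}

tp_leaf <- function(tape, value, param = NULL) {
  tp_node(tape, value, param = param)
}

## Backward sweep from node `out` with seed gradient `grad` (same shape as
## out$value). Returns a named list of parameter gradients.
tp_backward <- function(out, grad) {
  tape <- out$tape
  grads <- vector("list", tape$n)
  grads[[out$id]] <- grad
  pgrads <- list()
  for (id in seq(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    op <- tape$ops[[id]]
    if (!is.null(op$param)) {
      pg <- pgrads[[op$param]]
      pgrads[[op$param]] <- if (is.null(pg)) g else pg + g
    }
    if (length(op$parents) > 0L) {
      pg <- op$bwd(g)
      for (j in seq_along(op$parents)) {
        pid <- op$parents[[j]]
        if (is.null(grads[[pid]])) grads[[pid]] <- pg[[j]]
        else grads[[pid]] <- grads[[pid]] + pg[[j]]
      }
    }
    grads[[id]] <- NULL
  }
  pgrads
}
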