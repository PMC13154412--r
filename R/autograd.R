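# Minimal tape-based reverse-mode automatic differentiation.
#
# The generative attention model is small (a few hundred matrix ops per
# forward pass, largest operand ~180 x 740), so a lightweight tape over
# BLAS-backed matrix primitives is sufficient: nodes are environments
# holding a value, an accumulated gradient, parent references and a
# backward closure; ag_backward() replays the tape in reverse.  Only the
# primitives the model needs are implemented, and each is checked against
# central finite differences in the test suite.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ag_const <- function(tape, value) ag_node(tape, value)

ag_param <- function(tape, value) {
  nd <- ag_node(tape, value)
  nd$is_param <- TRUE
  nd
}

ag_acc <- function(p, g) p$grad <- if (is.null(p$grad)) g else p$grad + g

ag_matmul <- function(tape, x, y) {
  ag_node(tape, x$value %*% y$value, list(x, y), function(nd) {
    ag_acc(x, nd$grad %*% t(y$value))
    ag_acc(y, t(x$value) %*% nd$grad)
  })
}

ag_add <- function(tape, x, y) {
  ag_node(tape, x$value + y$value, list(x, y), function(nd) {
    ag_acc(x, nd$grad)
    ag_acc(y, nd$grad)
  })
}

# x: n x d, b: 1 x d broadcast over rows
ag_add_rowvec <- function(tape, x, b) {
  ag_node(tape, sweep(x$value, 2L, as.vector(b$value), "+"), list(x, b),
          function(nd) {
            ag_acc(x, nd$grad)
            ag_acc(b, matrix(colSums(nd$grad), 1L))
          })
}

ag_scale <- function(tape, x, s) {
  ag_node(tape, x$value * s, list(x), function(nd) ag_acc(x, nd$grad * s))
}

# elementwise product with a constant matrix (masking)
ag_mul_const <- function(tape, x, m) {
  ag_node(tape, x$value * m, list(x), function(nd) ag_acc(x, nd$grad * m))
}

ag_relu <- function(tape, x) {
  ag_node(tape, pmax(x$value, 0), list(x), function(nd) {
    ag_acc(x, nd$grad * (x$value > 0))
  })
}

ag_transpose <- function(tape, x) {
  ag_node(tape, t(x$value), list(x), function(nd) ag_acc(x, t(nd$grad)))
}

ag_concat_cols <- function(tape, xs) {
  vals <- lapply(xs, function(x) x$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(tape, do.call(cbind, vals), xs, function(nd) {
    for (ii in seq_along(xs))
      ag_acc(xs[[ii]], nd$grad[, starts[ii]:ends[ii], drop = FALSE])
  })
}

# out[m] = x[idx[m]] for an injective linear index map; `dims` shapes the output
ag_index_reshape <- function(tape, x, idx, dims) {
  v <- x$value[idx]
  dim(v) <- dims
  ag_node(tape, v, list(x), function(nd) {
    g <- array(0, dim = dim(x$value))
    g[idx] <- nd$grad
    ag_acc(x, g)
  })
}

# column vector (n x 1) -> n x n diagonal matrix
ag_diag_embed <- function(tape, x) {
  v <- as.vector(x$value)
  ag_node(tape, diag(v, nrow = length(v)), list(x), function(nd) {
    ag_acc(x, matrix(diag(nd$grad), ncol = 1L))
  })
}

ag_softmax_rows <- function(tape, x) {
  z <- x$value - apply(x$value, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  ag_node(tape, y, list(x), function(nd) {
    g <- nd$grad
    ag_acc(x, y * (g - rowSums(g * y)))
  })
}

ag_layernorm_rows <- function(tape, x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2L, as.vector(gamma$value), "*")
  y <- sweep(y, 2L, as.vector(beta$value), "+")
  ag_node(tape, y, list(x, gamma, beta), function(nd) {
    g <- nd$grad
    ag_acc(gamma, matrix(colSums(g * xhat), 1L))
    ag_acc(beta, matrix(colSums(g), 1L))
    dxhat <- sweep(g, 2L, as.vector(gamma$value), "*")
    ag_acc(x, inv_sd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)))
  })
}

# scale * sum((x - target)^2) as a 1x1 scalar node
ag_sum_sq_diff <- function(tape, x, target, scale = 1) {
  d <- x$value - target
  ag_node(tape, matrix(scale * sum(d * d), 1L, 1L), list(x), function(nd) {
    ag_acc(x, as.numeric(nd$grad) * scale * 2 * d)
  })
}

ag_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (ii in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[ii]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}
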