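# Minimal reverse-mode automatic differentiation on matrices.
#
# Internal substrate for the trainable models (feature reduction, transformer
# encoder, gated attention pooling, heads). A tape records nodes in creation
# order; ad_backward() walks it in reverse accumulating gradients. Every value
# is a numeric matrix (scalars are 1 x 1). Verified against central finite
# differences in the test suite.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$n <- 0L
  env
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  stopifnot(is.matrix(value))
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  tape$n <- tape$n + 1L
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_input <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(tape, x)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(node) {
    ad_accum(a, node$grad %*% t(b$value))
    ad_accum(b, t(a$value) %*% node$grad)
  })
}

ad_add <- function(tape, a, b) { # same shape
  ad_node(tape, a$value + b$value, list(a, b), function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, node$grad)
  })
}

ad_add_bias <- function(tape, a, b) { # b: 1 x d row vector broadcast over rows
  ad_node(tape, sweep(a$value, 2, as.vector(b$value), "+"), list(a, b),
          function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, matrix(colSums(node$grad), 1))
  })
}

ad_hadamard <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(node) {
    ad_accum(a, node$grad * b$value)
    ad_accum(b, node$grad * a$value)
  })
}

ad_scale <- function(tape, a, s) { # s: plain scalar constant
  ad_node(tape, a$value * s, list(a), function(node) {
    ad_accum(a, node$grad * s)
  })
}

ad_shift <- function(tape, a, s) { # constant shift
  ad_node(tape, a$value + s, list(a), function(node) ad_accum(a, node$grad))
}

ad_mul_const <- function(tape, a, m) { # elementwise constant mask/matrix
  ad_node(tape, a$value * m, list(a), function(node) {
    ad_accum(a, node$grad * m)
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(node) {
    ad_accum(a, t(node$grad))
  })
}

ad_tanh <- function(tape, a) {
  y <- tanh(a$value)
  ad_node(tape, y, list(a), function(node) {
    ad_accum(a, node$grad * (1 - y^2))
  })
}

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$value))
  ad_node(tape, y, list(a), function(node) {
    ad_accum(a, node$grad * y * (1 - y))
  })
}

ad_relu <- function(tape, a) {
  y <- pmax(a$value, 0)
  ad_node(tape, y, list(a), function(node) {
    ad_accum(a, node$grad * (a$value > 0))
  })
}

ad_exp <- function(tape, a) {
  y <- exp(a$value)
  ad_node(tape, y, list(a), function(node) ad_accum(a, node$grad * y))
}

ad_log <- function(tape, a, eps = 1e-12) {
  v <- pmax(a$value, eps)
  ad_node(tape, log(v), list(a), function(node) {
    ad_accum(a, node$grad / v)
  })
}

# numerically stable softplus: log(1 + exp(x))
ad_softplus <- function(tape, a) {
  x <- a$value
  y <- pmax(x, 0) + log1p(exp(-abs(x)))
  ad_node(tape, y, list(a), function(node) {
    ad_accum(a, node$grad / (1 + exp(-x)))
  })
}

ad_softmax_rows <- function(tape, a) {
  x <- a$value
  x <- x - apply(x, 1, max)
  e <- exp(x)
  p <- e / rowSums(e)
  ad_node(tape, p, list(a), function(node) {
    g <- node$grad
    dot <- rowSums(g * p)
    ad_accum(a, p * (g - dot))
  })
}

# row-wise layer normalization with gain g and bias b (1 x d each)
ad_layernorm <- function(tape, a, g, b, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(as.vector(g$value), each = nrow(x)), 2,
             as.vector(b$value), "+")
  ad_node(tape, y, list(a, g, b), function(node) {
    dy <- node$grad
    gv <- rep(as.vector(g$value), each = nrow(x))
    ad_accum(g, matrix(colSums(dy * xhat), 1))
    ad_accum(b, matrix(colSums(dy), 1))
    dxhat <- dy * gv
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    ad_accum(a, inv * (dxhat - m1 - xhat * m2))
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1, 1), list(a), function(node) {
    ad_accum(a, matrix(node$grad[1, 1], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1, 1), list(a), function(node) {
    ad_accum(a, matrix(node$grad[1, 1] / n, nrow(a$value), ncol(a$value)))
  })
}

ad_rbind <- function(tape, nodes) {
  rows <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ad_node(tape, do.call(rbind, lapply(nodes, function(n) n$value)), nodes,
          function(node) {
    off <- 0L
    for (p in node$parents) {
      nr <- nrow(p$value)
      ad_accum(p, node$grad[off + seq_len(nr), , drop = FALSE])
      off <- off + nr
    }
  })
}

ad_cbind <- function(tape, nodes) {
  ad_node(tape, do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(node) {
    off <- 0L
    for (p in node$parents) {
      nc <- ncol(p$value)
      ad_accum(p, node$grad[, off + seq_len(nc), drop = FALSE])
      off <- off + nc
    }
  })
}

# select rows (constant index); gradient scatters back
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(node) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    # accumulate duplicates correctly
    for (k in seq_along(idx)) g[idx[k], ] <- g[idx[k], ] + node$grad[k, ]
    ad_accum(a, g)
  })
}

# backpropagate from a scalar loss node
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1)
  for (node in tape$nodes) node$grad <- NULL
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
  }
  invisible(NULL)
}
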