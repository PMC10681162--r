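# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape (ad_graph) records nodes in creation order; each node holds its
# value, its parent nodes and a backward closure that accumulates gradients
# into the parents. Backpropagation walks the tape in reverse. Parameters
# are named; ad_grads() sums gradients across all tape occurrences of the
# same parameter name (needed when e.g. an embedding table is gathered from
# several times in one forward pass).
#
# Scalars are 1x1 matrices throughout. Correctness is pinned by the
# finite-difference gradient checks in the test suite.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 1024L)
  g$n <- 0L
  g
}

ad_node <- function(g, value, parents = list(), backward = NULL,
                    param = NA_character_) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$grad <- NULL
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) {
    g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  }
  g$nodes[[g$n]] <- node
  node
}

ad_param <- function(g, value, name) ad_node(g, value, param = name)
ad_const <- function(g, value) ad_node(g, value)

ad_acc <- function(node, d) {
  node$grad <- if (is.null(node$grad)) d else node$grad + d
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the whole tape.
ad_backward <- function(g, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(g$n))) {
    node <- g$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
  }
  invisible(NULL)
}

# Named list of parameter gradients, summed over tape occurrences.
ad_grads <- function(g) {
  out <- list()
  for (i in seq_len(g$n)) {
    node <- g$nodes[[i]]
    if (!is.na(node$param) && !is.null(node$grad)) {
      nm <- node$param
      out[[nm]] <- if (is.null(out[[nm]])) node$grad else out[[nm]] + node$grad
    }
  }
  out
}

ad_matmul <- function(g, a, b) {
  ad_node(g, a$value %*% b$value, list(a, b), function(node) {
    gr <- node$grad
    ad_acc(a, gr %*% t(b$value))
    ad_acc(b, t(a$value) %*% gr)
  })
}

# a + b; b may be a 1 x k bias row broadcast over the rows of a.
ad_add <- function(g, a, b) {
  av <- a$value; bv <- b$value
  broadcast <- nrow(bv) == 1L && nrow(av) > 1L
  val <- if (broadcast) av + rep(bv, each = nrow(av)) else av + bv
  ad_node(g, val, list(a, b), function(node) {
    gr <- node$grad
    ad_acc(a, gr)
    ad_acc(b, if (broadcast) matrix(colSums(gr), 1L) else gr)
  })
}

ad_mul <- function(g, a, b) {
  ad_node(g, a$value * b$value, list(a, b), function(node) {
    gr <- node$grad
    ad_acc(a, gr * b$value)
    ad_acc(b, gr * a$value)
  })
}

ad_scale <- function(g, a, s) {
  ad_node(g, a$value * s, list(a), function(node) ad_acc(a, node$grad * s))
}

ad_tanh <- function(g, a) {
  v <- tanh(a$value)
  ad_node(g, v, list(a), function(node) ad_acc(a, node$grad * (1 - v^2)))
}

ad_sigmoid <- function(g, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(g, v, list(a), function(node) ad_acc(a, node$grad * v * (1 - v)))
}

ad_relu <- function(g, a) {
  v <- pmax(a$value, 0)
  ad_node(g, v, list(a), function(node) ad_acc(a, node$grad * (a$value > 0)))
}

ad_transpose <- function(g, a) {
  ad_node(g, t(a$value), list(a), function(node) ad_acc(a, t(node$grad)))
}

# Row-wise softmax (numerically stabilised).
ad_softmax_rows <- function(g, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(g, p, list(a), function(node) {
    gr <- node$grad
    ad_acc(a, p * (gr - rowSums(gr * p)))
  })
}

# Gather rows (duplicates allowed); gradient scatter-adds.
ad_rows <- function(g, a, idx) {
  idx <- as.integer(idx)
  ad_node(g, a$value[idx, , drop = FALSE], list(a), function(node) {
    d <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(node$grad, group = idx)
    d[as.integer(rownames(agg)), ] <- agg
    ad_acc(a, d)
  })
}

ad_cols <- function(g, a, idx) {
  idx <- as.integer(idx)
  ad_node(g, a$value[, idx, drop = FALSE], list(a), function(node) {
    d <- matrix(0, nrow(a$value), ncol(a$value))
    d[, idx] <- node$grad
    ad_acc(a, d)
  })
}

ad_cbind <- function(g, nodes) {
  widths <- vapply(nodes, function(x) ncol(x$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_node(g, do.call(cbind, lapply(nodes, `[[`, "value")), nodes, function(node) {
    for (k in seq_along(nodes)) {
      ad_acc(nodes[[k]], node$grad[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

ad_rbind <- function(g, nodes) {
  heights <- vapply(nodes, function(x) nrow(x$value), integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_node(g, do.call(rbind, lapply(nodes, `[[`, "value")), nodes, function(node) {
    for (k in seq_along(nodes)) {
      ad_acc(nodes[[k]], node$grad[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

# Batched span max-pooling: spans is a list of integer row-index vectors
# (possibly empty). Row s of the result is the component-wise max over
# x[spans[[s]], ]; an empty span pools to the zero row (the max-pool
# identity under our empty-pool convention) and routes no gradient.
ad_span_maxpool <- function(g, x, spans) {
  H <- ncol(x$value)
  S <- length(spans)
  val <- matrix(0, S, H)
  argm <- matrix(NA_integer_, S, H)
  for (s in seq_len(S)) {
    rows <- spans[[s]]
    if (!length(rows)) next
    sub <- x$value[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    argm[s, ] <- rows[am]
    val[s, ] <- sub[cbind(am, seq_len(H))]
  }
  ad_node(g, val, list(x), function(node) {
    d <- matrix(0, nrow(x$value), H)
    for (s in seq_len(S)) {
      if (is.na(argm[s, 1L])) next
      ij <- cbind(argm[s, ], seq_len(H))
      d[ij] <- d[ij] + node$grad[s, ]
    }
    ad_acc(x, d)
  })
}

# Summed cross-entropy over rows of a logit matrix with integer labels
# (1-based). Returns a 1x1 node; softmax is fused for stability.
ad_ce_sum <- function(g, logits, labels) {
  labels <- as.integer(labels)
  z <- logits$value - apply(logits$value, 1L, max)
  lse <- log(rowSums(exp(z)))
  picked <- z[cbind(seq_along(labels), labels)]
  loss <- sum(lse - picked)
  p <- exp(z - lse)
  ad_node(g, matrix(loss, 1, 1), list(logits), function(node) {
    u <- node$grad[1, 1]
    d <- p
    d[cbind(seq_along(labels), labels)] <- d[cbind(seq_along(labels), labels)] - 1
    ad_acc(logits, u * d)
  })
}

ad_sum <- function(g, a) {
  ad_node(g, matrix(sum(a$value), 1, 1), list(a), function(node) {
    ad_acc(a, matrix(node$grad[1, 1], nrow(a$value), ncol(a$value)))
  })
}

# Central finite-difference gradient of f (params -> scalar) w.r.t. every
# entry of every parameter. Test-suite oracle for the tape.
numeric_grad <- function(f, params, eps = 1e-5) {
  out <- lapply(params, function(p) matrix(0, nrow(p), ncol(p)))
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in seq_along(p)) {
      up <- params; up[[nm]][i] <- p[i] + eps
      dn <- params; dn[[nm]][i] <- p[i] - eps
      out[[nm]][i] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  out
}
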