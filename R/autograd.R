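# Minimal reverse-mode automatic differentiation over base R matrices.
#
# Every value in the graph is a numeric matrix. Nodes are environments holding
# the forward value, an accumulated gradient, their parent nodes and a closure
# that maps the incoming gradient to per-parent gradients. backward() walks an
# iteratively computed topological order, so graph depth (e.g. long recurrent
# chains) is not limited by the C stack.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_node <- function(val, parents = list(), grad_fn = NULL) {
  if (!is.matrix(val)) stop("ag_node: value must be a matrix")
  e <- new.env(parent = emptyenv())
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$grad_fn <- grad_fn
  class(e) <- "ag_node"
  e
}

#' Wrap a constant matrix as an autodiff node
#'
#' Constants take part in forward computation but receive no gradient.
#'
#' @param x numeric matrix (vectors are promoted to one-column matrices).
#' @return an `ag_node`.
#' @keywords internal
ag_const <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ag_node(x)
}

#' Wrap a trainable parameter matrix as an autodiff node
#'
#' @param x numeric matrix.
#' @return an `ag_node` whose `$grad` is populated by [ag_backward()].
#' @keywords internal
ag_param <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- ag_node(x)
  n$is_param <- TRUE
  n
}

ag_val <- function(x) x$val

.ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into every reachable node's `$grad` field.
#'
#' @param root scalar (1x1) `ag_node`.
#' @keywords internal
ag_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  # iterative DFS post-order -> topological order
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- nd
    }
  }
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(ntopo, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$grad_fn) || is.null(nd$grad)) next
    gs <- nd$grad_fn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .ag_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

# ---- primitive ops ---------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), t(a$val) %*% g)
  })
}

ag_transpose <- function(a) {
  ag_node(t(a$val), list(a), function(g) list(t(g)))
}

# b may be a 1 x ncol(a) row vector, broadcast over rows of a (bias add)
ag_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    ag_node(av + rep(bv[1L, ], each = nrow(av)), list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    ag_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

# add a plain numeric constant (same shape or scalar); no gradient to it
ag_addc <- function(a, k) {
  ag_node(a$val + k, list(a), function(g) list(g))
}

ag_emul <- function(a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  ag_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

# elementwise multiply by a plain numeric constant (scalar or same shape)
ag_mulc <- function(a, k) {
  ag_node(a$val * k, list(a), function(g) list(g * k))
}

ag_tanh <- function(a) {
  y <- tanh(a$val)
  ag_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ag_sigmoid <- function(a) {
  y <- stats::plogis(a$val)
  ag_node(y, list(a), function(g) list(g * y * (1 - y)))
}

# exact GELU: x * pnorm(x)
ag_gelu <- function(a) {
  x <- a$val
  ph <- stats::pnorm(x)
  ag_node(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

# row-wise softmax with an additive mask of 0 / -Inf entries.
# Rows whose entries are all masked produce all-zero output.
ag_softmax_rows <- function(a, mask = NULL) {
  z <- a$val
  if (!is.null(mask)) z <- z + mask
  # row maxima without apply(); fully masked rows yield all-zero output
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  ez <- exp(z - m)  # column recycling = per-row subtraction
  den <- rowSums(ez)
  den[den == 0] <- 1
  s <- ez / den
  ag_node(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# row-wise layer normalization with scale gamma (1 x d) and shift beta (1 x d)
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$val[1L, ]
  n <- nrow(x)
  y <- xhat * rep(gv, each = n) + rep(beta$val[1L, ], each = n)
  ag_node(y, list(a, gamma, beta), function(g) {
    gxhat <- g * rep(gv, each = nrow(g))
    gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(gx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

ag_rows <- function(a, idx) {
  ag_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), ncol(a$val))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

ag_cols <- function(a, idx) {
  ag_node(a$val[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), ncol(a$val))
    out[, idx] <- g
    list(out)
  })
}

ag_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$val), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, lapply(nodes, ag_val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_rbind <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$val), 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_node(do.call(rbind, lapply(nodes, ag_val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# embedding lookup: rows of table W (vocab x d) selected by 1-based ids
ag_lookup <- function(W, ids) {
  ag_node(W$val[ids, , drop = FALSE], list(W), function(g) {
    out <- matrix(0, nrow(W$val), ncol(W$val))
    for (k in seq_along(ids)) out[ids[k], ] <- out[ids[k], ] + g[k, ]
    list(out)
  })
}

ag_sum <- function(a) {
  ag_node(matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$val), ncol(a$val)))
  })
}

# inverted dropout; draws its mask from the session RNG when training
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  keep <- matrix(stats::runif(length(a$val)) >= p, nrow(a$val)) / (1 - p)
  ag_mulc(a, keep)
}

# numerically stable mean binary cross-entropy on logits z against labels y
ag_bce_logits <- function(z, y) {
  zv <- z$val
  stopifnot(all(dim(zv) == dim(as.matrix(y))))
  y <- as.matrix(y)
  n <- length(zv)
  softplus <- pmax(zv, 0) + log1p(exp(-abs(zv)))
  val <- sum(softplus - y * zv) / n
  ag_node(matrix(val, 1L, 1L), list(z), function(g) {
    list(g[1L] * (stats::plogis(zv) - y) / n)
  })
}

ag_linear <- function(x, W, b) ag_add(ag_matmul(x, W), b)

# ---- Adam optimizer --------------------------------------------------------

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
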