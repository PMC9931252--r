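# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Both trainable models in the package (the pointer-network segmenter and the
# unit-level self-attention classifier) are small enough that a plain tape of
# matrix operations suffices.  Nodes are environments; parameters are nodes
# reused across forward passes, with gradients accumulated into `$grad` by
# `ad_backward()` and cleared by `ad_zero_grad()`.
#
# Internal API (not exported): the models are the supported surface.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_node <- function(val, parents = list(), backward = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$param <- param
  class(e) <- "ad_node"
  e
}

ad_param <- function(val) ad_node(as.matrix(val), param = TRUE)
ad_const <- function(val) ad_node(as.matrix(val))

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Topological sort (iterative DFS), then reverse sweep.
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  order <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      for (p in top$node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- top$node
    }
  }
  grads <- new.env(parent = emptyenv())
  grads[[as.character(loss$id)]] <- matrix(1, 1, 1)
  for (n in rev(order)) {
    g <- grads[[as.character(n$id)]]
    if (is.null(g)) next
    if (n$param) acc_grad(n, g)
    if (is.null(n$backward)) next
    pg <- n$backward(g)
    for (k in seq_along(n$parents)) {
      if (is.null(pg[[k]])) next
      key <- as.character(n$parents[[k]]$id)
      grads[[key]] <- if (is.null(grads[[key]])) pg[[k]] else grads[[key]] + pg[[k]]
    }
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- operations -----------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(g)
    list(g %*% t(b$val), t(a$val) %*% g))
}

ad_transpose <- function(a) {
  ad_node(t(a$val), list(a), function(g) list(t(g)))
}

# addition with row-vector broadcasting (bias terms)
ad_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, bv[1L, ], `+`)
    ad_node(val, list(a, b), function(g)
      list(g, matrix(colSums(g), 1L)))
  } else {
    ad_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

ad_scale <- function(a, k) {
  ad_node(a$val * k, list(a), function(g) list(g * k))
}

ad_mul <- function(a, b) {
  ad_node(a$val * b$val, list(a, b), function(g)
    list(g * b$val, g * a$val))
}

ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(a) {
  v <- pmax(a$val, 0)
  ad_node(v, list(a), function(g) list(g * (a$val > 0)))
}

ad_softmax_rows <- function(a) {
  m <- a$val - apply(a$val, 1L, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ad_node(v, list(a), function(g)
    list(v * (g - rowSums(g * v))))
}

# gather rows (also used as embedding lookup); scatter-add on backward
ad_rows <- function(a, idx) {
  ad_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), ncol(a$val))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

ad_mean_rows <- function(a) {
  n <- nrow(a$val)
  ad_node(matrix(colMeans(a$val), 1L), list(a), function(g)
    list(matrix(rep(g / n, each = n), n)))
}

ad_rbind <- function(nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ad_node(do.call(rbind, lapply(nodes, `[[`, "val")), nodes, function(g) {
    ends <- cumsum(sizes); starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_along(nodes), function(k)
      g[starts[k]:ends[k], , drop = FALSE])
  })
}

ad_cbind <- function(nodes) {
  sizes <- vapply(nodes, function(n) ncol(n$val), integer(1))
  ad_node(do.call(cbind, lapply(nodes, `[[`, "val")), nodes, function(g) {
    ends <- cumsum(sizes); starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_along(nodes), function(k)
      g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$val), 1L), list(a), function(g)
    list(matrix(g[1L], nrow(a$val), ncol(a$val))))
}

# mean binary cross-entropy from logits; y is a plain numeric vector
ad_bce_with_logits <- function(z, y) {
  zv <- z$val
  stopifnot(ncol(zv) == 1L, length(y) == nrow(zv))
  loss <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  n <- nrow(zv)
  ad_node(matrix(loss, 1L), list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    list(g[1L] * (p - y) / n)
  })
}

# mean softmax cross-entropy; z is n x k logits, target an index vector (1-based)
ad_softmax_ce <- function(z, target) {
  zv <- z$val
  m <- zv - apply(zv, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  n <- nrow(zv)
  picked <- p[cbind(seq_len(n), target)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ad_node(matrix(loss, 1L), list(z), function(g) {
    oh <- matrix(0, n, ncol(zv))
    oh[cbind(seq_len(n), target)] <- 1
    list(g[1L] * (p - oh) / n)
  })
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

adam_step <- function(opt, params, lr = 1e-2, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  opt
}

# Gaussian init scaled by fan-in, deterministic under the caller's seed
init_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}
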