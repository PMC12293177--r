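# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records operation nodes in execution order; ad_backward() walks the
# tape in reverse and accumulates gradients into tracked leaves (parameters).
# Everything is a plain R matrix. Broadcasting in binary elementwise ops is
# limited to the shapes the models need: equal dims, row vector (1 x C),
# column vector (R x 1), and scalar (1 x 1).
#
# Nodes are environments: $val (matrix), $grad (matrix or NULL), $track
# (does anything upstream require gradients), $tape. Only tracked non-leaf
# nodes are pushed onto the tape; constants are free-standing. A tape created
# with grad = FALSE skips all bookkeeping and gives a plain forward pass.

ad_tape <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$grad <- isTRUE(grad)
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

.ad_push <- function(tp, nd) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_const <- function(tp, x) {
  nd <- new.env(parent = emptyenv())
  nd$val <- .as_mat(x)
  nd$grad <- NULL
  nd$track <- FALSE
  nd$tape <- tp
  nd
}

ad_param <- function(tp, x) {
  nd <- new.env(parent = emptyenv())
  nd$val <- .as_mat(x)
  nd$grad <- NULL
  nd$track <- tp$grad
  nd$tape <- tp
  nd
}

.ad_node <- function(tp, val, parents, backward) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$tape <- tp
  track <- FALSE
  if (tp$grad) {
    for (p in parents) if (isTRUE(p$track)) { track <- TRUE; break }
  }
  nd$track <- track
  if (track) {
    nd$parents <- parents
    nd$backward <- backward
    .ad_push(tp, nd)
  }
  nd
}

.ad_acc <- function(p, g) {
  if (isTRUE(p$track)) {
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  invisible(NULL)
}

ad_backward <- function(tp, root) {
  if (!isTRUE(root$track)) {
    stop("backward root does not depend on any tracked parameter")
  }
  if (length(root$val) != 1L) stop("backward root must be scalar")
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- broadcasting helpers -------------------------------------------------

.bc_val <- function(a, b, op) {
  da <- dim(a); db <- dim(b)
  if (da[1L] == db[1L] && da[2L] == db[2L]) return(op(a, b))
  if (db[1L] == 1L && db[2L] == 1L) return(op(a, b[1L]))
  if (da[1L] == 1L && da[2L] == 1L) return(op(a[1L], b))
  if (db[1L] == 1L && db[2L] == da[2L]) {
    return(op(a, matrix(as.vector(b), da[1L], da[2L], byrow = TRUE)))
  }
  if (db[1L] == da[1L] && db[2L] == 1L) return(op(a, as.vector(b)))
  if (da[1L] == 1L && da[2L] == db[2L]) {
    return(op(matrix(as.vector(a), db[1L], db[2L], byrow = TRUE), b))
  }
  if (da[1L] == db[1L] && da[2L] == 1L) return(op(as.vector(a), b))
  stop(sprintf("incompatible shapes %dx%d and %dx%d",
               da[1L], da[2L], db[1L], db[2L]))
}

.bc_reduce <- function(g, dims) {
  dg <- dim(g)
  if (dg[1L] == dims[1L] && dg[2L] == dims[2L]) return(g)
  if (dims[1L] == 1L && dims[2L] == 1L) return(matrix(sum(g), 1L, 1L))
  if (dims[1L] == 1L) return(matrix(colSums(g), 1L))
  matrix(rowSums(g), ncol = 1L)
}

# ---- elementwise binary ops -----------------------------------------------

ad_add <- function(a, b) {
  .ad_node(a$tape, .bc_val(a$val, b$val, `+`), list(a, b), function(nd) {
    .ad_acc(nd$parents[[1L]], .bc_reduce(nd$grad, dim(nd$parents[[1L]]$val)))
    .ad_acc(nd$parents[[2L]], .bc_reduce(nd$grad, dim(nd$parents[[2L]]$val)))
  })
}

ad_sub <- function(a, b) {
  .ad_node(a$tape, .bc_val(a$val, b$val, `-`), list(a, b), function(nd) {
    .ad_acc(nd$parents[[1L]], .bc_reduce(nd$grad, dim(nd$parents[[1L]]$val)))
    .ad_acc(nd$parents[[2L]], -.bc_reduce(nd$grad, dim(nd$parents[[2L]]$val)))
  })
}

ad_mul <- function(a, b) {
  .ad_node(a$tape, .bc_val(a$val, b$val, `*`), list(a, b), function(nd) {
    a <- nd$parents[[1L]]; b <- nd$parents[[2L]]; g <- nd$grad
    .ad_acc(a, .bc_reduce(.bc_val(g, b$val, `*`), dim(a$val)))
    .ad_acc(b, .bc_reduce(.bc_val(g, a$val, `*`), dim(b$val)))
  })
}

ad_div <- function(a, b) {
  v <- .bc_val(a$val, b$val, `/`)
  nd <- .ad_node(a$tape, v, list(a, b), function(nd) {
    a <- nd$parents[[1L]]; b <- nd$parents[[2L]]; g <- nd$grad
    .ad_acc(a, .bc_reduce(.bc_val(g, b$val, `/`), dim(a$val)))
    gb <- -.bc_val(g, nd$val, `*`)
    .ad_acc(b, .bc_reduce(.bc_val(gb, b$val, `/`), dim(b$val)))
  })
  nd
}

ad_scale <- function(a, k) {
  .ad_node(a$tape, a$val * k, list(a), local({
    kk <- k
    function(nd) .ad_acc(nd$parents[[1L]], nd$grad * kk)
  }))
}

# ---- matrix products ------------------------------------------------------

ad_matmul <- function(a, b) {
  .ad_node(a$tape, a$val %*% b$val, list(a, b), function(nd) {
    a <- nd$parents[[1L]]; b <- nd$parents[[2L]]; g <- nd$grad
    .ad_acc(a, tcrossprod(g, b$val))
    .ad_acc(b, crossprod(a$val, g))
  })
}

# a %*% t(b)
ad_matmul_bt <- function(a, b) {
  .ad_node(a$tape, tcrossprod(a$val, b$val), list(a, b), function(nd) {
    a <- nd$parents[[1L]]; b <- nd$parents[[2L]]; g <- nd$grad
    .ad_acc(a, g %*% b$val)
    .ad_acc(b, crossprod(g, a$val))
  })
}

# ---- nonlinearities -------------------------------------------------------

ad_relu <- function(a) {
  v <- a$val
  v[v < 0] <- 0
  .ad_node(a$tape, v, list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad * (nd$val > 0))
  })
}

ad_relu_abs <- function(a) {
  .ad_node(a$tape, abs(a$val), list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad * sign(nd$parents[[1L]]$val))
  })
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  .ad_node(a$tape, v, list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad * nd$val * (1 - nd$val))
  })
}

ad_exp <- function(a) {
  v <- exp(a$val)
  .ad_node(a$tape, v, list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad * nd$val)
  })
}

ad_log <- function(a) {
  .ad_node(a$tape, log(a$val), list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad / nd$parents[[1L]]$val)
  })
}

ad_sqrt <- function(a) {
  v <- sqrt(a$val)
  .ad_node(a$tape, v, list(a), function(nd) {
    .ad_acc(nd$parents[[1L]], nd$grad / (2 * nd$val))
  })
}

ad_clip_min <- function(a, eps) {
  v <- pmax(a$val, eps)
  .ad_node(a$tape, v, list(a), local({
    mask <- a$val > eps
    function(nd) .ad_acc(nd$parents[[1L]], nd$grad * mask)
  }))
}

rowmax <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# row-wise softmax with max-shift
ad_softmax_rows <- function(a) {
  x <- a$val
  e <- exp(x - rowmax(x))
  s <- e / rowSums(e)
  .ad_node(a$tape, s, list(a), function(nd) {
    s <- nd$val; g <- nd$grad
    .ad_acc(nd$parents[[1L]], s * (g - rowSums(g * s)))
  })
}

# row-wise layer normalization with learned gain/offset (1 x d each)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$val
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  nr <- nrow(v); nc <- ncol(v)
  out <- xhat * matrix(as.vector(gamma$val), nr, nc, byrow = TRUE) +
    matrix(as.vector(beta$val), nr, nc, byrow = TRUE)
  .ad_node(x$tape, out, list(x, gamma, beta), local({
    xhat <- xhat; inv <- inv
    function(nd) {
      x <- nd$parents[[1L]]; gamma <- nd$parents[[2L]]; beta <- nd$parents[[3L]]
      g <- nd$grad
      .ad_acc(gamma, matrix(colSums(g * xhat), 1L))
      .ad_acc(beta, matrix(colSums(g), 1L))
      gy <- g * matrix(as.vector(gamma$val), nrow(g), ncol(g), byrow = TRUE)
      m1 <- rowMeans(gy)
      m2 <- rowMeans(gy * xhat)
      .ad_acc(x, inv * (gy - m1 - xhat * m2))
    }
  }))
}

# ---- shape ops ------------------------------------------------------------

ad_concat_cols <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  v <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, 1L)
  .ad_node(nodes[[1L]]$tape, v, nodes, local({
    widths <- widths
    function(nd) {
      off <- 0L
      for (i in seq_along(nd$parents)) {
        w <- widths[i]
        .ad_acc(nd$parents[[i]], nd$grad[, off + seq_len(w), drop = FALSE])
        off <- off + w
      }
    }
  }))
}

ad_slice_cols <- function(a, cols) {
  .ad_node(a$tape, a$val[, cols, drop = FALSE], list(a), local({
    cols <- cols
    function(nd) {
      p <- nd$parents[[1L]]
      g <- matrix(0, nrow(p$val), ncol(p$val))
      g[, cols] <- nd$grad
      .ad_acc(p, g)
    }
  }))
}

# gather by linear index (column-major) into a new nr x nc matrix;
# backward scatter-adds, so repeated indices are fine. With
# permutation = TRUE (each source element used at most once) the backward
# is a plain scatter, which is much cheaper.
ad_gather <- function(a, idx, nr, nc, permutation = FALSE) {
  v <- matrix(a$val[idx], nr, nc)
  .ad_node(a$tape, v, list(a), local({
    idx <- as.vector(idx); permutation <- permutation
    function(nd) {
      p <- nd$parents[[1L]]
      gv <- numeric(length(p$val))
      if (permutation) {
        gv[idx] <- nd$grad
      } else {
        acc <- rowsum(as.vector(nd$grad), idx)
        gv[as.integer(rownames(acc))] <- acc[, 1L]
      }
      .ad_acc(p, matrix(gv, nrow(p$val), ncol(p$val)))
    }
  }))
}

# mean over each segment's block of T consecutive rows: (B*T) x d -> B x d
ad_pool_rows <- function(a, B, T) {
  grp <- rep(seq_len(B), each = T)
  v <- rowsum(a$val, grp) / T
  dimnames(v) <- NULL
  .ad_node(a$tape, v, list(a), local({
    grp <- grp; T <- T
    function(nd) {
      .ad_acc(nd$parents[[1L]], nd$grad[grp, , drop = FALSE] / T)
    }
  }))
}

ad_sum_all <- function(a) {
  .ad_node(a$tape, matrix(sum(a$val), 1L, 1L), list(a), function(nd) {
    p <- nd$parents[[1L]]
    .ad_acc(p, matrix(nd$grad[1L], nrow(p$val), ncol(p$val)))
  })
}

ad_mean_all <- function(a) {
  n <- length(a$val)
  .ad_node(a$tape, matrix(mean(a$val), 1L, 1L), list(a), local({
    n <- n
    function(nd) {
      p <- nd$parents[[1L]]
      .ad_acc(p, matrix(nd$grad[1L] / n, nrow(p$val), ncol(p$val)))
    }
  }))
}

# ---- batched scaled dot-product attention ---------------------------------
#
# q, k, v: (B*T) x d matrices holding B stacked length-T sequences.
# Computes softmax(q_b k_b^T * scale) v_b independently per block b and
# restacks; the per-block loop is compiled (src/attention.cpp). Attention
# maps are kept on the node ($att, a T x T x B array) for diagnostics.
ad_attention <- function(q, k, v, B, T, scale) {
  f <- attention_forward_cpp(q$val, k$val, v$val, B, T, scale)
  nd <- .ad_node(q$tape, f$out, list(q, k, v), local({
    B <- B; T <- T; scale <- scale
    function(nd) {
      q <- nd$parents[[1L]]; k <- nd$parents[[2L]]; v <- nd$parents[[3L]]
      g <- attention_backward_cpp(nd$grad, nd$att, q$val, k$val, v$val,
                                  B, T, scale)
      .ad_acc(q, g$gq); .ad_acc(k, g$gk); .ad_acc(v, g$gv)
    }
  }))
  nd$att <- f$att
  nd
}

# ---- parameter plumbing ---------------------------------------------------

params_to_nodes <- function(tp, params, track = TRUE) {
  if (track) lapply(params, function(p) ad_param(tp, p))
  else lapply(params, function(p) ad_const(tp, p))
}

grads_of <- function(param_nodes) {
  lapply(param_nodes, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$val), ncol(n$val)) else n$grad
  })
}
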