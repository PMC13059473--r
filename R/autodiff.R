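# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Rationale: the training loop needs gradients through convolutions, graph
# attention, cross-attention, LayerNorm and the contrastive objective; no
# deep-learning framework is available in this R stack, and the model sizes
# here (desk-scale pMHC graphs) are tiny, so a tape of matrix ops with
# hand-derived adjoints is sufficient and fully testable (numerical
# gradient checks in the test suite cover every op).
#
# Nodes are environments: $val (matrix), $grad, $bw (adjoint closure),
# $req (participates in backprop). Ops append nodes to a tape in creation
# order, which is a valid topological order, so backward is a single
# reverse sweep. Parameters are off-tape leaves whose $grad accumulates.

.ad <- new.env(parent = emptyenv())
.ad$last <- NULL

# The tape is an intrusive linked list (each node keeps a $prev pointer),
# so pushes are O(1) without copying; creation order is a topological
# order, and backward walks the $prev chain.

#' Reset the autodiff tape (call once per forward pass)
#' @keywords internal
ad_tape_reset <- function() {
  .ad$last <- NULL
  invisible(NULL)
}

.ad_push <- function(node) {
  node$prev <- .ad$last
  .ad$last <- node
  node
}

.ad_node <- function(val, bw = NULL, req = TRUE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$bw <- bw
  e$req <- req
  if (req && !is.null(bw)) .ad_push(e)
  e
}

.ad_accum <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Wrap a constant matrix (no gradient)
#' @param x numeric matrix or vector (vectors become 1-row matrices)
#' @export
ad_const <- function(x) .ad_node(.as_mat(x), req = FALSE)

#' Wrap a trainable parameter matrix
#'
#' Parameter nodes live off-tape and persist across forward passes; their
#' `$grad` field accumulates during [ad_backward()] and is consumed by the
#' optimizer.
#' @param x initial value
#' @param name optional label
#' @export
ad_param <- function(x, name = NULL) {
  e <- .ad_node(.as_mat(x), req = TRUE)
  e$is_param <- TRUE
  e$name <- name
  e
}

#' Node value
#' @param a node
#' @export
ad_value <- function(a) a$val

#' Detach a node from the graph (stop-gradient)
#' @param a node
#' @export
ad_stopgrad <- function(a) ad_const(a$val)

#' Run the reverse sweep from a scalar loss node
#' @param root 1x1 node
#' @export
ad_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  node <- .ad$last
  while (!is.null(node)) {
    if (!is.null(node$grad)) node$bw(node$grad)
    node <- node$prev
  }
  invisible(NULL)
}

#' Clear gradients on a list of parameters
#' @param params list of parameter nodes
#' @export
ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- arithmetic ------------------------------------------------------------

#' Matrix product of two nodes
#' @param a,b nodes with conforming dimensions
#' @export
ad_matmul <- function(a, b) {
  val <- a$val %*% b$val
  .ad_node(val, req = a$req || b$req, bw = function(g) {
    if (a$req) .ad_accum(a, tcrossprod(g, b$val))
    if (b$req) .ad_accum(b, crossprod(a$val, g))
  })
}

# broadcast-aware adjoint reduction: g has dim of the broadcast result
.reduce_to <- function(g, dims) {
  if (identical(dim(g), dims)) return(g)
  if (all(dims == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  if (dims[1L] == 1L && dims[2L] == ncol(g)) {
    return(matrix(colSums(g), 1L))
  }
  stop("internal: unsupported broadcast reduction")
}

.bcast <- function(x, dims) {
  dx <- dim(x)
  if (identical(dx, dims)) return(x)
  if (all(dx == c(1L, 1L))) return(matrix(x[1L], dims[1L], dims[2L]))
  if (dx[1L] == 1L && dx[2L] == dims[2L]) {
    return(matrix(x, dims[1L], dims[2L], byrow = TRUE))
  }
  stop("internal: non-conforming dimensions")
}

#' Elementwise sum of two nodes (second argument may be a 1-row bias or a
#' scalar, broadcast over rows)
#' @param a,b nodes
#' @export
ad_add <- function(a, b) {
  val <- a$val + .bcast(b$val, dim(a$val))
  .ad_node(val, req = a$req || b$req, bw = function(g) {
    if (a$req) .ad_accum(a, g)
    if (b$req) .ad_accum(b, .reduce_to(g, dim(b$val)))
  })
}

#' Elementwise difference (broadcast as in [ad_add()])
#' @param a,b nodes
#' @export
ad_sub <- function(a, b) {
  val <- a$val - .bcast(b$val, dim(a$val))
  .ad_node(val, req = a$req || b$req, bw = function(g) {
    if (a$req) .ad_accum(a, g)
    if (b$req) .ad_accum(b, -.reduce_to(g, dim(b$val)))
  })
}

#' Elementwise (Hadamard) product; second argument broadcastable
#' @param a,b nodes
#' @export
ad_mul <- function(a, b) {
  bb <- .bcast(b$val, dim(a$val))
  val <- a$val * bb
  .ad_node(val, req = a$req || b$req, bw = function(g) {
    if (a$req) .ad_accum(a, g * bb)
    if (b$req) .ad_accum(b, .reduce_to(g * a$val, dim(b$val)))
  })
}

#' Multiply a node elementwise by a constant matrix or scalar
#' @param a node
#' @param m constant
#' @export
ad_cmul <- function(a, m) {
  m <- .bcast(.as_mat(m), dim(a$val))
  .ad_node(a$val * m, req = a$req, bw = function(g) .ad_accum(a, g * m))
}

#' Add a constant matrix or scalar to a node
#' @param a node
#' @param m constant
#' @export
ad_cadd <- function(a, m) {
  m <- .bcast(.as_mat(m), dim(a$val))
  .ad_node(a$val + m, req = a$req, bw = function(g) .ad_accum(a, g))
}

# ---- nonlinearities --------------------------------------------------------

#' ReLU activation
#' @param a node
#' @export
ad_relu <- function(a) {
  mask <- a$val > 0
  .ad_node(a$val * mask, req = a$req, bw = function(g) .ad_accum(a, g * mask))
}

#' Leaky ReLU activation
#' @param a node
#' @param slope negative-part slope (GAT convention 0.2)
#' @export
ad_leaky_relu <- function(a, slope = 0.2) {
  d <- slope + (1 - slope) * (a$val > 0)
  .ad_node(a$val * d, req = a$req, bw = function(g) .ad_accum(a, g * d))
}

#' Logistic sigmoid
#' @param a node
#' @export
ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  .ad_node(s, req = a$req, bw = function(g) .ad_accum(a, g * s * (1 - s)))
}

#' Hyperbolic tangent
#' @param a node
#' @export
ad_tanh <- function(a) {
  s <- tanh(a$val)
  .ad_node(s, req = a$req, bw = function(g) .ad_accum(a, g * (1 - s * s)))
}

#' Elementwise exponential
#' @param a node
#' @export
ad_exp <- function(a) {
  s <- exp(a$val)
  .ad_node(s, req = a$req, bw = function(g) .ad_accum(a, g * s))
}

# ---- reductions & reshaping ------------------------------------------------

#' Sum of all entries (1x1 node)
#' @param a node
#' @export
ad_sum <- function(a) {
  .ad_node(matrix(sum(a$val), 1L, 1L), req = a$req, bw = function(g) {
    .ad_accum(a, matrix(g[1L], nrow(a$val), ncol(a$val)))
  })
}

#' Mean of all entries (1x1 node)
#' @param a node
#' @export
ad_mean <- function(a) {
  n <- length(a$val)
  .ad_node(matrix(mean(a$val), 1L, 1L), req = a$req, bw = function(g) {
    .ad_accum(a, matrix(g[1L] / n, nrow(a$val), ncol(a$val)))
  })
}

#' Column-bind nodes
#' @param ... nodes with equal row counts
#' @export
ad_cbind <- function(...) {
  nodes <- list(...)
  widths <- vapply(nodes, function(n) ncol(n$val), 1L)
  val <- do.call(cbind, lapply(nodes, ad_value))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ad_node(val, req = any(vapply(nodes, function(n) n$req, TRUE)),
           bw = function(g) {
    for (i in seq_along(nodes)) {
      if (nodes[[i]]$req) {
        .ad_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
      }
    }
  })
}

#' Row-bind nodes
#' @param ... nodes with equal column counts
#' @export
ad_rbind <- function(...) {
  nodes <- list(...)
  heights <- vapply(nodes, function(n) nrow(n$val), 1L)
  val <- do.call(rbind, lapply(nodes, ad_value))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  .ad_node(val, req = any(vapply(nodes, function(n) n$req, TRUE)),
           bw = function(g) {
    for (i in seq_along(nodes)) {
      if (nodes[[i]]$req) {
        .ad_accum(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
      }
    }
  })
}

#' Transpose
#' @param a node
#' @export
ad_t <- function(a) {
  .ad_node(t(a$val), req = a$req, bw = function(g) .ad_accum(a, t(g)))
}

#' Select rows by index
#' @param a node
#' @param idx integer row indices (may repeat)
#' @export
ad_rows <- function(a, idx) {
  .ad_node(a$val[idx, , drop = FALSE], req = a$req, bw = function(g) {
    acc <- matrix(0, nrow(a$val), ncol(a$val))
    for (k in seq_along(idx)) {
      acc[idx[k], ] <- acc[idx[k], ] + g[k, ]
    }
    .ad_accum(a, acc)
  })
}

# ---- structured ops --------------------------------------------------------

#' Row-wise softmax restricted to a 0/1 support mask
#'
#' Entries outside the mask get probability 0; rows whose mask is empty
#' stay all-zero (excluded from normalization rather than NaN).
#' @param a node of scores
#' @param mask 0/1 matrix of the same dimension (constant), or NULL for full
#' @export
ad_softmax_row <- function(a, mask = NULL) {
  z <- a$val
  if (!is.null(mask)) z[mask == 0] <- -1e30
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  if (!is.null(mask)) e[mask == 0] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  p <- e / s
  .ad_node(p, req = a$req, bw = function(g) {
    .ad_accum(a, p * (g - rowSums(g * p)))
  })
}

#' Column-wise max pooling over a masked set of rows
#'
#' Returns a 1 x ncol node holding, per column, the maximum over rows with
#' `mask == 1`; gradient routes to the (first) argmax row.
#' @param a node
#' @param mask 0/1 vector over rows; NULL pools all rows
#' @export
ad_maxpool_masked <- function(a, mask = NULL) {
  rows <- if (is.null(mask)) seq_len(nrow(a$val)) else which(mask > 0)
  stopifnot(length(rows) > 0L)
  sub <- a$val[rows, , drop = FALSE]
  arg <- max.col(t(sub), ties.method = "first")
  val <- matrix(sub[cbind(arg, seq_len(ncol(sub)))], 1L)
  .ad_node(val, req = a$req, bw = function(g) {
    acc <- matrix(0, nrow(a$val), ncol(a$val))
    acc[cbind(rows[arg], seq_len(ncol(acc)))] <- g
    .ad_accum(a, acc)
  })
}

#' Column-wise mean over a masked set of rows (1 x ncol node)
#' @param a node
#' @param mask 0/1 vector over rows; NULL pools all rows
#' @export
ad_meanpool_masked <- function(a, mask = NULL) {
  rows <- if (is.null(mask)) seq_len(nrow(a$val)) else which(mask > 0)
  stopifnot(length(rows) > 0L)
  k <- length(rows)
  val <- matrix(colMeans(a$val[rows, , drop = FALSE]), 1L)
  .ad_node(val, req = a$req, bw = function(g) {
    acc <- matrix(0, nrow(a$val), ncol(a$val))
    acc[rows, ] <- matrix(g / k, k, ncol(acc), byrow = TRUE)
    .ad_accum(a, acc)
  })
}

#' Row-wise layer normalization (zero mean, unit variance per row)
#' @param a node
#' @param eps variance floor
#' @export
ad_layernorm_row <- function(a, eps = 1e-5) {
  x <- a$val
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  .ad_node(xhat, req = a$req, bw = function(g) {
    gm <- rowMeans(g)
    gx <- rowMeans(g * xhat)
    .ad_accum(a, inv * (g - gm - xhat * gx))
  })
}

#' Row-wise L2 normalization to unit vectors
#'
#' Zero rows stay zero (their gradient is dropped).
#' @param a node
#' @param eps norm floor
#' @export
ad_l2norm_row <- function(a, eps = 1e-12) {
  x <- a$val
  nrm <- sqrt(rowSums(x * x))
  zero <- nrm < eps
  safe <- pmax(nrm, eps)
  xhat <- x / safe
  xhat[zero, ] <- 0
  .ad_node(xhat, req = a$req, bw = function(g) {
    dot <- rowSums(g * xhat)
    gx <- (g - xhat * dot) / safe
    gx[zero, ] <- 0
    .ad_accum(a, gx)
  })
}

#' Symmetrically degree-normalized adjacency, degrees detached
#'
#' Computes `D_r^{-1/2} A D_c^{-1/2}` where the row/column degrees are
#' taken on `|A|` with an epsilon floor (noise can make entries negative
#' or degrees zero). The degrees are treated as constants in the backward
#' pass; the gradient flows through the elementwise `A` factor only.
#' @param a adjacency node
#' @param eps degree floor
#' @export
ad_gcn_norm <- function(a, eps = 1e-6) {
  A <- a$val
  dr <- 1 / sqrt(pmax(rowSums(abs(A)), eps))
  dc <- 1 / sqrt(pmax(colSums(abs(A)), eps))
  scalemat <- outer(dr, dc)
  .ad_node(A * scalemat, req = a$req,
           bw = function(g) .ad_accum(a, g * scalemat))
}

#' 1-D convolution over sequence positions ("same" zero padding)
#'
#' Implemented as im2col followed by a matrix product, so the adjoints are
#' exact matrix-calculus expressions.
#' @param x node, length x in_channels
#' @param w parameter node, (kernel * in_channels) x out_channels
#' @param b parameter node, 1 x out_channels bias
#' @param kernel odd kernel width
#' @export
ad_conv1d <- function(x, w, b, kernel) {
  stopifnot(kernel %% 2L == 1L)
  L <- nrow(x$val); cin <- ncol(x$val)
  pad <- (kernel - 1L) %/% 2L
  xp <- rbind(matrix(0, pad, cin), x$val, matrix(0, pad, cin))
  cols <- vector("list", kernel)
  for (o in seq_len(kernel)) cols[[o]] <- xp[(o):(o + L - 1L), , drop = FALSE]
  xcol <- do.call(cbind, cols)            # L x (kernel * cin)
  val <- xcol %*% w$val + matrix(b$val, L, ncol(w$val), byrow = TRUE)
  .ad_node(val, req = x$req || w$req || b$req, bw = function(g) {
    if (w$req) .ad_accum(w, crossprod(xcol, g))
    if (b$req) .ad_accum(b, matrix(colSums(g), 1L))
    if (x$req) {
      gcol <- tcrossprod(g, w$val)        # L x (kernel * cin)
      gxp <- matrix(0, L + 2L * pad, cin)
      for (o in seq_len(kernel)) {
        block <- gcol[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
        gxp[(o):(o + L - 1L), ] <- gxp[(o):(o + L - 1L), ] + block
      }
      .ad_accum(x, gxp[(pad + 1L):(pad + L), , drop = FALSE])
    }
  })
}

# ---- optimizer -------------------------------------------------------------

#' One AdamW step over a list of parameter nodes
#'
#' Decoupled weight decay: `p <- p - lr * (mhat / (sqrt(vhat) + eps)
#' + wd * p)`. Parameters with NULL gradients are skipped.
#' @param params list of [ad_param()] nodes
#' @param state optimizer state from a previous call, or NULL to initialize
#' @param lr learning rate
#' @param beta1,beta2 moment decay rates
#' @param eps denominator floor
#' @param weight_decay decoupled decay coefficient
#' @return updated state (keep passing it back in)
#' @export
adamw_step <- function(params, state = NULL, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-2) {
  if (is.null(state)) {
    state <- list(t = 0L,
                  m = lapply(params, function(p) p$val * 0),
                  v = lapply(params, function(p) p$val * 0))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$val)
  }
  state
}
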