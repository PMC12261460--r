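# Minimal reverse-mode automatic differentiation over R matrices.
#
# Every node's backward rule is expressed with the same graph-building
# primitives, so gradients are themselves differentiable graphs and
# higher-order derivatives (double backpropagation through input-gradient
# saliency maps) are exact. Dense linear algebra goes through BLAS (%*%,
# crossprod); the only bespoke kernels are gather/scatter used for im2col
# convolution and pooling.
#
# All values are 2-D double matrices (scalars are 1x1). Node ids increase
# monotonically as the graph is built, so parents always have smaller ids
# than children and reverse-id order is a valid topological order.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L
.ag$cache <- new.env(parent = emptyenv())  # index templates for conv/pool

.ag_next_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

#' @keywords internal
ag_node <- function(value, parents = list(), grad_fn = NULL, requires = NULL) {
  if (is.null(dim(value))) value <- matrix(value, nrow = 1L)
  if (is.null(requires)) {
    requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  }
  node <- new.env(parent = emptyenv())
  node$id <- .ag_next_id()
  node$value <- value
  node$parents <- parents
  node$grad_fn <- grad_fn
  node$requires <- requires
  class(node) <- "ag_node"
  node
}

ag_const <- function(value) ag_node(value, requires = FALSE)
ag_leaf  <- function(value) ag_node(value, requires = TRUE)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

.as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

.is_scalar <- function(x) length(x$value) == 1L

# reduce a gradient to a 1x1 scalar when the forward op broadcast a scalar
.reduce_if_scalar <- function(g, target) if (.is_scalar(target)) ag_sum(g) else g

# ---- elementwise arithmetic (same shape, or one side scalar) ----------------

ag_add <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  v <- if (.is_scalar(b)) a$value + as.vector(b$value) else
       if (.is_scalar(a)) as.vector(a$value) + b$value else a$value + b$value
  ag_node(v, list(a, b), function(g)
    list(.reduce_if_scalar(g, a), .reduce_if_scalar(g, b)))
}

ag_neg <- function(a) {
  a <- .as_node(a)
  ag_node(-a$value, list(a), function(g) list(ag_neg(g)))
}

ag_sub <- function(a, b) ag_add(a, ag_neg(.as_node(b)))

ag_mul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  v <- if (.is_scalar(b)) a$value * as.vector(b$value) else
       if (.is_scalar(a)) as.vector(a$value) * b$value else a$value * b$value
  ag_node(v, list(a, b), function(g)
    list(.reduce_if_scalar(ag_mul(g, b), a),
         .reduce_if_scalar(ag_mul(g, a), b)))
}

ag_div <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  v <- if (.is_scalar(b)) a$value / as.vector(b$value) else
       if (.is_scalar(a)) as.vector(a$value) / b$value else a$value / b$value
  ag_node(v, list(a, b), function(g)
    list(.reduce_if_scalar(ag_div(g, b), a),
         .reduce_if_scalar(ag_neg(ag_div(ag_mul(g, a), ag_mul(b, b))), b)))
}

ag_pow <- function(a, p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  a <- .as_node(a)
  ag_node(a$value^p, list(a), function(g)
    list(ag_mul(g, ag_mul(ag_pow(a, p - 1), p))))
}

ag_sqrt <- function(a) ag_pow(a, 0.5)

ag_exp <- function(a) {
  a <- .as_node(a)
  out <- ag_node(exp(a$value), list(a), NULL)
  out$grad_fn <- function(g) list(ag_mul(g, out))
  out
}

ag_log <- function(a) {
  a <- .as_node(a)
  ag_node(log(a$value), list(a), function(g) list(ag_div(g, a)))
}

# |x| and relu use the sign/indicator of the forward value as a constant:
# correct almost everywhere, second derivative zero (as in standard frameworks)
ag_abs <- function(a) {
  a <- .as_node(a)
  s <- ag_const(sign(a$value))
  ag_node(abs(a$value), list(a), function(g) list(ag_mul(g, s)))
}

ag_relu <- function(a) {
  a <- .as_node(a)
  m <- ag_const((a$value > 0) * 1)
  ag_node(pmax(a$value, 0), list(a), function(g) list(ag_mul(g, m)))
}

# ---- reductions and broadcasts ---------------------------------------------

ag_sum <- function(a) {
  a <- .as_node(a)
  d <- dim(a$value)
  ag_node(matrix(sum(a$value), 1L, 1L), list(a),
          function(g) list(ag_bcast(g, d)))
}

ag_bcast <- function(g, d) {
  g <- .as_node(g)
  stopifnot(length(g$value) == 1L)
  ag_node(matrix(as.vector(g$value), d[1L], d[2L]), list(g),
          function(out_g) list(ag_sum(out_g)))
}

ag_mean <- function(a) {
  a <- .as_node(a)
  ag_mul(ag_sum(a), 1 / length(a$value))
}

ag_colsums <- function(a) {
  a <- .as_node(a)
  n <- nrow(a$value)
  ag_node(matrix(colSums(a$value), nrow = 1L), list(a),
          function(g) list(ag_bcast_rows(g, n)))
}

ag_bcast_rows <- function(g, n) {
  g <- .as_node(g)   # 1 x d -> n x d
  d <- ncol(g$value)
  ag_node(matrix(as.vector(g$value), n, d, byrow = TRUE), list(g),
          function(out_g) list(ag_colsums(out_g)))
}

ag_rowsums <- function(a) {
  a <- .as_node(a)
  d <- ncol(a$value)
  ag_node(matrix(rowSums(a$value), ncol = 1L), list(a),
          function(g) list(ag_bcast_cols(g, d)))
}

ag_bcast_cols <- function(g, d) {
  g <- .as_node(g)   # n x 1 -> n x d
  n <- nrow(g$value)
  ag_node(matrix(as.vector(g$value), n, d), list(g),
          function(out_g) list(ag_rowsums(out_g)))
}

# ---- linear algebra ---------------------------------------------------------

ag_mm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- .as_node(a); b <- .as_node(b)
  stopifnot(!(ta && tb))
  v <- if (ta) crossprod(a$value, b$value)
       else if (tb) tcrossprod(a$value, b$value)
       else a$value %*% b$value
  grad_fn <- if (!ta && !tb) {
    function(g) list(ag_mm(g, b, tb = TRUE), ag_mm(a, g, ta = TRUE))
  } else if (ta) {
    function(g) list(ag_mm(b, g, tb = TRUE), ag_mm(a, g))
  } else {
    function(g) list(ag_mm(g, b), ag_mm(g, a, ta = TRUE))
  }
  ag_node(v, list(a, b), grad_fn)
}

ag_t <- function(a) {
  a <- .as_node(a)
  ag_node(t(a$value), list(a), function(g) list(ag_t(g)))
}

ag_reshape <- function(a, d) {
  a <- .as_node(a)
  old <- dim(a$value)
  v <- a$value
  dim(v) <- d
  ag_node(v, list(a), function(g) list(ag_reshape(g, old)))
}

# bias add: M (n x d) + row vector (1 x d)
ag_add_bias <- function(m, b) {
  m <- .as_node(m); b <- .as_node(b)
  ag_node(m$value + rep(as.vector(b$value), each = nrow(m$value)),
          list(m, b), function(g) list(g, ag_colsums(g)))
}

# ---- gather / scatter (mutually adjoint linear maps) ------------------------
# idx indexes into the flattened source; idx == 0 yields 0 (zero padding).

ag_gather <- function(x, idx, out_dim) {
  x <- .as_node(x)
  src_dim <- dim(x$value)
  clamped <- attr(idx, "clamped")
  v <- if (!is.null(clamped)) {
    # template-precomputed variant: zeros clamped to 1, then zeroed again
    vv <- x$value[clamped]
    zp <- attr(idx, "zpos")
    if (length(zp)) vv[zp] <- 0
    vv
  } else if (isTRUE(attr(idx, "nozero"))) {
    if (max(idx) > length(x$value)) stop("ag_gather: index out of bounds")
    x$value[idx]
  } else {
    if (length(idx) && max(idx) > length(x$value))
      stop("ag_gather: index out of bounds")
    vv <- numeric(length(idx))
    p <- idx > 0L
    vv[p] <- x$value[idx[p]]
    vv
  }
  dim(v) <- out_dim
  ag_node(v, list(x), function(g) list(ag_scatter(g, idx, src_dim)))
}

# Scatter plans (attribute "plan" on idx) avoid the generic grouped-sum:
#   "perm":  targets are distinct -> direct indexed assignment
#   "bycol": idx viewed as a matrix of `plan_cols` columns, each column's
#            targets distinct (im2col: one kernel offset x channel per
#            column) -> one vectorized += per column
ag_scatter <- function(g, idx, out_dim) {
  g <- .as_node(g)
  gd <- dim(g$value)
  plan <- attr(idx, "plan")
  v <- numeric(prod(out_dim))
  gv <- as.vector(g$value)
  if (identical(plan, "perm")) {
    p <- idx > 0L
    v[idx[p]] <- gv[p]
  } else if (identical(plan, "bycol")) {
    tg <- attr(idx, "col_targets")
    sr <- attr(idx, "col_src")
    for (j in seq_along(tg)) {
      ii <- tg[[j]]
      v[ii] <- v[ii] + gv[sr[[j]]]
    }
  } else {
    p <- idx > 0L
    if (any(p)) {
      acc <- rowsum(gv[p], idx[p])
      v[as.integer(rownames(acc))] <- acc
    }
  }
  dim(v) <- out_dim
  ag_node(v, list(g), function(out_g) list(ag_gather(out_g, idx, gd)))
}

# ---- softmax cross-entropy --------------------------------------------------
# logits: n x C; labels: integer vector in 1..C. reduce: "mean" or "sum".

ag_cross_entropy <- function(logits, labels, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  logits <- .as_node(logits)
  n <- nrow(logits$value); C <- ncol(logits$value)
  stopifnot(length(labels) == n, all(labels >= 1L), all(labels <= C))
  m <- matrixStats::rowMaxs(logits$value)                 # detached shift
  shifted <- ag_sub(logits, ag_const(matrix(m, n, C)))
  ez <- ag_exp(shifted)
  lse <- ag_log(ag_rowsums(ez))                           # n x 1
  idx <- seq_len(n) + (as.integer(labels) - 1L) * n
  attr(idx, "plan") <- "perm"
  attr(idx, "nozero") <- TRUE
  z_true <- ag_gather(shifted, idx, c(n, 1L))
  ce <- ag_sub(lse, z_true)                               # per-sample CE
  if (reduce == "mean") ag_mean(ce) else ag_sum(ce)
}

# ---- backward ---------------------------------------------------------------

#' Reverse-mode gradients of a scalar node
#'
#' @param out scalar `ag_node` (1x1).
#' @param wrt list of nodes to differentiate with respect to.
#' @param create_graph unused switch kept for API clarity; gradients are
#'   always built as graph nodes and can be differentiated again.
#' @return list of gradient nodes aligned with `wrt` (zero matrices where
#'   `out` does not depend on the node).
#' @keywords internal
ag_grad <- function(out, wrt, create_graph = FALSE) {
  stopifnot(inherits(out, "ag_node"), length(out$value) == 1L)
  # collect reachable nodes that require grad
  seen <- new.env(parent = emptyenv())
  stack <- list(out)
  nodes <- vector("list", 256L); nn <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    if (!nd$requires) next
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(nd) nd$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]

  grads <- new.env(parent = emptyenv())
  grads[[as.character(out$id)]] <- ag_const(matrix(1, 1L, 1L))
  for (nd in nodes) {
    g <- grads[[as.character(nd$id)]]
    if (is.null(g) || is.null(nd$grad_fn)) next
    pg <- nd$grad_fn(g)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires || is.null(pg[[i]])) next
      key <- as.character(p$id)
      prev <- grads[[key]]
      grads[[key]] <- if (is.null(prev)) pg[[i]] else ag_add(prev, pg[[i]])
    }
  }
  lapply(wrt, function(w) {
    g <- grads[[as.character(w$id)]]
    if (is.null(g)) ag_const(array(0, dim(w$value))) else g
  })
}

# ---- cached index templates -------------------------------------------------

.ag_cache_get <- function(key, builder) {
  v <- .ag$cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .ag$cache[[key]] <- v
  }
  v
}

# im2col indices for 1-D convolution with 'same' padding.
# Input x: (B*L) x Cin matrix, rows ordered (b-1)*L + l.
# Output: (B*Lo) x (k*Cin) index matrix into flattened x; 0 = zero pad.
# Column order matches kernel rows ordered (kk, c): row kk + (c-1)*k.
.conv_idx <- function(B, L, Cin, k, stride) {
  key <- paste("conv", B, L, Cin, k, stride, sep = "_")
  .ag_cache_get(key, function() {
    Lo <- ceiling(L / stride)
    pad <- (k - 1L) %/% 2L
    b  <- rep(seq_len(B), each = Lo)          # over output rows
    lo <- rep(seq_len(Lo), times = B)
    base <- matrix(0L, B * Lo, k)             # row into x, 0 = out of range
    for (kk in seq_len(k)) {
      l <- (lo - 1L) * stride + kk - pad      # 1-based input position
      valid <- l >= 1L & l <= L
      v <- integer(B * Lo)
      v[valid] <- ((b - 1L) * L + l)[valid]
      base[, kk] <- v
    }
    nr <- nrow(base)
    iv <- integer(nr * k * Cin)
    col_targets <- vector("list", k * Cin)
    col_src <- vector("list", k * Cin)
    for (c in seq_len(Cin)) {
      off_ch <- (c - 1L) * (B * L)
      for (kk in seq_len(k)) {
        j <- kk + (c - 1L) * k
        col <- base[, kk]
        valid <- col > 0L
        col[valid] <- col[valid] + off_ch
        iv[((j - 1L) * nr + 1L):(j * nr)] <- col
        col_targets[[j]] <- col[valid]
        col_src[[j]] <- (j - 1L) * nr + which(valid)
      }
    }
    zp <- which(iv == 0L)
    if (length(zp)) {
      cl <- iv
      cl[zp] <- 1L
      attr(iv, "clamped") <- cl
      attr(iv, "zpos") <- zp
    } else {
      attr(iv, "nozero") <- TRUE
    }
    attr(iv, "plan") <- "bycol"
    attr(iv, "col_targets") <- col_targets
    attr(iv, "col_src") <- col_src
    list(idx = iv, dim = c(B * Lo, k * Cin), Lo = Lo)
  })
}

# 1-D convolution ('same' padding): x (B*L x Cin), W (k*Cin x Cout), b (1 x Cout)
ag_conv1d <- function(x, W, bias, B, L, k, stride = 1L) {
  Cin <- ncol(ag_value(x))
  tmpl <- .conv_idx(B, L, Cin, k, stride)
  cols <- ag_gather(x, tmpl$idx, tmpl$dim)
  out <- ag_add_bias(ag_mm(cols, W), bias)
  list(out = out, L = tmpl$Lo)
}

# max pooling over the (position x channel) plane of a conv activation.
# x: (B*L) x C; window (wl, wc), stride equal to window. Argmax indices come
# from the forward values (constant), so the op is a gather.
ag_maxpool2d <- function(x, B, L, wl, wc) {
  xv <- ag_value(x)
  C <- ncol(xv)
  Lp <- L %/% wl; Cp <- C %/% wc
  stopifnot(Lp >= 1L, Cp >= 1L)
  key <- paste("maxpool", B, L, C, wl, wc, sep = "_")
  LIN <- .ag_cache_get(key, function() {
    # candidate source indices: one column per in-window offset, rows
    # ordered lp fastest, then cp, then b
    b  <- rep(seq_len(B), each = Lp * Cp)
    lp <- rep(rep(seq_len(Lp), times = Cp), times = B)
    cp <- rep(rep(seq_len(Cp), each = Lp), times = B)
    m <- matrix(0L, B * Lp * Cp, wl * wc)
    col <- 0L
    for (j in seq_len(wc)) {
      cc <- (cp - 1L) * wc + j
      base <- (cc - 1L) * (B * L) + (b - 1L) * L
      for (i in seq_len(wl)) {
        col <- col + 1L
        m[, col] <- base + (lp - 1L) * wl + i
      }
    }
    m
  })
  vals <- matrix(xv[LIN], nrow = nrow(LIN))
  best <- max.col(vals, ties.method = "first")
  best_idx <- LIN[cbind(seq_len(nrow(LIN)), best)]
  attr(best_idx, "plan") <- "perm"   # pool windows are disjoint
  attr(best_idx, "nozero") <- TRUE
  out <- ag_gather(x, best_idx, c(B * Lp * Cp, 1L))
  list(out = out, n_flat = Lp * Cp)
}

# flatten a (B*Lp*Cp) x 1 pooled tensor (order lp fastest, then cp, then b)
# into (B, Lp*Cp): linear index of (b, f) target (col-major) = b + (f-1)*B;
# source = (b-1)*Lp*Cp + f. Pure permutation -> gather.
ag_pool_flatten <- function(x, B, n_flat) {
  key <- paste("poolflat", B, n_flat, sep = "_")
  idx <- .ag_cache_get(key, function() {
    b <- rep(seq_len(B), times = n_flat)
    f <- rep(seq_len(n_flat), each = B)
    iv <- as.integer((b - 1L) * n_flat + f)
    attr(iv, "plan") <- "perm"
    attr(iv, "nozero") <- TRUE
    iv
  })
  ag_gather(x, idx, c(B, n_flat))
}

# global max over positions: x (B*L x C) -> (B x C); argmax via gather
ag_global_maxpool <- function(x, B, L) {
  xv <- ag_value(x)
  C <- ncol(xv)
  M <- matrix(xv, nrow = L)                  # columns ordered (b, c)
  j <- max.col(t(M), ties.method = "first")  # argmax position per (b, c)
  idx <- as.integer((seq_len(B * C) - 1L) * L + j)
  attr(idx, "plan") <- "perm"
  attr(idx, "nozero") <- TRUE
  ag_reshape(ag_gather(x, idx, c(B * C, 1L)), c(B, C))
}

# global average over positions: x (B*L x C) -> (B x C)
ag_global_avgpool <- function(x, B, L) {
  C <- ncol(ag_value(x))
  s <- ag_colsums(ag_reshape(x, c(L, B * C)))   # 1 x (B*C), order (b, c)
  ag_mul(ag_reshape(s, c(B, C)), 1 / L)
}

# linear interpolation matrix mapping a length-Lsrc grid onto length-Lout
# (align cell centers); used to resize activation maps to input length.
interp_matrix <- function(Lsrc, Lout) {
  R <- matrix(0, Lsrc, Lout)
  for (t in seq_len(Lout)) {
    s <- (t - 0.5) * Lsrc / Lout + 0.5
    lo <- floor(s); hi <- lo + 1
    w <- s - lo
    lo <- min(max(lo, 1), Lsrc); hi <- min(max(hi, 1), Lsrc)
    R[lo, t] <- R[lo, t] + (1 - w)
    R[hi, t] <- R[hi, t] + w
  }
  R
}
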