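# Minimal reverse-mode automatic differentiation over 5-axis feature volumes.
#
# Feature volumes follow the axis order (N, T, C, H, W): batch, frames,
# channels, height, width. A "tensor" is an environment holding a numeric
# array (`value`), an accumulated gradient (`grad`), and — for non-leaf nodes —
# the parent tensors plus a backward closure. Each differentiable operation
# appends its node to a global tape; ag_backward() walks the tape in reverse.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$grad_enabled <- FALSE
.ag$training <- FALSE

#' Create a tensor leaf
#'
#' Wraps a numeric array as an autograd leaf. Parameters of trainable layers
#' are tensors with `requires_grad = TRUE`; their `grad` field is accumulated
#' by [ag_backward()].
#'
#' @param value Numeric array (any shape; 5-axis `(N,T,C,H,W)` for feature
#'   volumes).
#' @param requires_grad Should gradients be accumulated into this leaf?
#' @return An object of class `ag_tensor`.
#' @export
ag_tensor <- function(value, requires_grad = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires_grad <- requires_grad
  node$parents <- list()
  node$backfn <- NULL
  class(node) <- "ag_tensor"
  node
}

is_ag_tensor <- function(x) inherits(x, "ag_tensor")

as_ag <- function(x) if (is_ag_tensor(x)) x else ag_tensor(x)

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) paste0("len ", length(x$value)) else
    paste(d, collapse = "x"),
    if (isTRUE(x$requires_grad)) "(parameter)" else "", ">\n")
  invisible(x)
}

# Register an op node on the tape. backfn(g) must return a list of gradients
# aligned with `parents` (NULL entries allowed for non-differentiable inputs).
ag_op <- function(value, parents, backfn) {
  track <- .ag$grad_enabled &&
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  node <- ag_tensor(value, requires_grad = track)
  if (track) {
    node$parents <- parents
    node$backfn <- backfn
    .ag$tape[[length(.ag$tape) + 1L]] <- node
  }
  node
}

#' Run an expression with gradient recording enabled
#'
#' Clears the tape, evaluates `expr` while recording operations, and leaves
#' the tape in place for a subsequent [ag_backward()] call.
#'
#' @param expr Expression building the computation graph.
#' @return The value of `expr`.
#' @export
ag_with_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$tape <- list()
  .ag$grad_enabled <- TRUE
  on.exit(.ag$grad_enabled <- old)
  expr
}

#' Run an expression without gradient recording
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  expr
}

#' Toggle training mode
#'
#' Training mode switches batch normalization to batch statistics and enables
#' dropout; evaluation mode uses running statistics and is deterministic.
#'
#' @param on Logical.
#' @return The previous mode, invisibly.
#' @export
ag_set_training <- function(on = TRUE) {
  old <- .ag$training
  .ag$training <- isTRUE(on)
  invisible(old)
}

ag_is_training <- function() .ag$training

accumulate_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Reverse-mode backward pass
#'
#' Seeds the gradient of `root` (a scalar loss unless `seed` is given) and
#' propagates through the recorded tape, accumulating gradients into every
#' reachable leaf with `requires_grad = TRUE`. The tape is cleared afterwards.
#'
#' @param root Tensor whose gradient seeds the pass.
#' @param seed Gradient array to seed with; defaults to 1 (scalar root).
#' @return Invisibly, `root`.
#' @export
ag_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$value))) rep(1, length(root$value)) else
      array(1, dim(root$value))
  }
  accumulate_grad(root, seed)
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (isTRUE(p$requires_grad) && !is.null(gs[[j]])) accumulate_grad(p, gs[[j]])
    }
    # free intermediate gradients as soon as they are consumed, unless the
    # caller asked to inspect them (node$retain, used by the CAM machinery)
    if (!isTRUE(node$retain)) node$grad <- NULL
  }
  .ag$tape <- list()
  invisible(root)
}

# ---- shape helpers ---------------------------------------------------------

# Expand singleton axes of `a` to `td` by index replication.
bcast <- function(a, td) {
  da <- dim(a)
  if (identical(as.integer(da), as.integer(td))) return(a)
  idx <- lapply(seq_along(td), function(i) {
    if (da[i] == td[i]) seq_len(td[i]) else rep(1L, td[i])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Sum over one axis, keeping it as extent 1. Order of remaining axes is kept.
sum_axis <- function(g, ax) {
  d <- dim(g)
  if (d[ax] == 1L) return(g)
  perm <- c(ax, setdiff(seq_along(d), ax))
  s <- colSums(matrix(aperm(g, perm), nrow = d[ax]))
  array(s, dim = replace(d, ax, 1L))
}

# Reduce `g` to target dims `td` by summing over axes where td == 1.
sum_to <- function(g, td) {
  d <- dim(g)
  for (ax in which(td == 1L & d > 1L)) g <- sum_axis(g, ax)
  g
}

# ---- elementwise ops -------------------------------------------------------

#' @rdname ag_ops
#' @export
ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

#' @rdname ag_ops
#' @export
ag_sub <- function(a, b) {
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

#' Differentiable array operations
#'
#' Elementwise and structural operations on [ag_tensor()] values:
#' addition/subtraction, broadcast multiplication (`ag_mul`; singleton axes of
#' either operand broadcast against the other), rectifier, logistic sigmoid,
#' scaling, axis means, time slicing/padding, channel concatenation, global
#' average pooling and affine (fully connected) maps.
#'
#' @param a,b,x Input tensors.
#' @param k Numeric scalar.
#' @param lo,hi Clamp bounds.
#' @param axes Integer vector of axes to reduce (kept as extent 1).
#' @param from,to Inclusive frame range.
#' @param n_pad Number of zero frames appended.
#' @param w,bias Affine parameters (`w`: features x units, `bias`: units).
#' @param p Dropout probability.
#' @name ag_ops
#' @return An `ag_tensor`.
#' @export
ag_mul <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  td <- pmax(da, db)
  av <- bcast(a$value, td); bv <- bcast(b$value, td)
  ag_op(av * bv, list(a, b), function(g) {
    list(sum_to(g * bv, da), sum_to(g * av, db))
  })
}

#' @rdname ag_ops
#' @export
ag_relu <- function(x) {
  m <- x$value > 0
  ag_op(x$value * m, list(x), function(g) list(g * m))
}

#' @rdname ag_ops
#' @export
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

#' @rdname ag_ops
#' @export
ag_clamp <- function(x, lo, hi) {
  inside <- x$value > lo & x$value < hi
  v <- pmin(pmax(x$value, lo), hi)
  if (!is.null(dim(x$value))) dim(v) <- dim(x$value)
  ag_op(v, list(x), function(g) list(g * inside))
}

#' @rdname ag_ops
#' @export
ag_scale <- function(x, k) {
  ag_op(x$value * k, list(x), function(g) list(g * k))
}

#' @rdname ag_ops
#' @export
ag_mean_axes <- function(x, axes) {
  d <- dim(x$value)
  v <- x$value
  for (ax in axes) v <- sum_axis(v, ax)
  cnt <- prod(d[axes])
  v <- v / cnt
  ag_op(v, list(x), function(g) list(bcast(g, d) / cnt))
}

#' @rdname ag_ops
#' @export
ag_time_slice <- function(x, from, to) {
  d <- dim(x$value)
  v <- x$value[, from:to, , , , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, from:to, , , ] <- g
    list(gx)
  })
}

#' @rdname ag_ops
#' @export
ag_time_pad_end <- function(x, n_pad) {
  d <- dim(x$value)
  dn <- replace(d, 2L, d[2L] + as.integer(n_pad))
  v <- array(0, dn)
  v[, seq_len(d[2L]), , , ] <- x$value
  ag_op(v, list(x), function(g) list(g[, seq_len(d[2L]), , , , drop = FALSE]))
}

#' @rdname ag_ops
#' @export
ag_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  if (!identical(da[-3L], db[-3L])) {
    ax <- which(da[-3L] != db[-3L])[1]
    nm <- c("batch (N)", "time (T)", "height (H)", "width (W)")[ax]
    stop(sprintf("channel concatenation: %s extents disagree (%s vs %s)",
                 nm, paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  dn <- replace(da, 3L, da[3L] + db[3L])
  v <- array(0, dn)
  v[, , seq_len(da[3L]), , ] <- a$value
  v[, , da[3L] + seq_len(db[3L]), , ] <- b$value
  ag_op(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3L]), , , drop = FALSE],
         g[, , da[3L] + seq_len(db[3L]), , , drop = FALSE])
  })
}

#' @rdname ag_ops
#' @export
ag_global_pool <- function(x) {
  # (N,T,C,H,W) -> (N,C) mean over T,H,W
  d <- dim(x$value)
  v <- x$value
  for (ax in c(2L, 4L, 5L)) v <- sum_axis(v, ax)
  cnt <- prod(d[c(2L, 4L, 5L)])
  v <- matrix(v / cnt, nrow = d[1L], ncol = d[3L])
  ag_op(v, list(x), function(g) {
    list(bcast(array(g, c(d[1L], 1L, d[3L], 1L, 1L)), d) / cnt)
  })
}

#' @rdname ag_ops
#' @export
ag_concat_cols <- function(a, b) {
  na <- ncol(a$value)
  ag_op(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

#' @rdname ag_ops
#' @export
ag_linear <- function(x, w, bias = NULL) {
  v <- x$value %*% w$value
  if (!is.null(bias)) v <- sweep(v, 2L, bias$value, `+`)
  parents <- c(list(x, w), if (!is.null(bias)) list(bias))
  ag_op(v, parents, function(g) {
    gs <- list(g %*% t(w$value), crossprod(x$value, g))
    if (!is.null(bias)) gs <- c(gs, list(colSums(g)))
    gs
  })
}

#' @rdname ag_ops
#' @export
ag_dropout <- function(x, p = 0.5) {
  if (!ag_is_training() || p <= 0) return(x)
  m <- array((stats::runif(length(x$value)) >= p) / (1 - p),
             dim(x$value) %||% length(x$value))
  ag_op(x$value * m, list(x), function(g) list(g * m))
}

#' Grouped 3D convolution (differentiable)
#'
#' Applies a grouped 3D convolution over a `(N,T,C,H,W)` volume with weights
#' `(C_out, C_in/groups, kt, kh, kw)`. Backward computes input and weight
#' gradients through compiled im2col/col2im kernels.
#'
#' @param x Input tensor `(N,T,C,H,W)`.
#' @param w Weight tensor.
#' @param stride,pad Length-3 integer vectors `(time, height, width)`.
#' @param groups Number of channel groups (`C_in` for depthwise).
#' @return Output tensor `(N,T',C_out,H',W')`.
#' @export
ag_conv3d <- function(x, w, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L),
                      groups = 1L) {
  stride <- as.integer(stride); pad <- as.integer(pad)
  v <- conv3d_fwd_cpp(x$value, w$value, stride, pad, as.integer(groups))
  xv <- x$value; wv <- w$value
  need_gx <- isTRUE(x$requires_grad); need_gw <- isTRUE(w$requires_grad)
  ag_op(v, list(x, w), function(g) {
    r <- conv3d_bwd_cpp(xv, wv, g, stride, pad, as.integer(groups),
                        need_gx, need_gw)
    list(if (need_gx) r$gx, if (need_gw) r$gw)
  })
}

#' Softmax cross-entropy over logits
#'
#' Computes the mean cross-entropy loss `-(1/N) sum_i sum_c y_ic log(p_ic)`
#' where `p` is the row-softmax of the logits, with probabilities clamped at
#' `1e-12` before the logarithm.
#'
#' @param logits Tensor of shape `(N, M)`.
#' @param y One-hot label matrix `(N, M)`.
#' @return Scalar loss tensor.
#' @export
ag_softmax_xent <- function(logits, y) {
  z <- logits$value
  z <- z - apply(z, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  n <- nrow(z)
  loss <- -sum(y * log(pmax(p, 1e-12))) / n
  ag_op(loss, list(logits), function(g) list(g * (p - y) / n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
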