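# Trainable layer containers. A "module" is an environment with, at least,
# a `forward` closure, a `params` list of ag_tensor parameters, and a
# `modules` list of sub-modules; parameters are collected recursively.

new_module <- function(.class, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  stopifnot(all(nzchar(names(fields))))
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  if (is.null(m$params)) m$params <- list()
  if (is.null(m$modules)) m$modules <- list()
  class(m) <- c(.class, "x3d_module")
  m
}

#' Collect the parameters of a module tree
#'
#' @param m A module (conv block, pathway, full model, ...).
#' @return Named list of `ag_tensor` parameters; names encode the module path.
#' @export
module_params <- function(m) {
  out <- m$params
  if (length(out)) names(out) <- paste0(m$name %||% class(m)[1], ".", names(out))
  for (i in seq_along(m$modules)) {
    sub <- module_params(m$modules[[i]])
    if (length(sub)) {
      pre <- names(m$modules)[i]
      if (is.null(pre) || is.na(pre) || !nzchar(pre)) pre <- as.character(i)
      names(sub) <- paste0(pre, "/", names(sub))
      out <- c(out, sub)
    }
  }
  out
}

# Running (non-trainable) state such as batch-norm statistics, collected with
# the same path naming as module_params().
module_buffers <- function(m) {
  out <- m$buffers %||% list()
  if (length(out)) names(out) <- paste0(m$name %||% class(m)[1], ".", names(out))
  for (i in seq_along(m$modules)) {
    sub <- module_buffers(m$modules[[i]])
    if (length(sub)) {
      pre <- names(m$modules)[i]
      if (is.null(pre) || is.na(pre) || !nzchar(pre)) pre <- as.character(i)
      names(sub) <- paste0(pre, "/", names(sub))
      out <- c(out, sub)
    }
  }
  out
}

#' Count learnable parameters
#'
#' @param m Module.
#' @param weights_only Count only convolution/affine weights, excluding
#'   normalization scales/offsets and bias vectors.
#' @return Integer count.
#' @export
n_params <- function(m, weights_only = FALSE) {
  ps <- module_params(m)
  if (weights_only) {
    keep <- grepl("(^|\\.)(w|weight)$", names(ps))
    ps <- ps[keep]
  }
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

#' @export
print.x3d_module <- function(x, ...) {
  cat("<", class(x)[1], "> ", format(n_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# He-normal initialization for a conv weight (C_out, C_in/g, kt, kh, kw).
init_conv_weight <- function(c_out, c_in_g, kernel, gain = 2) {
  fan_in <- c_in_g * prod(kernel)
  array(stats::rnorm(c_out * c_in_g * prod(kernel), sd = sqrt(gain / fan_in)),
        dim = c(c_out, c_in_g, kernel))
}

#' 3D convolution layer
#'
#' @param c_in,c_out Channel extents.
#' @param kernel Length-3 kernel extents `(kt, kh, kw)`.
#' @param stride Length-3 strides.
#' @param pad Length-3 padding; `"same"` pads `(k-1)/2` (odd kernels).
#' @param groups Channel groups.
#' @param bias Add a per-channel bias? Disabled by default: convolutions here
#'   are followed by normalization.
#' @return Module with a `forward(x)` closure.
#' @export
layer_conv3d <- function(c_in, c_out, kernel = c(3, 3, 3),
                         stride = c(1, 1, 1), pad = "same", groups = 1L,
                         bias = FALSE) {
  kernel <- as.integer(kernel)
  if (identical(pad, "same")) pad <- (kernel - 1L) %/% 2L
  w <- ag_tensor(init_conv_weight(c_out, c_in %/% groups, kernel),
                 requires_grad = TRUE)
  b <- if (bias) ag_tensor(array(0, c(1, 1, c_out, 1, 1)), requires_grad = TRUE)
  m <- new_module("layer_conv3d",
                  params = c(list(w = w), if (bias) list(b = b)),
                  c_in = c_in, c_out = c_out, kernel = kernel,
                  stride = as.integer(stride), pad = as.integer(pad),
                  groups = as.integer(groups))
  m$forward <- function(x) {
    y <- ag_conv3d(x, w, stride = m$stride, pad = m$pad, groups = m$groups)
    if (!is.null(b)) y <- ag_add(y, ag_op(bcast(b$value, dim(y$value)),
                                          list(b), function(g) list(sum_to(g, dim(b$value)))))
    y
  }
  m
}

#' Per-channel batch normalization over (N, T, H, W)
#'
#' @param c Channel extent.
#' @param eps Variance floor.
#' @param momentum Running-statistics update rate.
#' @param gamma_init Initial scale; residual branches use 0 so a freshly
#'   built group is an exact identity.
#' @return Module with a `forward(x)` closure.
#' @export
layer_batchnorm <- function(c, eps = 1e-5, momentum = 0.1, gamma_init = 1) {
  shp <- c(1L, 1L, as.integer(c), 1L, 1L)
  gamma <- ag_tensor(array(gamma_init, shp), requires_grad = TRUE)
  beta <- ag_tensor(array(0, shp), requires_grad = TRUE)
  m <- new_module("layer_batchnorm", params = list(gamma = gamma, beta = beta),
                  c = c, eps = eps, momentum = momentum)
  m$buffers <- list(running_mean = array(0, shp), running_var = array(1, shp))
  m$forward <- function(x) {
    d <- dim(x$value)
    if (ag_is_training()) {
      cnt <- prod(d[-3L])
      mu <- x$value
      for (ax in c(1L, 2L, 4L, 5L)) mu <- sum_axis(mu, ax)
      mu <- mu / cnt
      xc <- x$value - bcast(mu, d)
      va <- xc^2
      for (ax in c(1L, 2L, 4L, 5L)) va <- sum_axis(va, ax)
      va <- va / cnt
      m$buffers$running_mean <- (1 - m$momentum) * m$buffers$running_mean + m$momentum * mu
      m$buffers$running_var <- (1 - m$momentum) * m$buffers$running_var + m$momentum * va
      inv <- 1 / sqrt(va + m$eps)
      xhat <- xc * bcast(inv, d)
      y <- bcast(gamma$value, d) * xhat + bcast(beta$value, d)
      ag_op(y, list(x, gamma, beta), function(g) {
        gxh <- g * bcast(gamma$value, d)
        s1 <- sum_to(gxh, dim(mu))
        s2 <- sum_to(gxh * xhat, dim(mu))
        gx <- bcast(inv, d) / cnt * (cnt * gxh - bcast(s1, d) - xhat * bcast(s2, d))
        list(gx, sum_to(g * xhat, dim(gamma$value)), sum_to(g, dim(beta$value)))
      })
    } else {
      inv <- 1 / sqrt(m$buffers$running_var + m$eps)
      xhat <- (x$value - bcast(m$buffers$running_mean, d)) * bcast(inv, d)
      y <- bcast(gamma$value, d) * xhat + bcast(beta$value, d)
      ag_op(y, list(x, gamma, beta), function(g) {
        list(g * bcast(gamma$value * inv, d),
             sum_to(g * xhat, dim(gamma$value)), sum_to(g, dim(beta$value)))
      })
    }
  }
  m
}

#' Fully connected layer
#'
#' @param n_in,n_out Feature widths.
#' @param bias Add a bias vector?
#' @return Module with a `forward(x)` closure over `(N, n_in)` matrices.
#' @export
layer_linear <- function(n_in, n_out, bias = TRUE) {
  w <- ag_tensor(matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                        n_in, n_out), requires_grad = TRUE)
  b <- if (bias) ag_tensor(rep(0, n_out), requires_grad = TRUE)
  m <- new_module("layer_linear",
                  params = c(list(w = w), if (bias) list(b = b)),
                  n_in = n_in, n_out = n_out)
  m$forward <- function(x) ag_linear(x, w, b)
  m
}

# Sequential composition helper.
seq_module <- function(mods, name = "seq") {
  m <- new_module("seq_module", modules = mods)
  m$forward <- function(x) {
    for (mm in m$modules) x <- mm$forward(x)
    x
  }
  m
}

#' Extract / restore module state
#'
#' `module_state()` returns all parameter values and running buffers as plain
#' named arrays (serializable with `saveRDS`); `load_module_state()` writes a
#' state back into a structurally identical module tree.
#'
#' @param m Module.
#' @param state Named list from `module_state()`.
#' @return `module_state()`: named list of arrays. `load_module_state()`: the
#'   module, invisibly.
#' @export
module_state <- function(m) {
  ps <- module_params(m)
  c(lapply(ps, function(p) p$value), module_buffers(m))
}

#' @rdname module_state
#' @export
load_module_state <- function(m, state) {
  ps <- module_params(m)
  for (nm in names(ps)) {
    if (is.null(state[[nm]])) stop("missing parameter in state: ", nm)
    ps[[nm]]$value <- state[[nm]]
  }
  restore_buffers(m, state, prefix = NULL)
  invisible(m)
}

restore_buffers <- function(m, state, prefix = NULL) {
  base <- m$name %||% class(m)[1]
  if (length(m$buffers)) {
    for (nm in names(m$buffers)) {
      key <- paste0(if (is.null(prefix)) "" else paste0(prefix, "/"), base, ".", nm)
      if (!is.null(state[[key]])) m$buffers[[nm]] <- state[[key]]
    }
  }
  for (i in seq_along(m$modules)) {
    pre <- names(m$modules)[i]
    if (is.null(pre) || is.na(pre) || !nzchar(pre)) pre <- as.character(i)
    restore_buffers(m$modules[[i]], state,
                    prefix = if (is.null(prefix)) pre else paste0(prefix, "/", pre))
  }
}

#' Stochastic gradient descent with momentum
#'
#' @param params Named list of parameters from [module_params()].
#' @param lr Learning rate.
#' @param momentum Momentum coefficient (0 = plain SGD).
#' @param weight_decay L2 penalty coefficient.
#' @return An optimizer object with a `$step()` closure.
#' @export
sgd_optimizer <- function(params, lr = 0.01, momentum = 0.9, weight_decay = 0) {
  vel <- vector("list", length(params))
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  opt$step <- function() {
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- p$grad
      if (weight_decay > 0) g <- g + weight_decay * p$value
      v <- if (is.null(vel[[i]])) g else momentum * vel[[i]] + g
      vel[[i]] <<- v
      p$value <- p$value - opt$lr * v
      p$grad <- NULL
    }
  }
  opt$zero_grad <- function() for (p in params) p$grad <- NULL
  class(opt) <- "sgd_optimizer"
  opt
}
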