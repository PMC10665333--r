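# Parameterized convolution building blocks: the R(2+1)D factorized
# convolution with its parameter-matching mid-channel solver, the
# depthwise-separable 3D convolution, and the residual convolution group.

#' Mid-channel count for a parameter-matched R(2+1)D factorization
#'
#' An R(2+1)D unit factorizes a full `t x d x d` 3D convolution into a
#' `1 x d x d` spatial convolution (`n_in -> m_mid`) followed by a `t x 1 x 1`
#' temporal convolution (`m_mid -> n_out`). The mid-channel width is chosen so
#' the factorized pair has the same number of weights as the full 3D kernel:
#' solving `n_in*t*d^2*n_out = n_in*d^2*m + m*t*n_out` for `m` and flooring
#' gives the largest integer for which the factorized count does not exceed
#' the 3D count. The result is clamped to at least 1 so degenerate
#' single-channel configurations remain buildable.
#'
#' @param t Temporal kernel extent (frames).
#' @param d Spatial kernel extent (pixels).
#' @param n_in,n_out Input/output channel counts.
#' @return Integer mid-channel count `m_mid`.
#' @examples
#' solve_mid_channels(3, 3, 64, 64)  # 144; both factorizations have 110592 weights
#' @export
solve_mid_channels <- function(t, d, n_in, n_out) {
  args <- c(t = t, d = d, n_in = n_in, n_out = n_out)
  if (any(args != floor(args)) || any(args < 1)) {
    stop("solve_mid_channels: all arguments must be positive integers, got (",
         paste(args, collapse = ", "), ")")
  }
  m <- floor(t * d^2 * n_in * n_out / (d^2 * n_in + t * n_out))
  max(1L, as.integer(m))
}

#' R(2+1)D factorized convolution specification
#'
#' @inheritParams solve_mid_channels
#' @param m_mid Mid-channel count; defaults to the parameter-matched value
#'   from [solve_mid_channels()].
#' @return An object of class `r2plus1d_spec` with fields `t`, `d`, `n_in`,
#'   `n_out`, `m_mid` and the two parameter counts.
#' @export
r2plus1d_spec <- function(t, d, n_in, n_out, m_mid = NULL) {
  m_mid <- m_mid %||% solve_mid_channels(t, d, n_in, n_out)
  spec <- list(t = as.integer(t), d = as.integer(d),
               n_in = as.integer(n_in), n_out = as.integer(n_out),
               m_mid = as.integer(m_mid),
               params_factorized = n_in * d^2 * m_mid + m_mid * t * n_out,
               params_full3d = n_in * t * d^2 * n_out)
  if (any(unlist(spec[1:5]) < 1)) stop("r2plus1d_spec: all extents must be >= 1")
  structure(spec, class = "r2plus1d_spec")
}

#' @export
print.r2plus1d_spec <- function(x, ...) {
  cat(sprintf("R(2+1)D spec: %dx%dx%d, %d -> %d channels, m_mid = %d\n",
              x$t, x$d, x$d, x$n_in, x$n_out, x$m_mid))
  cat(sprintf("  weights: factorized %d vs full 3D %d\n",
              x$params_factorized, x$params_full3d))
  invisible(x)
}

#' Build an R(2+1)D convolution unit
#'
#' The unit applies a `1 x d x d` spatial convolution (`n_in -> m_mid`), a
#' rectifier, then a `t x 1 x 1` temporal convolution (`m_mid -> n_out`).
#' Splitting the 3D kernel inserts an extra nonlinearity per unit (two versus
#' one for the plain 3D convolution it replaces) at matched parameter count.
#'
#' @param spec An [r2plus1d_spec()].
#' @param stride Length-3 stride `(time, height, width)`; the spatial stride
#'   is taken by the spatial convolution, the temporal stride by the temporal
#'   convolution.
#' @param norm Insert batch normalization after each convolution?
#' @param final_activation Apply a rectifier after the temporal convolution?
#' @param bias Convolution biases (counted separately from weights).
#' @param gamma_init_last Initial scale of the final normalization layer.
#' @return A module; `$n_nonlinearities` records the rectifier count.
#' @export
build_r2plus1d <- function(spec, stride = c(1, 1, 1), norm = FALSE,
                           final_activation = TRUE, bias = FALSE,
                           gamma_init_last = 1) {
  stopifnot(inherits(spec, "r2plus1d_spec"))
  spatial <- layer_conv3d(spec$n_in, spec$m_mid, kernel = c(1, spec$d, spec$d),
                          stride = c(1, stride[2], stride[3]), bias = bias)
  temporal <- layer_conv3d(spec$m_mid, spec$n_out, kernel = c(spec$t, 1, 1),
                           stride = c(stride[1], 1, 1), bias = bias)
  mods <- list(spatial = spatial)
  if (norm) mods$bn1 <- layer_batchnorm(spec$m_mid)
  if (norm) mods$bn2 <- layer_batchnorm(spec$n_out, gamma_init = gamma_init_last)
  mods$temporal <- temporal
  m <- new_module("r2plus1d_unit", modules = mods, spec = spec,
                  n_nonlinearities = 1L + as.integer(final_activation))
  m$forward <- function(x) {
    y <- spatial$forward(x)
    if (norm) y <- mods$bn1$forward(y)
    y <- ag_relu(y)
    y <- temporal$forward(y)
    if (norm) y <- mods$bn2$forward(y)
    if (final_activation) y <- ag_relu(y)
    y
  }
  m
}

#' Build a depthwise-separable 3D convolution unit
#'
#' A per-channel (grouped) 3D convolution followed by a `1 x 1 x 1` pointwise
#' mixing convolution. Weight count is `c_in * prod(kernel) + c_in * c_out`,
#' strictly below the `c_in * c_out * prod(kernel)` of the full 3D kernel
#' whenever `c_out > 1`.
#'
#' @param c_in,c_out Channel extents.
#' @param kernel Length-3 kernel extents for the depthwise stage.
#' @param stride Length-3 stride, applied by the depthwise stage.
#' @param norm Insert batch normalization after each convolution?
#' @param final_activation Apply a rectifier after the pointwise convolution?
#' @param bias Convolution biases.
#' @param gamma_init_last Initial scale of the final normalization layer.
#' @return A module.
#' @export
build_depthwise_separable_3d <- function(c_in, c_out, kernel = c(3, 3, 3),
                                         stride = c(1, 1, 1), norm = FALSE,
                                         final_activation = TRUE, bias = FALSE,
                                         gamma_init_last = 1) {
  stopifnot(c_in >= 1, c_out >= 1)
  depthwise <- layer_conv3d(c_in, c_in, kernel = kernel, stride = stride,
                            groups = c_in, bias = bias)
  pointwise <- layer_conv3d(c_in, c_out, kernel = c(1, 1, 1), bias = bias)
  mods <- list(depthwise = depthwise)
  if (norm) mods$bn1 <- layer_batchnorm(c_in)
  if (norm) mods$bn2 <- layer_batchnorm(c_out, gamma_init = gamma_init_last)
  mods$pointwise <- pointwise
  m <- new_module("depthwise_separable_unit", modules = mods,
                  c_in = c_in, c_out = c_out)
  m$forward <- function(x) {
    y <- depthwise$forward(x)
    if (norm) y <- mods$bn1$forward(y)
    y <- ag_relu(y)
    y <- pointwise$forward(y)
    if (norm) y <- mods$bn2$forward(y)
    if (final_activation) y <- ag_relu(y)
    y
  }
  m
}

#' Residual convolution group specification
#'
#' Exactly one convolution style is active for the core convolution:
#' `"plain"` 3D, `"depthwise_separable"`, or `"r2plus1d"`.
#'
#' @param c_in,c_out Channel extents.
#' @param temporal_kernel,spatial_kernel Kernel extents of the core.
#' @param stride Length-2 `(time, space)` stride.
#' @param style Convolution style.
#' @return An object of class `conv_group_spec`.
#' @export
conv_group_spec <- function(c_in, c_out, temporal_kernel = 3, spatial_kernel = 3,
                            stride = c(1, 1),
                            style = c("depthwise_separable", "r2plus1d", "plain")) {
  style <- match.arg(style)
  if (any(stride < 1)) stop("conv_group_spec: stride entries must be >= 1")
  structure(list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 temporal_kernel = as.integer(temporal_kernel),
                 spatial_kernel = as.integer(spatial_kernel),
                 stride = as.integer(stride), style = style),
            class = "conv_group_spec")
}

#' Build a residual convolution group
#'
#' The residual branch is the style's convolution unit with normalization and
#' an internal rectifier; the final normalization scale starts at zero, so a
#' freshly built group computes the identity (up to the shortcut projection).
#' When the stride is 1 and `c_in == c_out`, the shortcut is the identity;
#' otherwise a strided `1 x 1 x 1` projection matches extents. No activation
#' follows the addition.
#'
#' @param spec A [conv_group_spec()].
#' @return A module.
#' @export
conv_group <- function(spec) {
  stopifnot(inherits(spec, "conv_group_spec"))
  st3 <- c(spec$stride[1], spec$stride[2], spec$stride[2])
  k <- c(spec$temporal_kernel, spec$spatial_kernel, spec$spatial_kernel)
  branch <- switch(spec$style,
    depthwise_separable = build_depthwise_separable_3d(
      spec$c_in, spec$c_out, kernel = k, stride = st3, norm = TRUE,
      final_activation = FALSE, gamma_init_last = 0),
    r2plus1d = build_r2plus1d(
      r2plus1d_spec(spec$temporal_kernel, spec$spatial_kernel,
                    spec$c_in, spec$c_out),
      stride = st3, norm = TRUE, final_activation = FALSE,
      gamma_init_last = 0),
    plain = {
      core <- layer_conv3d(spec$c_in, spec$c_out, kernel = k, stride = st3)
      mix <- layer_conv3d(spec$c_out, spec$c_out, kernel = c(1, 1, 1))
      mm <- new_module("plain_unit",
                       modules = list(core = core,
                                      bn1 = layer_batchnorm(spec$c_out),
                                      mix = mix,
                                      bn2 = layer_batchnorm(spec$c_out,
                                                            gamma_init = 0)))
      mm$forward <- function(x) {
        y <- mm$modules$bn1$forward(core$forward(x))
        y <- ag_relu(y)
        mm$modules$bn2$forward(mix$forward(y))
      }
      mm
    })
  identity_shortcut <- all(spec$stride == 1) && spec$c_in == spec$c_out
  mods <- list(branch = branch)
  if (!identity_shortcut) {
    mods$proj <- layer_conv3d(spec$c_in, spec$c_out, kernel = c(1, 1, 1),
                              stride = st3)
    mods$proj_bn <- layer_batchnorm(spec$c_out)
  }
  m <- new_module("conv_group", modules = mods, spec = spec,
                  identity_shortcut = identity_shortcut)
  m$forward <- function(x) {
    if (dim(x$value)[3] != spec$c_in) {
      stop(sprintf("residual group: input has %d channels, spec expects %d (input %s)",
                   dim(x$value)[3], spec$c_in,
                   paste(dim(x$value), collapse = "x")))
    }
    fx <- branch$forward(x)
    sc <- if (identity_shortcut) x else
      mods$proj_bn$forward(mods$proj$forward(x))
    ag_add(fx, sc)
  }
  m
}

#' Forward pass through a residual convolution group
#'
#' Functional surface over [conv_group()]: accepts either a built group or a
#' [conv_group_spec()] (in which case a fresh group is built from the current
#' random state).
#'
#' @param x Input tensor `(N,T,C,H,W)` (an [ag_tensor()] or plain array).
#' @param group A `conv_group` module or a `conv_group_spec`.
#' @return The output tensor.
#' @export
residual_group_forward <- function(x, group) {
  if (inherits(group, "conv_group_spec")) group <- conv_group(group)
  group$forward(as_ag(x))
}
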