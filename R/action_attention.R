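# Three-branch action attention: spatial-temporal excitation (STE), channel
# excitation (CE) and motion excitation (ME). Each branch derives a sigmoid
# mask from the input volume X and returns the residual recalibration
# Y = X + X * Mask; the module output combines the three branch outputs.

#' Attention branch configuration
#'
#' @param r Channel compression ratio; squeezed width is `ceil(C/r)`, at
#'   least 1.
#' @param ste_kernel 3D kernel extent of the STE convolution (odd).
#' @param ce_temporal_kernel Temporal kernel extent of the CE branch (odd).
#' @param me_spatial_kernel Spatial kernel extent of the ME branch (odd).
#' @param combine How the module merges branch outputs: elementwise `"mean"`
#'   (preserves activation scale) or `"sum"`.
#' @return An object of class `action_config`.
#' @export
action_config <- function(r = 16, ste_kernel = 3, ce_temporal_kernel = 3,
                          me_spatial_kernel = 3, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  ks <- c(ste_kernel, ce_temporal_kernel, me_spatial_kernel)
  if (r < 1) stop("action_config: compression ratio r must be >= 1")
  if (any(ks %% 2 == 0)) stop("action_config: kernel extents must be odd")
  structure(list(r = r, ste_kernel = as.integer(ste_kernel),
                 ce_temporal_kernel = as.integer(ce_temporal_kernel),
                 me_spatial_kernel = as.integer(me_spatial_kernel),
                 combine = combine),
            class = "action_config")
}

squeezed_width <- function(c, r) max(1L, as.integer(ceiling(c / r)))

# Excitation masks live in the open interval (0,1); clamp away from the
# saturated sigmoid values double precision rounds to 0 or 1.
open_sigmoid <- function(x) ag_clamp(ag_sigmoid(x), 1e-12, 1 - 1e-12)

#' Build an action attention block
#'
#' Constructs the three excitation branches for a feature volume with `c`
#' channels. The block is inserted after every residual convolution group of
#' the X3D pathway.
#'
#' @param c Channel extent of the incoming feature volume.
#' @param cfg An [action_config()].
#' @return A module whose `forward(x)` returns the combined branch output.
#' @export
action_block <- function(c, cfg = action_config()) {
  cr <- squeezed_width(c, cfg$r)
  k <- cfg$ste_kernel
  mods <- list(
    # STE: one 3D convolution on the channel-averaged 1-channel volume
    ste_conv = layer_conv3d(1, 1, kernel = c(k, k, k)),
    # CE: squeeze -> temporal 1D convolution -> expand
    ce_squeeze = layer_conv3d(c, cr, kernel = c(1, 1, 1)),
    ce_temporal = layer_conv3d(cr, cr, kernel = c(cfg$ce_temporal_kernel, 1, 1)),
    ce_expand = layer_conv3d(cr, c, kernel = c(1, 1, 1)),
    # ME: squeeze -> frame-wise 2D convolution + adjacent-frame difference
    #     -> spatial pooling -> expand
    me_squeeze = layer_conv3d(c, cr, kernel = c(1, 1, 1)),
    me_conv2d = layer_conv3d(cr, cr, kernel = c(1, cfg$me_spatial_kernel,
                                                cfg$me_spatial_kernel)),
    me_expand = layer_conv3d(cr, c, kernel = c(1, 1, 1)))
  m <- new_module("action_block", modules = mods, c = c, cfg = cfg)
  m$forward <- function(x) action_module(x, m)
  m
}

resolve_action_block <- function(x, block) {
  if (inherits(block, "action_config")) block <- action_block(dim(x$value)[3], block)
  if (!inherits(block, "action_block")) stop("expected an action_block or action_config")
  block
}

#' Spatial-temporal excitation branch
#'
#' Averages the volume over channels, applies a single 3D convolution and a
#' sigmoid to obtain a mask of shape `(N,T,1,H,W)`, then returns
#' `Y = X + X * Mask` with the mask broadcast over channels.
#'
#' @param x Feature volume `(N,T,C,H,W)` (array or [ag_tensor()]).
#' @param block An [action_block()] for the volume's channel width, or an
#'   [action_config()] from which a fresh block is built.
#' @param return_mask Return `list(y, mask)` instead of `y`.
#' @return Output tensor of the input shape (or a list when `return_mask`).
#' @export
ste_branch <- function(x, block = action_config(), return_mask = FALSE) {
  x <- as_ag(x)
  block <- resolve_action_block(x, block)
  xp <- ag_mean_axes(x, 3L)                       # (N,T,1,H,W)
  fo <- block$modules$ste_conv$forward(xp)
  mask <- open_sigmoid(fo)
  y <- ag_add(x, ag_mul(x, mask))
  if (return_mask) list(y = y, mask = mask) else y
}

#' Channel excitation branch
#'
#' Global spatial averaging gives a `(N,T,C,1,1)` descriptor; channels are
#' squeezed by ratio `r`, a 1D convolution runs along the frame axis, and the
#' expanded response is passed through a sigmoid to gate each channel per
#' frame.
#'
#' @inheritParams ste_branch
#' @return Output tensor of the input shape (or a list when `return_mask`).
#' @export
ce_branch <- function(x, block = action_config(), return_mask = FALSE) {
  x <- as_ag(x)
  block <- resolve_action_block(x, block)
  xp <- ag_mean_axes(x, c(4L, 5L))                # (N,T,C,1,1)
  fr <- block$modules$ce_squeeze$forward(xp)
  fr <- ag_relu(fr)
  fr <- block$modules$ce_temporal$forward(fr)
  fo <- block$modules$ce_expand$forward(fr)       # (N,T,C,1,1)
  mask <- open_sigmoid(fo)
  y <- ag_add(x, ag_mul(x, mask))
  if (return_mask) list(y = y, mask = mask) else y
}

#' Motion excitation branch
#'
#' After channel squeezing, each frame `t+1` is passed through a 2D spatial
#' convolution and the previous frame is subtracted, yielding motion features
#' `F_m(t)`; a zero frame restores the temporal length (placed at the last
#' slot), spatial pooling and channel expansion produce the `(N,T,C,1,1)`
#' mask.
#'
#' @inheritParams ste_branch
#' @return Output tensor of the input shape (or a list when `return_mask`).
#' @export
me_branch <- function(x, block = action_config(), return_mask = FALSE) {
  x <- as_ag(x)
  d <- dim(x$value)
  if (d[2] < 2) {
    stop("motion excitation is undefined for single-frame input (T = 1); ",
         "bypass this branch for static clips")
  }
  block <- resolve_action_block(x, block)
  fr <- block$modules$me_squeeze$forward(x)       # (N,T,C/r,H,W)
  nxt <- ag_time_slice(fr, 2L, d[2])              # frames 2..T
  prv <- ag_time_slice(fr, 1L, d[2] - 1L)         # frames 1..T-1
  fm <- ag_sub(block$modules$me_conv2d$forward(nxt), prv)
  fM <- ag_time_pad_end(fm, 1L)                   # (N,T,C/r,H,W), zero last slot
  pooled <- ag_mean_axes(fM, c(4L, 5L))           # (N,T,C/r,1,1)
  fo <- block$modules$me_expand$forward(pooled)   # (N,T,C,1,1)
  mask <- open_sigmoid(fo)
  y <- ag_add(x, ag_mul(x, mask))
  if (return_mask) list(y = y, mask = mask) else y
}

#' Combined action attention module
#'
#' Applies the three excitation branches to the same input and combines the
#' branch outputs elementwise (mean by default, preserving activation scale).
#'
#' @inheritParams ste_branch
#' @return Output tensor with the input shape.
#' @export
action_module <- function(x, block = action_config()) {
  x <- as_ag(x)
  block <- resolve_action_block(x, block)
  ys <- list(ste_branch(x, block), ce_branch(x, block), me_branch(x, block))
  out <- ag_add(ag_add(ys[[1]], ys[[2]]), ys[[3]])
  if (identical(block$cfg$combine, "mean")) out <- ag_scale(out, 1 / 3) else out
}
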