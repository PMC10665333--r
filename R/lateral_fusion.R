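# Lateral connection: transfers fast-pathway motion features into the X3D
# pathway via a time-strided 3D convolution (temporal downsampling), a 3D
# squeeze-excitation reweighting, and channel concatenation.

#' Lateral connection specification
#'
#' @param alpha Frame-rate ratio between pathways; the lateral convolution's
#'   temporal stride, so the downsampled fast features match the X3D frame
#'   count.
#' @param out_channels Channels after the lateral convolution (defaults to
#'   `2 * c_fast` at build time).
#' @param kernel,pad Length-3 convolution geometry; the default
#'   `(5,1,1)/(2,0,0)` is the canonical time-strided lateral setting of the
#'   two-pathway lineage.
#' @param se_ratio Squeeze ratio of the 3D SE block (squeezed width clamped
#'   to >= 1).
#' @return An object of class `lateral_spec`.
#' @export
lateral_spec <- function(alpha, out_channels = NULL, kernel = c(5, 1, 1),
                         pad = c(2, 0, 0), se_ratio = 16) {
  stopifnot(alpha >= 1, se_ratio >= 1)
  structure(list(alpha = as.integer(alpha),
                 out_channels = if (!is.null(out_channels)) as.integer(out_channels),
                 kernel = as.integer(kernel), stride = c(as.integer(alpha), 1L, 1L),
                 pad = as.integer(pad), se_ratio = se_ratio),
            class = "lateral_spec")
}

#' Build a lateral connection block
#'
#' @param c_fast Channels of the incoming fast-pathway features.
#' @param spec A [lateral_spec()].
#' @return A module; `forward(fast_feat)` returns the downsampled, SE-gated
#'   lateral features.
#' @export
lateral_block <- function(c_fast, spec) {
  c_out <- spec$out_channels %||% (2L * c_fast)
  cs <- max(1L, as.integer(floor(c_out / spec$se_ratio)))
  mods <- list(
    conv = layer_conv3d(c_fast, c_out, kernel = spec$kernel,
                        stride = spec$stride, pad = spec$pad),
    bn = layer_batchnorm(c_out),
    se_squeeze = layer_conv3d(c_out, cs, kernel = c(1, 1, 1), bias = TRUE),
    se_excite = layer_conv3d(cs, c_out, kernel = c(1, 1, 1), bias = TRUE))
  m <- new_module("lateral_block", modules = mods, c_fast = c_fast,
                  c_out = c_out, spec = spec)
  m$forward <- function(fast_feat) {
    h <- temporal_downsample(fast_feat, m)
    se3d_reweight(h, m)
  }
  m
}

#' Temporal downsampling of fast-pathway features
#'
#' A 3D convolution with temporal stride `alpha` reduces the fast pathway's
#' frame count to the X3D pathway's; spatial extents are unchanged.
#'
#' @param fast_feat Fast-pathway feature volume (array or [ag_tensor()]);
#'   its frame count must be divisible by `alpha`.
#' @param block A built [lateral_block()], or a [lateral_spec()] from which
#'   one is built for the input's channel width.
#' @return Feature tensor with `T_fast / alpha` frames and
#'   `spec$out_channels` channels.
#' @export
temporal_downsample <- function(fast_feat, block) {
  x <- as_ag(fast_feat)
  if (inherits(block, "lateral_spec")) block <- lateral_block(dim(x$value)[3], block)
  a <- block$spec$alpha
  if (dim(x$value)[2] %% a != 0) {
    stop(sprintf("temporal downsampling: fast T = %d is not divisible by alpha = %d",
                 dim(x$value)[2], a))
  }
  y <- block$modules$conv$forward(x)
  ag_relu(block$modules$bn$forward(y))
}

#' 3D squeeze-excitation channel reweighting
#'
#' Global spatiotemporal averaging per channel, a squeeze/excite bottleneck
#' and a sigmoid produce per-channel gates in (0, 1) that rescale the volume.
#'
#' @param feat Feature volume (array or [ag_tensor()]).
#' @param block A built [lateral_block()], a [lateral_spec()], or a numeric
#'   squeeze ratio (a fresh SE block is then built for the input width).
#' @param return_gates Also return the gate tensor.
#' @return The reweighted tensor (or `list(y, gates)`).
#' @export
se3d_reweight <- function(feat, block, return_gates = FALSE) {
  x <- as_ag(feat)
  if (is.numeric(block)) block <- lateral_spec(1, se_ratio = block)
  if (inherits(block, "lateral_spec")) {
    block <- se_only_block(dim(x$value)[3], block$se_ratio)
  }
  pooled <- ag_mean_axes(x, c(2L, 4L, 5L))        # (N,1,C,1,1)
  z <- ag_relu(block$modules$se_squeeze$forward(pooled))
  gates <- ag_clamp(ag_sigmoid(block$modules$se_excite$forward(z)),
                    1e-12, 1 - 1e-12)
  y <- ag_mul(x, gates)
  if (return_gates) list(y = y, gates = gates) else y
}

se_only_block <- function(c, se_ratio) {
  cs <- max(1L, as.integer(floor(c / se_ratio)))
  new_module("lateral_block",
             modules = list(se_squeeze = layer_conv3d(c, cs, kernel = c(1, 1, 1),
                                                      bias = TRUE),
                            se_excite = layer_conv3d(cs, c, kernel = c(1, 1, 1),
                                                     bias = TRUE)),
             c_out = c)
}

#' Fuse lateral features into the X3D stream
#'
#' Concatenates the X3D features and the (already downsampled and SE-gated)
#' lateral features along the channel axis, X3D channels first. All other
#' extents must agree exactly; mismatches raise an error naming the axis.
#'
#' @param x3d_feat X3D-pathway feature volume.
#' @param lateral_feat Lateral feature volume from [lateral_block()].
#' @return Fused tensor with `C_x3d + C_lateral` channels.
#' @export
fuse <- function(x3d_feat, lateral_feat) {
  ag_concat_channels(as_ag(x3d_feat), as_ag(lateral_feat))
}
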