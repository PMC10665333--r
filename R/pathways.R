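# The two pathways: the X3D pathway (spatial emphasis; four stages of
# 3/5/11/7 residual groups with action attention) and the fast pathway
# (temporal emphasis; beta-scaled channels, R(2+1)D convolutions, alpha-times
# higher frame rate), plus dual-rate clip sampling.

#' Pathway profile
#'
#' Describes one pathway of the two-pathway network: residual groups and
#' channel widths per stage, clip length, spatial stride schedule, stem, and
#' the convolution style of the residual cores. Temporal extent is preserved
#' through every stage; downsampling is spatial only.
#'
#' @param stage_groups Integer vector of residual groups per stage (the full
#'   X3D pathway uses `c(3, 5, 11, 7)`).
#' @param stage_channels Channel width per stage.
#' @param t_frames Clip length (frames) fed to this pathway.
#' @param spatial_strides Per-stage spatial stride (default: stride 2 at
#'   stages 2-4).
#' @param attention Insert an action attention block after each residual
#'   group?
#' @param conv_style Core convolution style of the residual groups.
#' @param stem_channels Stem output width (defaults to the first stage width).
#' @param stem_kernel,stem_stride Stem convolution geometry.
#' @return An object of class `pathway_profile`.
#' @export
pathway_profile <- function(stage_groups, stage_channels, t_frames,
                            spatial_strides = c(1, 2, 2, 2),
                            attention = FALSE,
                            conv_style = c("depthwise_separable", "r2plus1d",
                                           "plain"),
                            stem_channels = stage_channels[1],
                            stem_kernel = c(3, 3, 3),
                            stem_stride = c(1, 2, 2)) {
  conv_style <- match.arg(conv_style)
  n <- length(stage_groups)
  stopifnot(n == length(stage_channels), n == length(spatial_strides),
            all(stage_groups >= 1), all(stage_channels >= 1), t_frames >= 1)
  structure(list(stage_groups = as.integer(stage_groups),
                 stage_channels = as.integer(stage_channels),
                 t_frames = as.integer(t_frames),
                 spatial_strides = as.integer(spatial_strides),
                 attention = isTRUE(attention), conv_style = conv_style,
                 stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride)),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway profile: stages (%s) groups, (%s) channels, T = %d, %s%s\n",
              paste(x$stage_groups, collapse = ","),
              paste(x$stage_channels, collapse = ","),
              x$t_frames, x$conv_style,
              if (x$attention) " + action attention" else ""))
  invisible(x)
}

#' Dual-rate clip sampling
#'
#' Selects `alpha * t_x3d` frame indices uniformly across the clip for the
#' fast pathway and every `alpha`-th of those (the first of each block) for
#' the X3D pathway. Clips shorter than the fast frame count are looped (wrap
#' padding) before uniform indexing. Both index vectors are non-decreasing
#' and order-preserving.
#'
#' @param frames Either a `(T,H,W,3)` frame array or an integer frame count.
#' @param t_x3d Frames consumed by the X3D pathway.
#' @param alpha Frame-rate ratio between pathways (integer, >= 1).
#' @return List with `fast_idx`, `x3d_idx`, and — when `frames` is an array —
#'   `fast` and `x3d` frame stacks.
#' @export
sample_dual_rate <- function(frames, t_x3d, alpha) {
  n_avail <- if (is.array(frames)) dim(frames)[1] else as.integer(frames)
  if (is.na(n_avail) || n_avail < 1) stop("sample_dual_rate: empty clip")
  stopifnot(t_x3d >= 1, alpha >= 1, alpha == floor(alpha))
  nf <- as.integer(t_x3d * alpha)
  if (n_avail >= nf) {
    fast_idx <- unique_strict(round(seq(1, n_avail, length.out = nf)), n_avail)
  } else {
    fast_idx <- ((seq_len(nf) - 1L) %% n_avail) + 1L  # loop the clip
  }
  x3d_idx <- fast_idx[seq(1L, nf, by = alpha)]
  out <- list(fast_idx = fast_idx, x3d_idx = x3d_idx)
  if (is.array(frames)) {
    out$fast <- frames[fast_idx, , , , drop = FALSE]
    out$x3d <- frames[x3d_idx, , , , drop = FALSE]
  }
  out
}

make_stage <- function(blocks) {
  stage <- new_module("pathway_stage", modules = blocks)
  stage$forward <- function(x) {
    for (b in blocks) x <- b$forward(x)
    x
  }
  stage
}

# round() can repeat an index when length.out > span; nudge repeats forward
# while keeping indices within range and strictly increasing.
unique_strict <- function(idx, n_max) {
  for (i in seq_along(idx)[-1]) if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + 1L
  as.integer(pmin(idx, n_max))
}

#' Build a pathway
#'
#' Assembles stem plus four stages of residual convolution groups. The first
#' group of each stage applies the stage's spatial stride and changes the
#' channel width; when the profile enables attention, an action block follows
#' every residual group. `extra_in_channels` widens the input of each stage
#' to accommodate laterally fused channels.
#'
#' @param profile A [pathway_profile()].
#' @param in_channels Channels of the incoming clip (3 for RGB).
#' @param extra_in_channels Per-stage additive input width from lateral
#'   fusion (0 when the pathway runs standalone).
#' @param action_cfg An [action_config()] for the attention blocks.
#' @return A module; `forward(x)` returns the list of stage outputs.
#' @export
build_pathway <- function(profile, in_channels = 3L,
                          extra_in_channels = rep(0L, length(profile$stage_groups)),
                          action_cfg = action_config()) {
  n_stages <- length(profile$stage_groups)
  stem <- seq_module(list(
    conv = layer_conv3d(in_channels, profile$stem_channels,
                        kernel = profile$stem_kernel,
                        stride = profile$stem_stride),
    bn = layer_batchnorm(profile$stem_channels)))
  stem_fwd <- stem$forward
  stem$forward <- function(x) ag_relu(stem_fwd(x))

  mods <- list(stem = stem)
  prev <- profile$stem_channels
  for (s in seq_len(n_stages)) {
    c_in <- prev + as.integer(extra_in_channels[s])
    c_out <- profile$stage_channels[s]
    blocks <- list()
    for (g in seq_len(profile$stage_groups[s])) {
      spec <- conv_group_spec(
        c_in = if (g == 1L) c_in else c_out, c_out = c_out,
        stride = if (g == 1L) c(1L, profile$spatial_strides[s]) else c(1L, 1L),
        style = profile$conv_style)
      blocks[[paste0("group", g)]] <- conv_group(spec)
      if (profile$attention) {
        blocks[[paste0("action", g)]] <- action_block(c_out, action_cfg)
      }
    }
    mods[[paste0("stage", s)]] <- make_stage(blocks)
    prev <- c_out
  }

  m <- new_module("pathway", modules = mods, profile = profile,
                  extra_in_channels = as.integer(extra_in_channels))
  m$forward <- function(x) {
    if (dim(x$value)[2] != profile$t_frames) {
      stop(sprintf("pathway expects T = %d frames, got %d",
                   profile$t_frames, dim(x$value)[2]))
    }
    h <- mods$stem$forward(x)
    out <- vector("list", n_stages)
    for (s in seq_len(n_stages)) {
      h <- mods[[paste0("stage", s)]]$forward(h)
      out[[s]] <- h
    }
    out
  }
  m
}

#' Forward pass through the X3D pathway
#'
#' @param clip Input tensor or array `(N,T,C,H,W)` with `T` equal to the
#'   profile's `t_frames`.
#' @param profile A [pathway_profile()] (attention enabled for the X3D
#'   pathway) or a built pathway module.
#' @return List of the four stage output tensors.
#' @export
x3d_pathway_forward <- function(clip, profile) {
  m <- if (inherits(profile, "pathway")) profile else
    build_pathway(profile, in_channels = dim(as_ag(clip)$value)[3])
  m$forward(as_ag(clip))
}

#' Forward pass through the fast pathway
#'
#' Identical stage layout with beta-scaled channel widths and (by default)
#' R(2+1)D residual cores; no temporal downsampling occurs, so every stage
#' output keeps the input frame count.
#'
#' @inheritParams x3d_pathway_forward
#' @return List of the four stage output tensors.
#' @export
fast_pathway_forward <- function(clip, profile) {
  x3d_pathway_forward(clip, profile)
}

#' Scale X3D channel widths for the fast pathway
#'
#' @param x3d_channels Integer vector of X3D stage widths.
#' @param beta Channel ratio (< 1); widths are rounded, minimum 1.
#' @return Integer vector of fast-pathway widths.
#' @export
fast_channels <- function(x3d_channels, beta) {
  pmax(1L, as.integer(round(beta * x3d_channels)))
}
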