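# Named model profiles and their YAML serialization.

#' Built-in model profiles
#'
#' `"full"` is the complete architecture: X3D pathway with 3/5/11/7 residual
#' groups (26 in total) and widths 24/48/96/192 over 8 frames; fast pathway
#' with channel ratio beta = 1/8 (widths 3/6/12/24) over 32 frames
#' (alpha = 4). `"tiny"` is a desk-scale profile used for training
#' experiments on synthetic clips: 1/1/2/1 groups, widths 8/12/16/24 over 4
#' frames, fast ratio beta = 1/2 over 8 frames (alpha = 2).
#'
#' @param name `"full"` or `"tiny"`.
#' @param use_lateral,use_r2plus1d,use_action Ablation switches forwarded to
#'   [x3dfast_config()].
#' @return An [x3dfast_config()].
#' @export
x3dfast_profile <- function(name = c("tiny", "full"), use_lateral = TRUE,
                            use_r2plus1d = TRUE, use_action = TRUE) {
  name <- match.arg(name)
  path <- system.file("extdata", "profiles", paste0(name, ".yaml"),
                      package = "x3dfast")
  if (!nzchar(path)) stop("profile not found: ", name)
  cfg <- read_model_profile(path)
  cfg$use_lateral <- isTRUE(use_lateral)
  cfg$use_r2plus1d <- isTRUE(use_r2plus1d)
  cfg$use_action <- isTRUE(use_action)
  cfg$x3d_profile$attention <- cfg$use_action
  cfg$fast_profile$conv_style <- if (cfg$use_r2plus1d) "r2plus1d" else "plain"
  cfg
}

#' Read / write a model profile as YAML
#'
#' @param path YAML file path.
#' @return `read_model_profile()`: an [x3dfast_config()];
#'   `write_model_profile()`: `path`, invisibly.
#' @export
read_model_profile <- function(path) {
  y <- yaml::read_yaml(path)
  pw <- function(p) pathway_profile(
    stage_groups = p$stage_groups, stage_channels = p$stage_channels,
    t_frames = p$t_frames,
    spatial_strides = p$spatial_strides %||% c(1, 2, 2, 2),
    attention = isTRUE(p$attention),
    conv_style = p$conv_style %||% "depthwise_separable",
    stem_channels = p$stem_channels %||% p$stage_channels[1],
    stem_kernel = p$stem_kernel %||% c(3, 3, 3),
    stem_stride = p$stem_stride %||% c(1, 2, 2))
  lat <- y$lateral
  x3dfast_config(
    x3d_profile = pw(y$x3d), fast_profile = pw(y$fast),
    lateral = lateral_spec(alpha = y$fast$t_frames / y$x3d$t_frames,
                           out_channels = lat$out_channels,
                           kernel = lat$kernel %||% c(5, 1, 1),
                           pad = lat$pad %||% c(2, 0, 0),
                           se_ratio = lat$se_ratio %||% 16),
    num_classes = y$num_classes %||% 4,
    predictor_hidden = y$predictor_hidden %||% 256,
    dropout = y$dropout %||% 0.5,
    use_lateral = !isFALSE(y$use_lateral),
    use_r2plus1d = !isFALSE(y$use_r2plus1d),
    use_action = !isFALSE(y$use_action),
    action = action_config(r = y$action_r %||% 16))
}

#' @rdname read_model_profile
#' @param cfg An [x3dfast_config()].
#' @export
write_model_profile <- function(cfg, path) {
  pw <- function(p) list(stage_groups = p$stage_groups,
                         stage_channels = p$stage_channels,
                         t_frames = p$t_frames,
                         spatial_strides = p$spatial_strides,
                         attention = p$attention, conv_style = p$conv_style,
                         stem_channels = p$stem_channels,
                         stem_kernel = p$stem_kernel,
                         stem_stride = p$stem_stride)
  y <- list(x3d = pw(cfg$x3d_profile), fast = pw(cfg$fast_profile),
            lateral = list(out_channels = cfg$lateral$out_channels,
                           kernel = cfg$lateral$kernel, pad = cfg$lateral$pad,
                           se_ratio = cfg$lateral$se_ratio),
            num_classes = cfg$num_classes,
            predictor_hidden = cfg$predictor_hidden, dropout = cfg$dropout,
            use_lateral = cfg$use_lateral, use_r2plus1d = cfg$use_r2plus1d,
            use_action = cfg$use_action, action_r = cfg$action$r)
  yaml::write_yaml(y, path)
  invisible(path)
}
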