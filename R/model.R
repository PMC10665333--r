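# Full model assembly: both pathways, stage-wise lateral fusion, the
# fully-connected predictor, the cross-entropy loss, the top-1 metric, and
# gradient-weighted class activation maps.

#' Model configuration
#'
#' Assembles the architectural profile of the two-pathway network. The three
#' ablation switches correspond to the architecture's three improvements:
#' the lateral connection, the R(2+1)D fast-pathway convolution, and the
#' action attention module.
#'
#' @param x3d_profile,fast_profile [pathway_profile()]s; `fast_profile`
#'   frames must equal `alpha * x3d` frames.
#' @param lateral A [lateral_spec()] (built when `use_lateral`).
#' @param num_classes Number of behavior classes.
#' @param predictor_hidden Width of the hidden fully connected layer.
#' @param dropout Dropout probability before the output layer.
#' @param use_lateral,use_r2plus1d,use_action Ablation switches.
#' @param action An [action_config()].
#' @return An object of class `x3dfast_config`.
#' @export
x3dfast_config <- function(x3d_profile, fast_profile, lateral = NULL,
                           num_classes = 4L, predictor_hidden = 256L,
                           dropout = 0.5, use_lateral = TRUE,
                           use_r2plus1d = TRUE, use_action = TRUE,
                           action = action_config()) {
  stopifnot(num_classes >= 2)
  alpha <- fast_profile$t_frames / x3d_profile$t_frames
  if (alpha != floor(alpha) || alpha < 1) {
    stop("fast-pathway frames must be an integer multiple of X3D frames")
  }
  x3d_profile$attention <- isTRUE(use_action)
  fast_profile$conv_style <- if (isTRUE(use_r2plus1d)) "r2plus1d" else "plain"
  lateral <- lateral %||% lateral_spec(alpha)
  lateral$alpha <- as.integer(alpha)
  lateral$stride <- c(as.integer(alpha), 1L, 1L)
  structure(list(x3d_profile = x3d_profile, fast_profile = fast_profile,
                 lateral = lateral, num_classes = as.integer(num_classes),
                 predictor_hidden = as.integer(predictor_hidden),
                 dropout = dropout, alpha = as.integer(alpha),
                 use_lateral = isTRUE(use_lateral),
                 use_r2plus1d = isTRUE(use_r2plus1d),
                 use_action = isTRUE(use_action), action = action),
            class = "x3dfast_config")
}

#' @export
print.x3dfast_config <- function(x, ...) {
  cat("X3DFast configuration\n")
  cat("  X3D pathway:  "); print(x$x3d_profile)
  cat("  fast pathway: "); print(x$fast_profile)
  cat(sprintf("  alpha = %d, classes = %d, switches: lateral=%s r2plus1d=%s action=%s\n",
              x$alpha, x$num_classes, x$use_lateral, x$use_r2plus1d, x$use_action))
  invisible(x)
}

#' Build the two-pathway model
#'
#' @param cfg An [x3dfast_config()].
#' @param in_channels Clip channels (3 for RGB).
#' @return A model module with `forward(x3d_clip, fast_clip)`.
#' @export
build_x3dfast <- function(cfg, in_channels = 3L) {
  n_stages <- length(cfg$x3d_profile$stage_groups)
  fastp <- build_pathway(cfg$fast_profile, in_channels = in_channels)

  laterals <- NULL
  extra <- rep(0L, n_stages)
  if (cfg$use_lateral) {
    laterals <- list()
    for (s in seq_len(n_stages)) {
      cf <- cfg$fast_profile$stage_channels[s]
      sp <- cfg$lateral
      if (is.null(sp$out_channels)) sp$out_channels <- 2L * cf
      laterals[[paste0("lateral", s)]] <- lateral_block(cf, sp)
    }
    # stages 2..n consume the previous stage's fused output
    extra <- c(0L, vapply(laterals, function(b) b$c_out, integer(1))[-n_stages])
  }
  x3dp <- build_pathway(cfg$x3d_profile, in_channels = in_channels,
                        extra_in_channels = extra, action_cfg = cfg$action)

  c_final_x3d <- cfg$x3d_profile$stage_channels[n_stages] +
    if (cfg$use_lateral) laterals[[n_stages]]$c_out else 0L
  feat_width <- c_final_x3d + cfg$fast_profile$stage_channels[n_stages]
  head <- list(fc1 = layer_linear(feat_width, cfg$predictor_hidden),
               fc2 = layer_linear(cfg$predictor_hidden, cfg$num_classes))

  mods <- c(list(x3d = x3dp, fast = fastp), laterals, head)
  m <- new_module("x3dfast_model", modules = mods, cfg = cfg,
                  in_channels = as.integer(in_channels))
  x3d_mods <- x3dp$modules
  m$forward <- function(x3d_clip, fast_clip, want_features = FALSE) {
    xc <- as_ag(x3d_clip); fc <- as_ag(fast_clip)
    f <- fastp$forward(fc)
    h <- x3d_mods$stem$forward(xc)
    fused <- vector("list", n_stages)
    for (s in seq_len(n_stages)) {
      h <- x3d_mods[[paste0("stage", s)]]$forward(h)
      if (cfg$use_lateral) {
        lat <- laterals[[s]]$forward(f[[s]])
        h <- fuse(h, lat)
      }
      fused[[s]] <- h
    }
    pooled <- ag_concat_cols(ag_global_pool(h), ag_global_pool(f[[n_stages]]))
    z <- ag_relu(head$fc1$forward(pooled))
    z <- ag_dropout(z, cfg$dropout)
    logits <- head$fc2$forward(z)
    if (want_features) list(logits = logits, features = fused) else logits
  }
  m
}

#' Forward pass of the full model
#'
#' @param x3d_clip,fast_clip Clip tensors `(N,T,C,H,W)` with the frame counts
#'   of the respective profiles.
#' @param model A built model from [build_x3dfast()], or an
#'   [x3dfast_config()] (a fresh model is then built).
#' @return Logit matrix `(N, num_classes)` as an [ag_tensor()].
#' @export
x3dfast_forward <- function(x3d_clip, fast_clip, model) {
  if (inherits(model, "x3dfast_config")) {
    model <- build_x3dfast(model, in_channels = dim(as_ag(x3d_clip)$value)[3])
  }
  model$forward(x3d_clip, fast_clip)
}

#' Cross-entropy loss over class probabilities
#'
#' `L = -(1/N) * sum_i sum_c y_ic * log(p_ic)`, with probabilities clamped at
#' `eps = 1e-12` before the logarithm. Probability rows must sum to 1 within
#' `1e-6` and label rows must be one-hot.
#'
#' @param p Predicted probability matrix `(N, M)`.
#' @param y One-hot label matrix `(N, M)`, or an integer class vector
#'   (converted internally).
#' @param eps Clamping floor for the logarithm.
#' @return Scalar loss (plain numeric).
#' @examples
#' cross_entropy(matrix(0.25, 2, 4), one_hot(c(1, 3), 4))  # log(4)
#' @export
cross_entropy <- function(p, y, eps = 1e-12) {
  p <- as.matrix(p)
  if (is.vector(y) || (is.matrix(y) && ncol(y) == 1 && ncol(p) > 1)) {
    y <- one_hot(as.integer(y), ncol(p))
  }
  if (!all(dim(p) == dim(y))) stop("cross_entropy: dimension mismatch")
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("cross_entropy: probability rows must sum to 1")
  }
  if (any(rowSums(y == 1) != 1L) || !all(y %in% c(0, 1))) {
    stop("cross_entropy: labels must be one-hot rows")
  }
  -sum(y * log(pmax(p, eps))) / nrow(p)
}

#' One-hot encoding
#'
#' @param classes Integer class indices (1-based).
#' @param m Number of classes.
#' @return A `(length(classes), m)` 0/1 matrix.
#' @export
one_hot <- function(classes, m) {
  out <- matrix(0, length(classes), m)
  out[cbind(seq_along(classes), as.integer(classes))] <- 1
  out
}

#' Top-1 accuracy
#'
#' Fraction of samples whose highest-scoring prediction equals the true
#' class; ties are broken deterministically toward the lowest class index.
#' Invariant under any strictly monotone transformation of the scores.
#'
#' @param predictions Score/probability matrix `(N, M)` or predicted class
#'   vector.
#' @param labels True class indices (1-based) or one-hot matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
top1 <- function(predictions, labels) {
  pred <- if (is.matrix(predictions)) {
    max.col(predictions, ties.method = "first")
  } else as.integer(predictions)
  truth <- if (is.matrix(labels)) max.col(labels, ties.method = "first") else
    as.integer(labels)
  if (length(pred) != length(truth)) stop("top1: length mismatch")
  if (length(pred) == 0) stop("top1: empty input")
  mean(pred == truth)
}

#' Gradient-weighted class activation maps
#'
#' Computes per-frame heatmaps on a fused feature volume (the final stage by
#' default). With `method = "gradcam"`, channel weights are the
#' spatially-and-temporally pooled gradients of the target class logit and
#' the heatmap is the rectified weighted channel sum. With
#' `method = "elementwise"`, the rectified elementwise product of gradient
#' and activation is summed over channels, which localizes more sharply on
#' low-resolution feature grids. Each frame's maximum is normalized to 1
#' whenever any activation is nonzero.
#'
#' @param model A built (trained) model.
#' @param x3d_clip,fast_clip Clip arrays for one or more clips.
#' @param target_class Class index (1-based); defaults to the predicted
#'   class.
#' @param upsample_to Optional `(H, W)` to bilinearly upsample each frame to.
#' @param stage Fused stage whose feature volume is mapped; the default is
#'   the final stage. Earlier stages trade semantic depth for spatial
#'   resolution (each stage halves H and W), which matters at small input
#'   sizes.
#' @param method Heatmap weighting scheme (see Description).
#' @return An object of class `cam_result`: list with `heatmaps`
#'   `(T',H',W')` per clip, `class`, and `logits`.
#' @export
compute_cam <- function(model, x3d_clip, fast_clip, target_class = NULL,
                        upsample_to = NULL, stage = NULL,
                        method = c("gradcam", "elementwise")) {
  method <- match.arg(method)
  if (!inherits(model, "x3dfast_model")) stop("compute_cam: expected a built model")
  if (!isTRUE(model$trained)) {
    stop("compute_cam: model has no trained state; fit or load a checkpoint first")
  }
  old <- ag_set_training(FALSE)
  on.exit(ag_set_training(old))
  res <- ag_with_grad({
    x <- ag_tensor(as_array5(x3d_clip), requires_grad = TRUE)
    f <- ag_tensor(as_array5(fast_clip), requires_grad = TRUE)
    model$forward(x, f, want_features = TRUE)
  })
  stage <- stage %||% length(res$features)
  feat <- res$features[[stage]]
  logits <- res$logits$value
  n <- nrow(logits)
  cls <- if (is.null(target_class)) {
    max.col(logits, ties.method = "first")
  } else rep_len(as.integer(target_class), n)
  seed <- matrix(0, n, ncol(logits))
  seed[cbind(seq_len(n), cls)] <- 1
  feat$retain <- TRUE
  ag_backward(res$logits, seed = seed)
  act <- feat$value                              # (N,T',C,H',W')
  grad <- feat$grad
  if (is.null(grad)) stop("compute_cam: no gradient reached the feature volume")
  d <- dim(act)
  heatmaps <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grad[i, , , , , drop = FALSE]
    a <- act[i, , , , , drop = FALSE]
    hm <- array(0, d[c(2L, 4L, 5L)])
    if (method == "gradcam") {
      wch <- apply(g, 3L, mean)                  # pooled gradient per channel
      for (ch in seq_len(d[3L])) hm <- hm + wch[ch] * a[1, , ch, , ]
      hm <- pmax(hm, 0)
    } else {
      for (ch in seq_len(d[3L])) hm <- hm + pmax(g[1, , ch, , ] * a[1, , ch, , ], 0)
    }
    for (t in seq_len(d[2L])) {
      mx <- max(hm[t, , ])
      if (mx > 0) hm[t, , ] <- hm[t, , ] / mx
    }
    if (!is.null(upsample_to)) {
      up <- array(0, c(d[2L], upsample_to))
      for (t in seq_len(d[2L])) {
        up[t, , ] <- as.numeric(EBImage::resize(EBImage::as.Image(hm[t, , ]),
                                                w = upsample_to[1],
                                                h = upsample_to[2]))
      }
      hm <- up
    }
    heatmaps[[i]] <- hm
  }
  structure(list(heatmaps = heatmaps, class = cls, logits = logits),
            class = "cam_result")
}

# Coerce a (T,C,H,W) clip or (N,T,C,H,W) batch to the 5-axis convention.
as_array5 <- function(x) {
  if (is_ag_tensor(x)) x <- x$value
  d <- dim(x)
  if (length(d) == 4L) x <- array(x, c(1L, d))
  if (length(dim(x)) != 5L) stop("expected a (N,T,C,H,W) or (T,C,H,W) array")
  x
}
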