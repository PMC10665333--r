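# End-to-end pipeline: stratified splitting, clip preprocessing, from-scratch
# SGD training, evaluation reports, and checkpointing. The fitting function
# x3dfast() returns a classed object with print/summary/predict/plot methods.

#' Training configuration
#'
#' Defaults follow the architecture's training protocol: plain stochastic
#' gradient descent at learning rate 0.01, trained from scratch, no
#' learning-rate schedule, no weight decay. Momentum 0.9 is on by default
#' but configurable to 0. The full-scale protocol uses 256 epochs with
#' frames resized to 256 on the short side and cropped to 224; the
#' desk-scale defaults (30 epochs, 32 px) are sized for CPU experiments on
#' synthetic clips.
#'
#' @param lr Learning rate (> 0).
#' @param epochs Number of epochs (>= 1).
#' @param momentum SGD momentum (0 = plain SGD).
#' @param weight_decay L2 penalty (0 by default).
#' @param batch_size Minibatch size.
#' @param resize Short-side resize target (px).
#' @param crop Square crop size (px); training mode crops randomly,
#'   evaluation mode centrally.
#' @param norm_mean,norm_sd Per-channel normalization constants (recorded in
#'   every checkpoint).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param scale `"tiny"` or `"full"`; picks the epoch/resize/crop defaults.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, epochs = NULL, momentum = 0.9,
                         weight_decay = 0, batch_size = NULL, resize = NULL,
                         crop = NULL, norm_mean = 0.45, norm_sd = 0.225,
                         seed = 1L, scale = c("tiny", "full")) {
  scale <- match.arg(scale)
  epochs <- epochs %||% if (scale == "tiny") 30L else 256L
  batch_size <- batch_size %||% if (scale == "tiny") 8L else 32L
  resize <- resize %||% if (scale == "tiny") 32L else 256L
  crop <- crop %||% if (scale == "tiny") 32L else 224L
  if (lr <= 0) stop("learning rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 resize = as.integer(resize), crop = as.integer(crop),
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 seed = as.integer(seed), scale = scale),
            class = "train_config")
}

#' Stratified train/validation split
#'
#' Shuffles within each class and assigns `floor(train_frac * n_class)`
#' clips to training, the remainder to validation. The two sets are disjoint
#' and jointly exhaustive.
#'
#' @param manifest Data frame with a `label` column (e.g. from
#'   [generate_dataset()]).
#' @param train_frac Training fraction per class.
#' @param seed Shuffle seed.
#' @return An object of class `split_manifest`: list with integer row
#'   indices `train` and `validation`, per-class counts, and the seed.
#' @export
stratified_split <- function(manifest, train_frac = 0.8, seed = 1L) {
  labs <- manifest$label
  tab <- table(labs)
  if (any(tab < 2)) {
    stop("every class needs at least 2 clips; got: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  train <- integer(0)
  local_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labs == cl))
      n_tr <- floor(train_frac * length(idx))
      train <- c(train, idx[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  validation <- setdiff(seq_along(labs), train)
  structure(list(train = train, validation = validation,
                 counts = data.frame(label = names(tab),
                                     n_train = as.integer(table(labs[train])[names(tab)]),
                                     n_validation = as.integer(table(labs[validation])[names(tab)])),
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "split_manifest")
}

#' Preprocess a clip into model-ready pathway inputs
#'
#' Aspect-preserving resize so the short side equals `cfg$resize` (long side
#' rounded half up), then a square crop (`random` in training mode, center
#' in evaluation mode), dual-rate frame sampling for the two pathways, and
#' per-channel normalization with the fixed constants recorded in the
#' configuration.
#'
#' @param frames `(T,H,W,3)` integer array (0-255) or a `clip_record`.
#' @param cfg A [train_config()].
#' @param t_x3d,alpha Frame counts of the model profile.
#' @param mode `"eval"` (deterministic center crop) or `"train"`.
#' @return List with `x3d` and `fast` arrays `(T,C,H,W)` plus the sampled
#'   source frame indices.
#' @export
preprocess_clip <- function(frames, cfg, t_x3d, alpha, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(frames, "clip_record")) frames <- frames$frames
  d <- dim(frames)
  sam <- sample_dual_rate(d[1], t_x3d, alpha)
  fr <- frames[sam$fast_idx, , , , drop = FALSE] / 255

  H <- d[2]; W <- d[3]
  if (min(H, W) != cfg$resize) {
    hw <- resize_dims(H, W, cfg$resize)
    H2 <- hw[1]; W2 <- hw[2]
    out <- array(0, c(dim(fr)[1], H2, W2, 3))
    for (t in seq_len(dim(fr)[1])) {
      out[t, , , ] <- as.array(EBImage::resize(EBImage::as.Image(fr[t, , , ]),
                                               w = H2, h = W2))
    }
    fr <- out
    H <- H2; W <- W2
  }
  if (H < cfg$crop || W < cfg$crop) {
    stop(sprintf("frame %dx%d smaller than crop %d after resize", H, W, cfg$crop))
  }
  off_y <- if (mode == "train") sample.int(H - cfg$crop + 1L, 1L) else
    (H - cfg$crop) %/% 2L + 1L
  off_x <- if (mode == "train") sample.int(W - cfg$crop + 1L, 1L) else
    (W - cfg$crop) %/% 2L + 1L
  fr <- fr[, off_y:(off_y + cfg$crop - 1L), off_x:(off_x + cfg$crop - 1L), ,
           drop = FALSE]
  fr <- (fr - cfg$norm_mean) / cfg$norm_sd
  # (T,H,W,C) -> (T,C,H,W)
  fast <- aperm(fr, c(1, 4, 2, 3))
  x3d <- fast[seq(1L, dim(fast)[1], by = alpha), , , , drop = FALSE]
  list(x3d = x3d, fast = fast, x3d_idx = sam$x3d_idx, fast_idx = sam$fast_idx)
}

#' Aspect-preserving resize target
#'
#' Output extents of the short-side resize: the short side becomes `target`
#' and the long side scales proportionally, rounded half up.
#'
#' @param h,w Input extents (pixels).
#' @param target Short-side target.
#' @return Integer `(h', w')`.
#' @examples
#' resize_dims(1080, 2560, 256)  # 256 x 607
#' @export
resize_dims <- function(h, w, target) {
  sc <- target / min(h, w)
  if (h <= w) c(as.integer(target), as.integer(floor(w * sc + 0.5))) else
    c(as.integer(floor(h * sc + 0.5)), as.integer(target))
}

stack_batch <- function(pre_list, which) {
  d <- dim(pre_list[[1]][[which]])
  out <- array(0, c(length(pre_list), d))
  for (i in seq_along(pre_list)) out[i, , , , ] <- pre_list[[i]][[which]]
  out
}

#' Fit the two-pathway behavior recognition model
#'
#' From-scratch minibatch SGD training minimizing softmax cross-entropy.
#' Logs per-epoch training loss (and top-1) and, when a validation set is
#' given, validation top-1; keeps the best-validation parameter state. Fully
#' seeded: identical inputs and seeds give identical metric logs.
#'
#' @param clips List of `clip_record`s (or a [generate_dataset()] result).
#' @param labels Behavior labels; taken from the clips when omitted.
#' @param profile An [x3dfast_config()] or profile name (`"tiny"`,
#'   `"full"`).
#' @param config A [train_config()].
#' @param validation Optional list of clips (with labels in the same way) or
#'   a [stratified_split()] applied to `clips`.
#' @param max_iterations Optional hard cap on optimizer steps (overrides
#'   epochs when reached first).
#' @param stop_at_train_top1 Optionally stop early once training top-1
#'   reaches this value.
#' @param verbose Print per-epoch progress.
#' @return An object of class `x3dfast_fit`.
#' @export
x3dfast <- function(clips, labels = NULL, profile = "tiny",
                    config = train_config(), validation = NULL,
                    max_iterations = Inf, stop_at_train_top1 = NULL,
                    verbose = FALSE) {
  if (is.list(clips) && !is.null(clips$clips)) clips <- clips$clips
  cfg <- if (inherits(profile, "x3dfast_config")) profile else
    x3dfast_profile(profile)
  labels <- labels %||% vapply(clips, function(cl) cl$label, character(1))
  lev <- if (all(labels %in% BEHAVIOR_LEVELS)) BEHAVIOR_LEVELS else
    sort(unique(labels))
  yi <- match(labels, lev)
  if (anyNA(yi)) stop("unknown labels: ", paste(unique(labels[is.na(yi)]), collapse = ", "))

  val_clips <- NULL; val_yi <- NULL
  if (inherits(validation, "split_manifest")) {
    val_clips <- clips[validation$validation]
    val_yi <- yi[validation$validation]
    clips <- clips[validation$train]
    yi <- yi[validation$train]
  } else if (!is.null(validation)) {
    if (is.list(validation) && !is.null(validation$clips)) validation <- validation$clips
    val_clips <- validation
    val_yi <- match(vapply(val_clips, function(cl) cl$label, character(1)), lev)
  }

  alpha <- cfg$alpha
  t_x3d <- cfg$x3d_profile$t_frames
  set.seed(config$seed)
  model <- build_x3dfast(cfg)
  params <- module_params(model)
  opt <- sgd_optimizer(params, lr = config$lr, momentum = config$momentum,
                       weight_decay = config$weight_decay)

  # preprocessing is deterministic at the desk scale (resize == crop), so
  # clips are preprocessed once and reused across epochs
  pre <- lapply(clips, preprocess_clip, cfg = config, t_x3d = t_x3d,
                alpha = alpha, mode = "eval")
  pre_val <- if (!is.null(val_clips)) {
    lapply(val_clips, preprocess_clip, cfg = config, t_x3d = t_x3d,
           alpha = alpha, mode = "eval")
  }

  n <- length(pre)
  history <- data.frame()
  best <- list(metric = -Inf, state = NULL, epoch = NA_integer_)
  iter <- 0L
  done <- FALSE
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ag_set_training(TRUE)
    ep_loss <- 0; ep_hits <- 0; ep_n <- 0L
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- stack_batch(pre[idx], "x3d")
      fb <- stack_batch(pre[idx], "fast")
      yb <- one_hot(yi[idx], cfg$num_classes)
      loss_node <- NULL
      logits <- ag_with_grad({
        lg <- model$forward(ag_tensor(xb), ag_tensor(fb))
        loss_node <- ag_softmax_xent(lg, yb)  # evaluated in this frame
        lg
      })
      if (!is.finite(loss_node$value)) {
        stop(sprintf("training diverged: non-finite loss at iteration %d", iter + 1L))
      }
      ag_backward(loss_node)
      opt$step()
      iter <- iter + 1L
      nb <- nb + 1L
      ep_loss <- ep_loss + loss_node$value
      ep_hits <- ep_hits + sum(max.col(logits$value, ties.method = "first") == yi[idx])
      ep_n <- ep_n + length(idx)
      if (iter >= max_iterations) { done <- TRUE; break }
    }
    ag_set_training(FALSE)
    train_top1 <- ep_hits / ep_n
    val_top1 <- NA_real_
    if (!is.null(pre_val)) {
      vp <- predict_pre(model, pre_val, config$batch_size)
      val_top1 <- top1(vp, val_yi)
      metric <- val_top1
    } else {
      metric <- train_top1
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, iterations = iter,
                                loss = ep_loss / nb, train_top1 = train_top1,
                                val_top1 = val_top1))
    if (metric >= best$metric) {
      best <- list(metric = metric, state = module_state(model), epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train top-1 %.3f  val top-1 %s",
                      epoch, ep_loss / nb, train_top1,
                      if (is.na(val_top1)) "-" else sprintf("%.3f", val_top1)))
    }
    if (!is.null(stop_at_train_top1) && train_top1 >= stop_at_train_top1) done <- TRUE
    if (done) break
  }
  if (!is.null(best$state)) load_module_state(model, best$state)
  model$trained <- TRUE
  structure(list(model = model, config = cfg, train_config = config,
                 history = history, class_levels = lev,
                 best_epoch = best$epoch, best_metric = best$metric,
                 n_train = n, n_validation = length(val_clips %||% list())),
            class = "x3dfast_fit")
}

predict_pre <- function(model, pre_list, batch_size) {
  out <- NULL
  for (start in seq(1L, length(pre_list), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(pre_list))
    lg <- ag_no_grad(model$forward(ag_tensor(stack_batch(pre_list[idx], "x3d")),
                                   ag_tensor(stack_batch(pre_list[idx], "fast"))))
    out <- rbind(out, lg$value)
  }
  out
}

#' Predict behavior classes for new clips
#'
#' @param object An `x3dfast_fit`.
#' @param newdata List of `clip_record`s (or a dataset list).
#' @param type `"class"`, `"prob"` or `"logits"`.
#' @param ... Unused.
#' @return Factor of classes, or a probability/logit matrix.
#' @export
predict.x3dfast_fit <- function(object, newdata,
                                type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata$clips)) newdata <- newdata$clips
  if (inherits(newdata, "clip_record")) newdata <- list(newdata)
  cfgm <- object$config
  pre <- lapply(newdata, preprocess_clip, cfg = object$train_config,
                t_x3d = cfgm$x3d_profile$t_frames, alpha = cfgm$alpha,
                mode = "eval")
  ag_set_training(FALSE)
  lg <- predict_pre(object$model, pre, object$train_config$batch_size)
  colnames(lg) <- object$class_levels
  switch(type,
         logits = lg,
         prob = exp(lg - apply(lg, 1, max)) /
           rowSums(exp(lg - apply(lg, 1, max))),
         class = factor(object$class_levels[max.col(lg, ties.method = "first")],
                        levels = object$class_levels))
}

#' @export
print.x3dfast_fit <- function(x, ...) {
  cat("X3DFast behavior recognition model\n")
  cat(sprintf("  classes: %s\n", paste(x$class_levels, collapse = ", ")))
  cat(sprintf("  parameters: %s\n", format(n_params(x$model), big.mark = ",")))
  cat(sprintf("  trained: %d epochs on %d clips (batch %d, lr %g)\n",
              nrow(x$history), x$n_train, x$train_config$batch_size,
              x$train_config$lr))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, train top-1 %.3f%s\n", last$loss,
              last$train_top1,
              if (!is.na(last$val_top1))
                sprintf(", best val top-1 %.3f (epoch %d)", x$best_metric,
                        x$best_epoch) else ""))
  invisible(x)
}

#' @export
summary.x3dfast_fit <- function(object, ...) {
  out <- list(history = object$history,
              n_parameters = n_params(object$model),
              class_levels = object$class_levels,
              best_epoch = object$best_epoch, best_metric = object$best_metric)
  class(out) <- "summary.x3dfast_fit"
  out
}

#' @export
print.summary.x3dfast_fit <- function(x, ...) {
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  cat(sprintf("\n%s parameters; best epoch %d (metric %.3f)\n",
              format(x$n_parameters, big.mark = ","), x$best_epoch,
              x$best_metric))
  invisible(x)
}

#' @export
plot.x3dfast_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$train_top1, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "top-1", main = "accuracy", ...)
  if (!all(is.na(h$val_top1))) {
    graphics::lines(h$epoch, h$val_top1, lty = 2)
    graphics::legend("bottomright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Evaluate a fitted model
#'
#' @param fit An `x3dfast_fit`.
#' @param clips Evaluation clips (list or dataset).
#' @param labels Labels; taken from the clips when omitted.
#' @return An `x3dfast_report`: overall top-1, per-class accuracy, and the
#'   confusion matrix (rows = truth, columns = prediction).
#' @export
evaluate_model <- function(fit, clips, labels = NULL) {
  if (is.list(clips) && !is.null(clips$clips)) clips <- clips$clips
  if (length(clips) == 0) stop("evaluate_model: empty clip set")
  labels <- labels %||% vapply(clips, function(cl) cl$label, character(1))
  pred <- predict(fit, clips, type = "class")
  truth <- factor(labels, levels = fit$class_levels)
  conf <- table(truth = truth, prediction = pred)
  per_class <- diag(conf) / pmax(rowSums(conf), 1)
  structure(list(top1 = sum(diag(conf)) / sum(conf),
                 per_class = per_class,
                 n_per_class = rowSums(conf),
                 confusion = conf, n = sum(conf)),
            class = "x3dfast_report")
}

#' @export
print.x3dfast_report <- function(x, ...) {
  cat(sprintf("overall top-1: %.4f (n = %d)\n", x$top1, x$n))
  cat("per-class accuracy:\n")
  print(round(x$per_class, 4))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report An `x3dfast_report`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json` with identical numbers.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  df <- data.frame(label = names(report$per_class),
                   n = as.integer(report$n_per_class),
                   accuracy = as.numeric(report$per_class))
  df <- rbind(df, data.frame(label = "overall", n = report$n,
                             accuracy = report$top1))
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  conf <- matrix(as.numeric(report$confusion), nrow(report$confusion),
                 dimnames = dimnames(report$confusion))
  jsonlite::write_json(list(top1 = report$top1,
                            per_class = as.list(report$per_class),
                            confusion = conf),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Save / load a checkpoint
#'
#' A checkpoint is a self-describing list: model configuration, parameter
#' and buffer state, training configuration (including the normalization
#' constants and seed) and the metric history.
#'
#' @param fit An `x3dfast_fit`.
#' @param path Destination `.rds` path.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a
#'   restored `x3dfast_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(config = fit$config, state = module_state(fit$model),
               train_config = fit$train_config, history = fit$history,
               class_levels = fit$class_levels, best_epoch = fit$best_epoch,
               best_metric = fit$best_metric, n_train = fit$n_train,
               n_validation = fit$n_validation), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  # construction draws are overwritten by the stored state; keep the caller's
  # random stream untouched
  model <- local_seed(0L, build_x3dfast(ck$config))
  load_module_state(model, ck$state)
  model$trained <- TRUE
  structure(list(model = model, config = ck$config,
                 train_config = ck$train_config, history = ck$history,
                 class_levels = ck$class_levels, best_epoch = ck$best_epoch,
                 best_metric = ck$best_metric, n_train = ck$n_train,
                 n_validation = ck$n_validation),
            class = "x3dfast_fit")
}
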