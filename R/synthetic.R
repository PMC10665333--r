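# Deterministic simulator of labeled behavior clips. Four classes with the
# statistical structure of a barn-camera behavior dataset: static classes
# (standing, lying) are distinguished by body aspect in space, dynamic
# classes by temporal cues (walking = translation, mounting = two bodies
# with oscillating overlap). Bodies are textured ellipses on a textured
# background; occlusion, blur and illumination degradations are applied
# separately. A rule-based kinematic oracle validates that the class signal
# is present.

BEHAVIOR_LEVELS <- c("standing", "lying", "walking", "mounting")

# Class mix of a realistic barn dataset (standing:lying:walking:mounting).
BEHAVIOR_RATIOS <- c(standing = 1799, lying = 1947, walking = 1130,
                     mounting = 774)

# Clip duration ranges in seconds per class.
DURATION_RANGES <- list(standing = c(1, 2), lying = c(1, 2),
                        walking = c(1, 3), mounting = c(2, 4))

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Scene specification for one synthetic behavior clip
#'
#' Geometry and kinematics of a rendered clip. Defaults encode the
#' separability guarantees the simulator is built around: the walking speed
#' is at least twice the static jitter (temporal separability), standing and
#' lying aspect ratios differ by more than 1.5x (spatial separability), and
#' the mounting oscillation keeps the two bodies overlapping in at least
#' half of the frames.
#'
#' @param behavior One of `"standing"`, `"lying"`, `"walking"`,
#'   `"mounting"`.
#' @param canvas `(H, W)` pixels.
#' @param fps Frame rate; the test-scale default is 12.5.
#' @param duration_s Clip length in seconds; default drawn uniformly from
#'   the class's range (standing/lying 1-2 s, walking 1-3 s, mounting
#'   2-4 s).
#' @param body_axes `(rx, ry)` semi-axes of the main body in pixels;
#'   class-specific defaults.
#' @param velocity Walking translation speed, pixels/frame.
#' @param jitter Static-class centroid jitter amplitude, pixels.
#' @param overlap_amplitude Mounting vertical-offset oscillation amplitude.
#' @param n_distractors Background (non-labeled) bodies.
#' @param occluders List of `c(x, y, w, h)` rectangles for
#'   [apply_degradations()].
#' @param blur_sigma Gaussian blur sigma (pixels) for degradations.
#' @param illumination_gain Multiplicative intensity gain for degradations.
#' @param seed Integer seed; the rendered clip is a pure function of the
#'   spec including this seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(behavior, canvas = c(64, 64), fps = 12.5,
                       duration_s = NULL, body_axes = NULL, velocity = 2,
                       jitter = 1, overlap_amplitude = 8, n_distractors = 0,
                       occluders = list(), blur_sigma = 0,
                       illumination_gain = 1, seed = 1L) {
  behavior <- match.arg(behavior, BEHAVIOR_LEVELS)
  if (is.null(duration_s)) {
    rng <- DURATION_RANGES[[behavior]]
    duration_s <- local_seed((seed %% 2147483L) * 131L + 17L,
                             stats::runif(1, rng[1], rng[2]))
  }
  t_frames <- max(2L, as.integer(round(duration_s * fps)))
  body_axes <- body_axes %||% switch(behavior,
    standing = c(6, 13), walking = c(6, 13), lying = c(14, 6),
    mounting = c(12, 7))
  aspect <- body_axes[2] / body_axes[1]
  if (behavior %in% c("standing", "walking") && aspect < 1.25) {
    stop("standing/walking bodies must be upright (ry/rx >= 1.25) to keep ",
         "the standing-vs-lying aspect contrast above 1.5x")
  }
  if (behavior == "lying" && aspect > 0.8) {
    stop("lying bodies must be flat (ry/rx <= 0.8) to keep the ",
         "standing-vs-lying aspect contrast above 1.5x")
  }
  if (behavior == "walking" && velocity < 2 * jitter) {
    stop("walking velocity must be at least twice the jitter amplitude ",
         "to guarantee temporal separability")
  }
  if (any(2 * body_axes + 2 >= rev(canvas))) {
    stop("body larger than canvas")
  }
  structure(list(behavior = behavior, canvas = as.integer(canvas), fps = fps,
                 duration_s = duration_s, t_frames = t_frames,
                 body_axes = body_axes, velocity = velocity, jitter = jitter,
                 overlap_amplitude = overlap_amplitude,
                 n_distractors = as.integer(n_distractors),
                 occluders = occluders, blur_sigma = blur_sigma,
                 illumination_gain = illumination_gain,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Logical mask of a (rotated) ellipse on an H x W grid (rows = y, cols = x).
ellipse_mask <- function(H, W, cx, cy, rx, ry, theta = 0) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), W), H, W) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

smooth_field <- function(H, W, cells = 8) {
  base <- matrix(stats::runif(cells * cells), cells, cells)
  as.matrix(EBImage::resize(EBImage::as.Image(base), w = H, h = W))
}

#' Render a synthetic behavior clip
#'
#' Renders textured elliptical bodies on a textured background according to
#' the class kinematics of `spec`: standing = upright static body with
#' jitter, lying = flat static body with jitter, walking = translating
#' upright body with vertical bob (bouncing off the canvas edges), mounting
#' = two bodies whose vertical separation oscillates so they overlap in at
#' least half of the frames. The result is a pure function of the spec.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `clip_record`: list with `frames`
#'   (`T x H x W x 3`, integer 0-255), `label`, `masks` (`T x H x W`
#'   logical foreground masks) and `spec`.
#' @export
generate_clip <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, {
    H <- spec$canvas[1]; W <- spec$canvas[2]; Tn <- spec$t_frames
    rx <- spec$body_axes[1]; ry <- spec$body_axes[2]

    bodies <- body_tracks(spec, H, W, Tn)
    bg <- 0.22 + 0.25 * smooth_field(H, W)
    tint <- c(1, 1.05, 0.95)

    frames <- array(0, c(Tn, H, W, 3))
    masks <- array(FALSE, c(Tn, H, W))
    distr <- distractor_layout(spec, H, W)
    for (t in seq_len(Tn)) {
      fr <- array(0, c(H, W, 3))
      for (ch in 1:3) fr[, , ch] <- bg * tint[ch]
      for (d in distr) {
        dm <- ellipse_mask(H, W, d$cx, d$cy, d$rx, d$ry)
        for (ch in 1:3) {
          pl <- fr[, , ch]
          pl[dm] <- d$col[ch] + stats::rnorm(sum(dm), sd = 0.04)
          fr[, , ch] <- pl
        }
      }
      fg <- matrix(FALSE, H, W)
      for (b in bodies) {
        bm <- ellipse_mask(H, W, b$cx[t], b$cy[t], b$rx, b$ry, b$theta)
        fg <- fg | bm
        for (ch in 1:3) {
          pl <- fr[, , ch]
          pl[bm] <- b$col[ch] + stats::rnorm(sum(bm), sd = 0.05)
          fr[, , ch] <- pl
        }
      }
      fr <- fr + stats::rnorm(length(fr), sd = 0.01)
      frames[t, , , ] <- pmin(pmax(fr, 0), 1)
      masks[t, , ] <- fg
    }

    if (spec$behavior == "mounting") {
      n_overlap <- sum(vapply(seq_len(Tn), function(t) {
        m1 <- ellipse_mask(H, W, bodies[[1]]$cx[t], bodies[[1]]$cy[t],
                           bodies[[1]]$rx, bodies[[1]]$ry, bodies[[1]]$theta)
        m2 <- ellipse_mask(H, W, bodies[[2]]$cx[t], bodies[[2]]$cy[t],
                           bodies[[2]]$rx, bodies[[2]]$ry, bodies[[2]]$theta)
        any(m1 & m2)
      }, logical(1)))
      if (n_overlap < Tn / 2) {
        stop("mounting oscillation failed to keep the bodies overlapping in ",
             "at least half of the frames; adjust overlap_amplitude")
      }
    }

    structure(list(frames = to_uint8(frames), label = spec$behavior,
                   masks = masks, spec = spec),
              class = "clip_record")
  })
}

to_uint8 <- function(x) {
  y <- as.integer(round(255 * x))
  array(y, dim(x))
}

# Per-frame body center tracks and shapes for each class.
body_tracks <- function(spec, H, W, Tn) {
  rx <- spec$body_axes[1]; ry <- spec$body_axes[2]
  j <- spec$jitter
  main_col <- c(0.80, 0.74, 0.68)
  jit <- function() stats::runif(Tn, -j, j)
  switch(spec$behavior,
    standing = ,
    lying = {
      cx0 <- W / 2 + stats::runif(1, -4, 4)
      cy0 <- H / 2 + stats::runif(1, -4, 4)
      list(list(cx = cx0 + jit(), cy = cy0 + jit(), rx = rx, ry = ry,
                theta = 0, col = main_col))
    },
    walking = {
      dir <- sample(c(-1, 1), 1)
      lo <- rx + 2; hi <- W - rx - 2
      cx0 <- if (dir > 0) lo + stats::runif(1, 0, 4) else hi - stats::runif(1, 0, 4)
      path <- cx0 + dir * spec$velocity * (seq_len(Tn) - 1)
      cx <- reflect_path(path, lo, hi)
      cy0 <- H / 2 + stats::runif(1, -4, 4)
      bob <- 1.5 * sin(2 * pi * (seq_len(Tn) - 1) / 8)
      list(list(cx = cx + jit(), cy = cy0 + bob + jit(), rx = rx, ry = ry,
                theta = 0, col = main_col))
    },
    mounting = {
      # 12-frame mount/apart cycle starting mounted: 7 frames with a small
      # vertical gap (strong overlap), 5 frames clearly apart. Starting with
      # the mounted phase keeps the overlapping fraction >= 1/2 for every
      # clip length.
      cx0 <- W / 2 + stats::runif(1, -4, 4)
      cyL <- H / 2 + 8 + stats::runif(1, -2, 2)
      phase <- (seq_len(Tn) - 1) %% 12
      gap <- ifelse(phase < 7, 8, 8 + 2 * spec$overlap_amplitude)
      list(
        list(cx = cx0 + jit(), cy = cyL + jit(), rx = rx, ry = ry,
             theta = 0, col = main_col),
        list(cx = cx0 + 6 + jit(), cy = cyL - gap + jit(), rx = 7, ry = 10,
             theta = 0.25, col = c(0.72, 0.66, 0.60)))
    })
}

# Reflect a 1D path into [lo, hi] (bounce off the walls).
reflect_path <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

distractor_layout <- function(spec, H, W) {
  if (spec$n_distractors < 1) return(list())
  lapply(seq_len(spec$n_distractors), function(i) {
    list(cx = stats::runif(1, 6, W - 6), cy = sample(c(6, H - 6), 1),
         rx = 5, ry = 3, col = c(0.58, 0.55, 0.52))
  })
}

#' Apply degradations to a clip
#'
#' Applies, in order: illumination gain, Gaussian blur, and occluder
#' rectangles (from the clip's spec unless overridden). The label is
#' unchanged; foreground masks are clipped by occluders.
#'
#' @param clip A [generate_clip()] result.
#' @param gain,blur_sigma,occluders Override the spec's degradation fields.
#' @return The degraded `clip_record`.
#' @export
apply_degradations <- function(clip, gain = NULL, blur_sigma = NULL,
                               occluders = NULL) {
  stopifnot(inherits(clip, "clip_record"))
  gain <- gain %||% clip$spec$illumination_gain
  blur_sigma <- blur_sigma %||% clip$spec$blur_sigma
  occluders <- occluders %||% clip$spec$occluders
  if (gain == 1 && blur_sigma <= 0 && length(occluders) == 0) return(clip)
  d <- dim(clip$frames)
  fr <- clip$frames / 255
  fr <- fr * gain
  if (blur_sigma > 0) {
    for (t in seq_len(d[1])) {
      img <- EBImage::as.Image(fr[t, , , ])
      fr[t, , , ] <- as.array(EBImage::gblur(img, sigma = blur_sigma))
    }
  }
  masks <- clip$masks
  for (oc in occluders) {
    xs <- max(1, oc[1]):min(d[3], oc[1] + oc[3] - 1)
    ys <- max(1, oc[2]):min(d[2], oc[2] + oc[4] - 1)
    fr[, ys, xs, ] <- 0.25
    masks[, ys, xs] <- FALSE
  }
  clip$frames <- to_uint8(pmin(pmax(fr, 0), 1))
  clip$masks <- masks
  clip
}

#' Generate a labeled clip dataset
#'
#' Per-class counts are either given directly or derived from the barn
#' dataset's class mix (standing:lying:walking:mounting =
#' 1799:1947:1130:774) scaled to `total`. Clip durations are drawn per class
#' from the class's range. The dataset is byte-reproducible: identical
#' arguments and seed give identical clips.
#'
#' @param n_per_class Integer (scalar or length 4) clip counts; mutually
#'   exclusive with `total`.
#' @param total Total clip count for ratio mode.
#' @param seed Global seed; per-clip seeds are derived from it.
#' @param canvas,fps Forwarded to [scene_spec()].
#' @param degrade `"none"`, `"mild"` (gain 0.6-1, blur up to 0.8, at most
#'   one occluder) or `"heavy"` (gain 0.3-1, blur 1-2, 1-2 occluders).
#' @return List with `clips` (list of `clip_record`) and `manifest`
#'   (data.frame: id, label, duration_s, t_frames, seed).
#' @export
generate_dataset <- function(n_per_class = NULL, total = NULL, seed = 1L,
                             canvas = c(64, 64), fps = 12.5,
                             degrade = c("none", "mild", "heavy")) {
  degrade <- match.arg(degrade)
  if (is.null(n_per_class)) {
    if (is.null(total)) stop("give n_per_class or total")
    counts <- largest_remainder(BEHAVIOR_RATIOS / sum(BEHAVIOR_RATIOS), total)
  } else {
    counts <- rep_len(as.integer(n_per_class), 4L)
  }
  if (any(counts < 1)) stop("per-class counts must be >= 1")
  names(counts) <- BEHAVIOR_LEVELS
  labels <- rep(BEHAVIOR_LEVELS, counts)
  n <- length(labels)
  clip_seeds <- local_seed(seed, sample.int(2147483646L, n))
  clips <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- scene_spec(labels[i], canvas = canvas, fps = fps, seed = clip_seeds[i])
    cl <- generate_clip(sp)
    if (degrade != "none") {
      cl <- local_seed(clip_seeds[i] + 7L, {
        mild <- degrade == "mild"
        n_occ <- if (mild) stats::rbinom(1, 1, 0.5) else sample(1:2, 1)
        occ <- replicate(n_occ, simplify = FALSE,
                         c(sample.int(canvas[2] - 12L, 1), sample.int(canvas[1] - 12L, 1),
                           sample(6:14, 1), sample(6:14, 1)))
        apply_degradations(cl,
          gain = stats::runif(1, if (mild) 0.6 else 0.3, 1),
          blur_sigma = if (mild) stats::runif(1, 0, 0.8) else stats::runif(1, 1, 2),
          occluders = occ)
      })
    }
    clips[[i]] <- cl
  }
  manifest <- data.frame(id = seq_len(n), label = labels,
                         duration_s = vapply(clips, function(cl) cl$spec$duration_s, 1),
                         t_frames = vapply(clips, function(cl) cl$spec$t_frames, 1L),
                         seed = clip_seeds, stringsAsFactors = FALSE)
  list(clips = clips, manifest = manifest, counts = counts, seed = seed)
}

largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Write / read a clip dataset on disk
#'
#' Mirrors a standard video-classification layout: a `manifest.csv` (clip
#' path, label, duration, seed) plus one array bundle per clip.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory.
#' @return `write_clip_dataset()`: the manifest with paths, invisibly;
#'   `read_clip_dataset()`: a dataset list.
#' @export
write_clip_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds$manifest
  man$path <- file.path(dir, sprintf("clip_%04d.rds", man$id))
  for (i in seq_len(nrow(man))) saveRDS(ds$clips[[i]], man$path[i])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_clip_dataset
#' @export
read_clip_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  list(clips = lapply(man$path, readRDS), manifest = man)
}

#' Rule-based kinematic oracle
#'
#' Classifies a clip from segmentation features alone: Otsu thresholding and
#' connected components per frame, then (in order) a mounting test (two
#' large components in enough frames, or a median foreground area consistent
#' with two bodies), a walking test (maximum centroid displacement above a
#' threshold), and the standing/lying aspect test. Thresholds default to the
#' simulator's default geometry at a 64x64 canvas.
#'
#' @param clip A `clip_record`.
#' @param min_comp_area Minimum component area (px) to count as a body.
#' @param two_body_frac Fraction of frames with >= 2 components that
#'   triggers mounting.
#' @param area_two Median foreground area (px) consistent with two bodies.
#' @param disp_thresh Centroid displacement (px) separating walking from
#'   static jitter.
#' @param aspect_thresh Height/width ratio separating standing from lying.
#' @return A behavior label (character scalar).
#' @export
oracle_classify <- function(clip, min_comp_area = 40, two_body_frac = 0.2,
                            area_two = 420, disp_thresh = 6,
                            aspect_thresh = 1.15) {
  f <- frame_features(clip, min_comp_area)
  if (mean(f$n_comp >= 2) >= two_body_frac ||
      stats::median(f$area) >= area_two) return("mounting")
  disp <- sqrt((f$cx - f$cx[1])^2 + (f$cy - f$cy[1])^2)
  if (max(disp, na.rm = TRUE) > disp_thresh) return("walking")
  if (stats::median(f$aspect, na.rm = TRUE) >= aspect_thresh) "standing" else "lying"
}

#' Spatial-only single-frame oracle
#'
#' Classifies from one frame only. Spatial cues separate standing from lying
#' (aspect) and detect mounting (two bodies / large area), but carry no
#' motion information, so walking clips are indistinguishable from standing
#' ones and are labeled `"standing"`.
#'
#' @inheritParams oracle_classify
#' @param frame Frame index (defaults to the middle frame).
#' @return A behavior label; never `"walking"`.
#' @export
oracle_classify_frame <- function(clip, frame = NULL, min_comp_area = 40,
                                  area_two = 420, aspect_thresh = 1.15) {
  Tn <- dim(clip$frames)[1]
  frame <- frame %||% as.integer(ceiling(Tn / 2))
  f <- frame_features(clip, min_comp_area, frames = frame)
  if (f$n_comp[1] >= 2 || f$area[1] >= area_two) return("mounting")
  if (!is.na(f$aspect[1]) && f$aspect[1] >= aspect_thresh) "standing" else "lying"
}

frame_features <- function(clip, min_comp_area, frames = NULL) {
  d <- dim(clip$frames)
  frames <- frames %||% seq_len(d[1])
  n_comp <- area <- cx <- cy <- aspect <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    gray <- (clip$frames[t, , , 1] + clip$frames[t, , , 2] +
               clip$frames[t, , , 3]) / (3 * 255)
    img <- EBImage::as.Image(gray)
    th <- EBImage::otsu(img)
    lab <- EBImage::bwlabel(img > th)
    tab <- tabulate(as.integer(lab))
    big <- which(tab >= min_comp_area)
    n_comp[k] <- length(big)
    area[k] <- sum(tab[big])
    if (length(big)) {
      largest <- big[which.max(tab[big])]
      pix <- which(as.matrix(lab) == largest, arr.ind = TRUE)
      cy[k] <- mean(pix[, 1]); cx[k] <- mean(pix[, 2])
      hh <- diff(range(pix[, 1])) + 1
      ww <- diff(range(pix[, 2])) + 1
      aspect[k] <- hh / ww
    }
  }
  list(n_comp = n_comp, area = area, cx = cx, cy = cy, aspect = aspect)
}
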