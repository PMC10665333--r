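test_that("model forward: logits contract and evaluation-mode determinism", {
  set.seed(50)
  model <- build_x3dfast(tiny_cfg())
  xb <- rand5(2, 4, 3, 32, 32)
  fb <- rand5(2, 8, 3, 32, 32)
  ag_set_training(FALSE)
  l1 <- ag_no_grad(model$forward(ag_tensor(xb), ag_tensor(fb)))
  l2 <- ag_no_grad(model$forward(ag_tensor(xb), ag_tensor(fb)))
  expect_equal(dim(l1$value), c(2, 4))
  expect_identical(l1$value, l2$value)
})

test_that("cross-entropy matches closed forms and a brute-force oracle", {
  # perfect prediction -> 0
  expect_equal(cross_entropy(one_hot(c(1, 2, 4), 4), c(1, 2, 4)), 0,
               tolerance = 1e-9)
  # uniform over 4 classes -> log 4
  expect_equal(cross_entropy(matrix(0.25, 3, 4), c(2, 1, 3)), log(4),
               tolerance = 1e-12)
  expect_equal(log(4), 1.386294, tolerance = 1e-6)
  # hand evaluation: p_true = (0.9, 0.5)
  p <- rbind(c(0.9, 0.05, 0.03, 0.02), c(0.2, 0.5, 0.2, 0.1))
  expect_equal(cross_entropy(p, c(1, 2)), -(log(0.9) + log(0.5)) / 2,
               tolerance = 1e-12)
  expect_equal(-(log(0.9) + log(0.5)) / 2, 0.399254, tolerance = 1e-5)

  # brute-force oracle over random batches
  set.seed(51)
  for (i in 1:100) {
    n <- sample(1:6, 1); m <- sample(2:5, 1)
    p <- matrix(stats::rexp(n * m), n, m); p <- p / rowSums(p)
    y <- sample.int(m, n, replace = TRUE)
    manual <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
    expect_equal(cross_entropy(p, y), manual, tolerance = 1e-6)
  }

  expect_error(cross_entropy(matrix(0.3, 2, 4), c(1, 2)), "sum to 1")
  bad_y <- matrix(c(1, 1, 0, 0), 1, 4)  # two ones in a label row
  expect_error(cross_entropy(matrix(0.25, 1, 4), bad_y), "one-hot")
})

test_that("top-1 equals a counting oracle and is invariant to monotone maps", {
  set.seed(52)
  n <- 1000; m <- 4
  scores <- matrix(stats::rnorm(n * m), n, m)
  labels <- sample.int(m, n, replace = TRUE)
  hits <- 0
  for (i in seq_len(n)) {
    best <- which(scores[i, ] == max(scores[i, ]))[1]  # lowest-index tie-break
    if (best == labels[i]) hits <- hits + 1
  }
  expect_identical(top1(scores, labels), hits / n)
  expect_identical(top1(scores, labels), top1(exp(scores), labels))
  expect_identical(top1(scores, labels), top1(scores * 10 - 3, labels))
  expect_identical(top1(rbind(c(1, 0), c(0, 1)), c(1, 2)), 1)
  expect_equal(top1(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)), c(1, 2, 2, 1)), 0.5)
  expect_error(top1(matrix(0, 0, 2), integer(0)), "empty")
  # deterministic tie-break toward the lowest class index
  expect_identical(top1(matrix(1, 3, 4), c(1, 1, 2)), 2 / 3)
})

test_that("class activation maps: state guard, rectification, zero fixed point", {
  set.seed(53)
  model <- build_x3dfast(tiny_cfg())
  xb <- rand5(1, 4, 3, 32, 32); fb <- rand5(1, 8, 3, 32, 32)
  expect_error(compute_cam(model, xb, fb), "trained")
  model$trained <- TRUE
  cam <- compute_cam(model, xb, fb)
  hm <- cam$heatmaps[[1]]
  expect_equal(dim(hm), c(4, 2, 2))  # final fused volume at 32-px input
  expect_true(all(hm >= 0))
  expect_true(all(hm <= 1))
  # constant-zero clip: normalized input is constant, activations carry no
  # spatial contrast, heatmap peaks are degenerate zeros after rectification
  cam0 <- compute_cam(model, array(0, c(1, 4, 3, 32, 32)),
                      array(0, c(1, 8, 3, 32, 32)))
  expect_true(all(is.finite(cam0$heatmaps[[1]])))
  up <- compute_cam(model, xb, fb, upsample_to = c(32, 32))
  expect_equal(dim(up$heatmaps[[1]]), c(4, 32, 32))
})

test_that("ablation switches toggle independently with exact bookkeeping", {
  set.seed(54)
  build <- function(...) build_x3dfast(tiny_cfg(...))
  set.seed(54); m_full <- build()
  set.seed(54); m_noact <- build(use_action = FALSE)
  set.seed(54); m_nolat <- build(use_lateral = FALSE)
  set.seed(54); m_nor <- build(use_r2plus1d = FALSE)

  # action switch removes exactly the attention blocks
  act_params <- 0
  for (s in 1:4) {
    st <- m_full$modules$x3d$modules[[paste0("stage", s)]]
    act_params <- act_params +
      sum(vapply(st$modules[grepl("^action", names(st$modules))], n_params,
                 numeric(1)))
  }
  expect_identical(n_params(m_full) - n_params(m_noact), act_params)

  # R(2+1)D switch changes only the fast pathway
  expect_identical(n_params(m_nor$modules$x3d), n_params(m_full$modules$x3d))
  expect_false(n_params(m_nor$modules$fast) == n_params(m_full$modules$fast))
  for (nm in c("fc1", "fc2")) {
    expect_identical(n_params(m_nor$modules[[nm]]), n_params(m_full$modules[[nm]]))
  }

  # lateral switch removes the lateral blocks and narrows only the fused
  # stage inputs; the fast pathway is untouched
  expect_identical(n_params(m_nolat$modules$fast), n_params(m_full$modules$fast))
  lat_params <- sum(vapply(m_full$modules[grepl("^lateral", names(m_full$modules))],
                           n_params, numeric(1)))
  expect_gt(lat_params, 0)
  diff_total <- n_params(m_full) - n_params(m_nolat)
  widen <- n_params(m_full$modules$x3d) - n_params(m_nolat$modules$x3d)
  head_widen <- (n_params(m_full$modules$fc1) - n_params(m_nolat$modules$fc1))
  expect_identical(diff_total, lat_params + widen + head_widen)
})

test_that("checkpoint round-trip restores predictions exactly", {
  set.seed(55)
  ds <- generate_dataset(n_per_class = 2, seed = 60)
  fit <- x3dfast(ds, profile = "tiny",
                 config = train_config(seed = 3, epochs = 1))
  p1 <- predict(fit, ds, type = "logits")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  p2 <- predict(fit2, ds, type = "logits")
  expect_identical(p1, p2)
  unlink(path)
})
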