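test_that("STE branch: mask shape, sigmoid range, residual recalibration bounds", {
  set.seed(20)
  x <- rand5(2, 8, 16, 12, 12)
  blk <- action_block(16)
  r <- ste_branch(x, blk, return_mask = TRUE)
  expect_equal(dim(r$mask$value), c(2, 8, 1, 12, 12))
  expect_true(all(r$mask$value > 0 & r$mask$value < 1))
  expect_equal(dim(r$y$value), dim(x))
  # for strictly positive input, x < y < 2x elementwise
  xp <- abs(x) + 0.1
  yp <- ste_branch(xp, blk)$value
  expect_true(all(yp > xp) && all(yp < 2 * xp))
})

test_that("all-zero input is a fixed point of every branch (zero-bias configuration)", {
  set.seed(21)
  x <- array(0, c(1, 4, 8, 6, 6))
  blk <- action_block(8)
  for (f in list(ste_branch, ce_branch, me_branch)) {
    r <- f(x, blk, return_mask = TRUE)
    expect_equal(r$y$value, x)
    # sigmoid of a zero response is exactly 1/2
    expect_true(all(r$mask$value == 0.5))
  }
  expect_equal(action_module(x, blk)$value, x)
})

test_that("CE branch: spatial pooling, squeeze width, mask shape", {
  set.seed(22)
  # spatially constant input pools to its own value
  x <- array(rep(rnorm(2 * 4 * 8), times = 25), c(2, 4, 8, 5, 5))
  for (t in 1:4) for (ch in 1:8) {
    expect_equal(stats::var(as.numeric(x[1, t, ch, , ])), 0)
  }
  pooled <- ag_mean_axes(ag_tensor(x), c(4L, 5L))
  expect_equal(pooled$value[, , , 1, 1, drop = FALSE], x[, , , 1, 1, drop = FALSE])
  expect_identical(x3dfast:::squeezed_width(32, 16), 2L)
  expect_identical(x3dfast:::squeezed_width(8, 16), 1L)
  blk <- action_block(8)
  r <- ce_branch(rand5(2, 4, 8, 5, 5), blk, return_mask = TRUE)
  expect_equal(dim(r$mask$value), c(2, 4, 8, 1, 1))
  expect_true(all(r$mask$value > 0 & r$mask$value < 1))
})

test_that("ME branch: motion features, final-slot zero pad, single-frame error", {
  set.seed(23)
  blk <- action_block(16)
  x <- rand5(2, 6, 16, 8, 8)
  r <- me_branch(x, blk, return_mask = TRUE)
  expect_equal(dim(r$mask$value), c(2, 6, 16, 1, 1))

  # temporally constant input: every motion slice identical, zero pad at T
  xc <- rand5(1, 1, 16, 8, 8)
  xrep <- array(0, c(1, 5, 16, 8, 8))
  for (t in 1:5) xrep[, t, , , ] <- xc[, 1, , , ]
  fr <- blk$modules$me_squeeze$forward(ag_tensor(xrep))
  nxt <- ag_time_slice(fr, 2, 5)
  fm <- ag_sub(blk$modules$me_conv2d$forward(nxt), ag_time_slice(fr, 1, 4))
  fM <- ag_time_pad_end(fm, 1)
  expect_equal(dim(fM$value), c(1, 5, 1, 8, 8))  # (N,T,C/r,H,W), r = 16
  for (t in 2:4) expect_equal(fM$value[, t, , , ], fM$value[, 1, , , ])
  expect_true(all(fM$value[, 5, , , ] == 0))

  expect_error(me_branch(rand5(1, 1, 16, 8, 8), blk), "single-frame")
})

test_that("module output equals the average of independently computed branches", {
  set.seed(24)
  x <- rand5(2, 5, 8, 6, 6)
  blk <- action_block(8)
  out <- action_module(x, blk)
  ind <- (ste_branch(x, blk)$value + ce_branch(x, blk)$value +
            me_branch(x, blk)$value) / 3
  expect_equal(out$value, ind, tolerance = 1e-6)
  # shape contract and evaluation-mode determinism
  expect_equal(dim(out$value), dim(x))
  expect_identical(action_module(x, blk)$value, action_module(x, blk)$value)
})

test_that("masks stay inside (0,1) for arbitrary finite inputs", {
  set.seed(25)
  blk <- action_block(4)
  for (i in 1:5) {
    x <- rand5(1, 3, 4, 5, 5, sd = 10^runif(1, -2, 2))
    for (f in list(ste_branch, ce_branch, me_branch)) {
      m <- f(x, blk, return_mask = TRUE)$mask$value
      expect_true(all(m > 0 & m < 1))
    }
  }
})

test_that("attention configuration is validated", {
  expect_error(action_config(r = 0), "ratio")
  expect_error(action_config(ste_kernel = 4), "odd")
})
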