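test_that("mid-channel solver reproduces the parameter-matched factorization", {
  expect_identical(solve_mid_channels(3, 3, 64, 64), 144L)
  # both factorizations count 110 592 weights at (3,3,64,64)
  expect_equal(64 * 9 * 144 + 144 * 3 * 64, 110592)
  expect_equal(64 * 27 * 64, 110592)
  expect_identical(solve_mid_channels(3, 3, 4, 4), 9L)
  expect_equal(4 * 9 * 9 + 9 * 3 * 4, 432)
  expect_equal(4 * 27 * 4, 432)
  # degenerate configuration clamps to 1 (raw floor would give 0)
  expect_identical(solve_mid_channels(3, 1, 1, 1), 1L)
  expect_error(solve_mid_channels(0, 3, 4, 4), "positive")
  expect_error(solve_mid_channels(3, 3, -2, 4), "positive")
})

test_that("floor property holds across the kernel/channel grid", {
  for (t in c(1, 3, 5)) for (d in c(1, 3)) {
    for (n_in in c(1, 4, 16, 64)) for (n_out in c(1, 4, 16, 64)) {
      m <- solve_mid_channels(t, d, n_in, n_out)
      p3d <- n_in * t * d^2 * n_out
      pf <- function(mm) n_in * d^2 * mm + mm * t * n_out
      expect_lte(pf(m), max(p3d, pf(1)))  # clamped case admits m = 1
      if (m > 1 || pf(1) <= p3d) {
        expect_lte(pf(m), p3d)
        expect_gt(pf(m + 1), p3d)
      }
    }
  }
})

test_that("R(2+1)D unit: shape contract, weight count, doubled nonlinearities", {
  set.seed(10)
  spec <- r2plus1d_spec(3, 3, 64, 64)
  expect_identical(spec$m_mid, 144L)
  unit <- build_r2plus1d(spec)
  expect_identical(n_params(unit), 110592)
  expect_identical(unit$n_nonlinearities, 2L)
  plain <- layer_conv3d(4, 4, kernel = c(3, 3, 3))
  # a plain 3D conv unit carries a single output nonlinearity
  small <- build_r2plus1d(r2plus1d_spec(3, 3, 4, 4))
  x <- rand5(2, 8, 4, 6, 6)
  y <- small$forward(ag_tensor(x))
  expect_equal(dim(y$value), c(2, 8, 4, 6, 6))
})

test_that("depthwise-separable unit: weight accounting and shape", {
  set.seed(11)
  u <- build_depthwise_separable_3d(24, 24)
  expect_identical(n_params(u), 24 * 27 + 24 * 24)  # 1224
  expect_identical(24 * 24 * 27, 15552)
  u1 <- build_depthwise_separable_3d(1, 1)
  expect_identical(n_params(u1), 28)
  x <- rand5(1, 4, 24, 8, 8)
  expect_equal(dim(u$forward(ag_tensor(x))$value), c(1, 4, 24, 8, 8))
  # strictly fewer weights than the full 3D kernel whenever c_out > 1
  for (ci in c(2, 8, 16)) for (co in c(2, 8, 32)) {
    expect_lt(ci * 27 + ci * co, ci * co * 27)
  }
})

test_that("residual group: identity at initialization, strides, gradient flow", {
  set.seed(12)
  sp <- conv_group_spec(6, 6, style = "depthwise_separable")
  grp <- conv_group(sp)
  x <- rand5(2, 4, 6, 8, 8)
  # zero-initialized residual branch (final normalization scale 0) => identity
  expect_equal(residual_group_forward(x, grp)$value, x, tolerance = 1e-12)

  sp2 <- conv_group_spec(8, 12, stride = c(1, 2))
  y <- residual_group_forward(rand5(1, 4, 8, 16, 16), conv_group(sp2))
  expect_equal(dim(y$value), c(1, 4, 12, 8, 8))

  # gradient reaches the input through the identity shortcut
  xt <- ag_tensor(x, requires_grad = TRUE)
  out <- ag_with_grad(grp$forward(xt))
  ag_backward(out, seed = array(1, dim(out$value)))
  expect_gt(max(abs(xt$grad)), 0)

  expect_error(grp$forward(ag_tensor(rand5(1, 4, 5, 8, 8))), "channels")
})

test_that("exactly one convolution style is active per group core", {
  set.seed(13)
  for (style in c("depthwise_separable", "r2plus1d", "plain")) {
    grp <- conv_group(conv_group_spec(4, 4, style = style))
    cls <- class(grp$modules$branch)[1]
    expect_identical(cls, switch(style,
      depthwise_separable = "depthwise_separable_unit",
      r2plus1d = "r2plus1d_unit", plain = "plain_unit"))
  }
  expect_error(conv_group_spec(4, 4, stride = c(0, 1)), "stride")
})
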