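test_that("compiled conv3d matches the brute-force oracle across geometries", {
  set.seed(1)
  cases <- list(
    list(x = c(2, 5, 4, 6, 7), w = c(6, 2, 3, 3, 3), stride = c(1, 2, 2),
         pad = c(1, 1, 1), groups = 2),
    list(x = c(1, 4, 3, 5, 5), w = c(2, 3, 1, 3, 3), stride = c(1, 1, 1),
         pad = c(0, 1, 1), groups = 1),
    list(x = c(2, 8, 4, 4, 4), w = c(4, 1, 5, 1, 1), stride = c(4, 1, 1),
         pad = c(2, 0, 0), groups = 4),
    list(x = c(1, 3, 2, 6, 6), w = c(2, 2, 3, 3, 3), stride = c(1, 2, 2),
         pad = c(1, 1, 1), groups = 1))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$x)), cs$x)
    w <- array(rnorm(prod(cs$w)), cs$w)
    y <- ag_conv3d(ag_tensor(x), ag_tensor(w), stride = cs$stride,
                   pad = cs$pad, groups = cs$groups)
    expect_equal(y$value, naive_conv3d(x, w, cs$stride, cs$pad, cs$groups),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with central differences through deep compositions", {
  set.seed(2)
  x <- rand5(1, 3, 2, 4, 4)
  w1 <- ag_tensor(array(rnorm(3 * 2 * 27, sd = 0.5), c(3, 2, 3, 3, 3)),
                  requires_grad = TRUE)
  w2 <- ag_tensor(array(rnorm(2 * 3, sd = 0.5), c(2, 3, 1, 1, 1)),
                  requires_grad = TRUE)
  fwd <- function() {
    h <- ag_conv3d(ag_tensor(x), w1, pad = c(1, 1, 1))
    h <- ag_relu(h)
    h <- ag_conv3d(h, w2)
    m <- ag_sigmoid(ag_mean_axes(h, 3L))
    y <- ag_add(h, ag_mul(h, m))
    p <- ag_global_pool(y)
    sum(p$value^2)
  }
  loss <- ag_with_grad({
    h <- ag_conv3d(ag_tensor(x), w1, pad = c(1, 1, 1))
    h <- ag_relu(h)
    h <- ag_conv3d(h, w2)
    m <- ag_sigmoid(ag_mean_axes(h, 3L))
    y <- ag_add(h, ag_mul(h, m))
    p <- ag_global_pool(y)
    x3dfast:::ag_op(sum(p$value^2), list(p), function(g) list(2 * g * p$value))
  })
  ag_backward(loss)
  for (w in list(w1, w2)) {
    idx <- which.max(abs(w$grad))
    eps <- 1e-6
    old <- w$value[idx]
    w$value[idx] <- old + eps; up <- fwd()
    w$value[idx] <- old - eps; dn <- fwd()
    w$value[idx] <- old
    expect_equal((up - dn) / (2 * eps), w$grad[idx], tolerance = 1e-5)
  }
})

test_that("broadcast multiply reduces gradients over the broadcast axes", {
  set.seed(3)
  a <- ag_tensor(rand5(2, 3, 4, 2, 2), requires_grad = TRUE)
  m <- ag_tensor(array(rnorm(2 * 3 * 2 * 2), c(2, 3, 1, 2, 2)),
                 requires_grad = TRUE)
  out <- ag_with_grad(ag_mul(a, m))
  ag_backward(out, seed = array(1, dim(out$value)))
  expect_equal(dim(m$grad), dim(m$value))
  # gradient for the mask sums the other factor over channels
  expect_equal(m$grad[1, 2, 1, 1, 2], sum(a$value[1, 2, , 1, 2]),
               tolerance = 1e-12)
  expect_equal(a$grad[2, 1, 3, 2, 1], m$value[2, 1, 1, 2, 1],
               tolerance = 1e-12)
})

test_that("batch normalization: training statistics, eval determinism, gradients", {
  set.seed(4)
  bn <- layer_batchnorm(3)
  x <- rand5(4, 2, 3, 3, 3, sd = 2)
  ag_set_training(TRUE)
  y <- ag_with_grad(bn$forward(ag_tensor(x, requires_grad = TRUE)))
  # per-channel standardization
  for (ch in 1:3) {
    v <- y$value[, , ch, , ]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(stats::sd(v) * sqrt((length(v) - 1) / length(v)), 1,
                 tolerance = 1e-4)
  }
  # numerical gradient for gamma
  g <- bn$params$gamma
  ag_backward(y, seed = array(seq_along(y$value) / length(y$value), dim(y$value)))
  seedv <- array(seq_along(y$value) / length(y$value), dim(y$value))
  fwd <- function() sum(seedv * bn$forward(ag_tensor(x))$value)
  eps <- 1e-6
  old <- g$value[2]
  g$value[2] <- old + eps; up <- fwd()
  g$value[2] <- old - eps; dn <- fwd()
  g$value[2] <- old
  expect_equal((up - dn) / (2 * eps), g$grad[2], tolerance = 1e-5)
  ag_set_training(FALSE)
  e1 <- bn$forward(ag_tensor(x))$value
  e2 <- bn$forward(ag_tensor(x))$value
  expect_identical(e1, e2)
})

test_that("time slicing, zero padding and channel concatenation round-trip", {
  set.seed(5)
  x <- ag_tensor(rand5(1, 4, 2, 3, 3), requires_grad = TRUE)
  sl <- ag_with_grad(ag_time_pad_end(ag_time_slice(x, 2, 4), 1))
  expect_equal(dim(sl$value), dim(x$value))
  expect_equal(sl$value[, 4, , , ], array(0, c(1, 2, 3, 3))[1, , , ])
  a <- ag_tensor(rand5(1, 2, 3, 2, 2))
  b <- ag_tensor(rand5(1, 2, 2, 2, 2))
  cc <- ag_concat_channels(a, b)
  expect_equal(dim(cc$value)[3], 5L)
  expect_identical(cc$value[, , 1:3, , ], a$value[, , , , ])
  bad <- ag_tensor(rand5(1, 2, 2, 3, 2))
  expect_error(ag_concat_channels(a, bad), "height")
})
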