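# Shared oracles and fixtures, built in code.

# Brute-force grouped 3D convolution (independent of the compiled kernels).
naive_conv3d <- function(x, w, stride = c(1, 1, 1), pad = c(0, 0, 0),
                         groups = 1) {
  d <- dim(x); wd <- dim(w)
  N <- d[1]; Tn <- d[2]; C <- d[3]; H <- d[4]; W <- d[5]
  Cout <- wd[1]; Cg <- wd[2]; kt <- wd[3]; kh <- wd[4]; kw <- wd[5]
  To <- (Tn + 2 * pad[1] - kt) %/% stride[1] + 1
  Ho <- (H + 2 * pad[2] - kh) %/% stride[2] + 1
  Wo <- (W + 2 * pad[3] - kw) %/% stride[3] + 1
  Coutg <- Cout / groups
  y <- array(0, c(N, To, Cout, Ho, Wo))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% Coutg
    for (to in 1:To) for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- 0
      for (ci in 1:Cg) for (it in 1:kt) for (ih in 1:kh) for (iw in 1:kw) {
        ti <- (to - 1) * stride[1] - pad[1] + it
        hi <- (ho - 1) * stride[2] - pad[2] + ih
        wi <- (wo - 1) * stride[3] - pad[3] + iw
        if (ti >= 1 && ti <= Tn && hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          s <- s + x[n, ti, g * Cg + ci, hi, wi] * w[co, ci, it, ih, iw]
        }
      }
      y[n, to, co, ho, wo] <- s
    }
  }
  y
}

rand5 <- function(n, t, c, h, w, sd = 1) {
  array(stats::rnorm(n * t * c * h * w, sd = sd), c(n, t, c, h, w))
}

# a quick, quiet tiny config used by several files
tiny_cfg <- function(...) x3dfast_profile("tiny", ...)
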