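# The autodiff engine and its compiled kernels, checked against independent
# R oracles (naive loops, closed-form interpolation) and finite differences.

naive_conv2d <- function(x, w, b, stride, pad, groups) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  KH <- wd[1]; KW <- wd[2]; Cig <- wd[3]; Cout <- wd[4]
  Cog <- Cout / groups
  Ho <- (H + 2 * pad - KH) / stride + 1
  Wo <- (W + 2 * pad - KW) / stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (oc in 1:Cout) {
    g <- (oc - 1) %/% Cog
    for (oh in 1:Ho) for (ow in 1:Wo) {
      acc <- b[oc]
      for (icg in 1:Cig) for (kh in 1:KH) for (kw in 1:KW) {
        ih <- (oh - 1) * stride - pad + kh
        iw <- (ow - 1) * stride - pad + kw
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[ih, iw, g * Cig + icg, n] * w[kh, kw, icg, oc]
      }
      y[oh, ow, oc, n] <- acc
    }
  }
  y
}

test_that("compiled convolution matches a naive loop oracle", {
  set.seed(5)
  cases <- list(list(k = 3L, s = 1L, p = 1L, g = 1L, ci = 3L, co = 4L),
                list(k = 4L, s = 2L, p = 1L, g = 1L, ci = 2L, co = 3L),
                list(k = 1L, s = 1L, p = 0L, g = 1L, ci = 5L, co = 2L),
                list(k = 3L, s = 1L, p = 1L, g = 4L, ci = 4L, co = 4L))
  for (cs in cases) {
    x <- array(rnorm(8 * 8 * cs$ci * 2), c(8, 8, cs$ci, 2))
    w <- array(rnorm(cs$k * cs$k * (cs$ci / cs$g) * cs$co),
               c(cs$k, cs$k, cs$ci / cs$g, cs$co))
    b <- rnorm(cs$co)
    got <- t_conv2d(ng_tensor(x), ng_tensor(w), ng_tensor(b),
                    cs$s, cs$p, cs$g)$value
    want <- naive_conv2d(x, w, b, cs$s, cs$p, cs$g)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("bilinear upsampling matches the closed-form interpolation", {
  # 2x2 column ramp -> 4x4: half-pixel sampling gives (0, .25, .75, 1)
  x <- array(c(0, 0, 1, 1), c(2, 2, 1, 1))
  got <- t_upsample(ng_tensor(x), 4, 4)$value
  want <- matrix(rep(c(0, 0.25, 0.75, 1), each = 4), 4, 4)
  expect_equal(got[, , 1, 1], want)
  # identity when sizes match
  x2 <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  expect_identical(t_upsample(ng_tensor(x2), 6, 6)$value, x2)
  # constants stay constant under any resize
  x3 <- array(2.5, c(4, 4, 1, 1))
  expect_true(all(t_upsample(ng_tensor(x3), 9, 7)$value == 2.5))
})

test_that("max pooling picks block maxima", {
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  got <- t_maxpool2(ng_tensor(x))$value
  for (n in 1:2) for (c in 1:2) for (i in 1:4) for (j in 1:4)
    expect_equal(got[i, j, c, n],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]))
})

test_that("gradients match finite differences through composite graphs", {
  set.seed(8)
  x <- ng_tensor(array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2)),
                 requires_grad = TRUE)
  cl <- conv_layer(3, 4, 3)
  bn <- batchnorm_layer(4)
  make_loss <- function() {
    h <- t_relu(batchnorm_fwd(bn, conv_fwd(cl, x), train = TRUE))
    h <- t_maxpool2(h)
    t_mean(t_abs(t_upsample(h, 8, 8)))
  }
  loss <- make_loss()
  ng_backward(loss)
  for (p in list(x, cl$w, bn$gamma)) {
    idx <- sample(length(p$value), 4)
    fd <- fd_gradient(make_loss, p, idx)
    expect_equal(p$grad[idx], fd, tolerance = 1e-3)
    p$grad <- NULL
  }
})

test_that("gradient flows through attention-style fusion", {
  set.seed(9)
  x <- ng_tensor(array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)),
                 requires_grad = TRUE)
  wk <- ng_tensor(rep(1, 4), requires_grad = TRUE)
  make_loss <- function()
    t_mean(t_sum_channels(t_channel_scale(t_mul(t_softmax_channels(x), x), wk)))
  ng_backward(make_loss())
  for (p in list(x, wk)) {
    idx <- sample(length(p$value), 3)
    fd <- fd_gradient(make_loss, p, idx)
    expect_equal(p$grad[idx], fd, tolerance = 1e-4)
    p$grad <- NULL
  }
})

test_that("detach blocks gradients and no_grad skips graph building", {
  x <- ng_tensor(array(1, c(2, 2, 1, 1)), requires_grad = TRUE)
  y <- t_mean(t_mul(ng_detach(t_scale(x, 3)), x))
  ng_backward(y)
  expect_equal(unique(as.vector(x$grad)), 3 / 4)  # only the direct factor
  z <- ng_no_grad(t_scale(x, 2))
  expect_length(z$parents, 0)
})

test_that("Adam under a cosine schedule reduces a quadratic", {
  set.seed(2)
  p <- ng_tensor(rnorm(10), requires_grad = TRUE)
  target <- rnorm(10)
  opt <- adam_optimizer(list(p = p), lr = 0.1)
  loss0 <- sum((p$value - target)^2)
  for (e in 1:150) {
    d <- t_sub(p, ng_tensor(target))
    loss <- t_mean(t_mul(d, d))
    ng_zero_grad(list(p))
    ng_backward(loss)
    adam_step(opt, lr = cosine_lr(e - 1, 150, 0.1, 1e-3))
  }
  expect_lt(sum((p$value - target)^2), loss0 / 100)
  # schedule endpoints
  expect_equal(cosine_lr(0, 10, 1e-3, 1e-5), 1e-3)
  expect_equal(cosine_lr(9, 10, 1e-3, 1e-5), 1e-5)
})
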