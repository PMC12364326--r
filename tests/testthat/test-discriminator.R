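# Critic: trunk contracts, minibatch discrimination against a brute-force
# oracle, score symmetries and weight clipping.

small_disc <- function(...) {
  make_discriminator(disc_config(widths = c(4L, 8L, 16L, 32L),
                                 input_size = 32L, ...))
}

# double-loop oracle for the minibatch-discrimination arithmetic
mb_oracle <- function(X, W, beta, sigma) {
  b <- nrow(X); k <- ncol(W)
  Z <- matrix(0, b, k)
  for (i in 1:b) for (j in 1:k)
    Z[i, j] <- sum(X[i, ] * W[, j]) + beta[j]
  D <- matrix(0, b, b); K <- matrix(0, b, b)
  for (i in 1:b) for (j in 1:b) {
    D[i, j] <- sum((Z[i, ] - Z[j, ])^2)
    K[i, j] <- exp(-D[i, j] / (2 * sigma^2))
  }
  M <- numeric(b)
  for (i in 1:b) M[i] <- mean(K[i, ])
  list(Z = Z, D = D, K = K, M = M)
}

test_that("minibatch discrimination handles the degenerate cases exactly", {
  W <- matrix(0.5, 2, 2); beta <- c(0, 0)
  one <- minibatch_discrimination(matrix(c(1, 2), 1, 2), W, beta, 1)
  expect_equal(one$D, matrix(0, 1, 1))
  expect_equal(one$K, matrix(1, 1, 1))
  expect_equal(one$M, 1.0)
  two <- minibatch_discrimination(matrix(1, 2, 2), W, beta, 1)
  expect_true(all(two$D == 0))
  expect_true(all(two$K == 1))
  expect_equal(two$M, c(1, 1))
})

test_that("minibatch discrimination matches the double-loop oracle", {
  set.seed(41)
  X <- matrix(rnorm(3 * 2), 3, 2)
  W <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  beta <- c(0.05, -0.05)
  got <- minibatch_discrimination(X, W, beta, 1)
  want <- mb_oracle(X, W, beta, 1)
  for (f in c("Z", "D", "K", "M"))
    expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
})

test_that("minibatch state invariants hold under both bandwidth modes", {
  set.seed(42)
  for (rep in 1:20) {
    b <- sample(1:8, 1); n <- sample(2:16, 1); k <- sample(1:4, 1)
    X <- matrix(rnorm(b * n), b, n)
    W <- matrix(rnorm(n * k, sd = 0.5), n, k)
    beta <- rnorm(k)
    for (sigma in c(1.0, k / (2 * n))) {
      st <- minibatch_discrimination(X, W, beta, sigma)
      expect_equal(st$D, t(st$D))
      expect_true(all(diag(st$D) == 0))
      expect_true(all(st$D >= 0))
      if (sigma == 1.0) {
        # strict positivity holds numerically at a moderate bandwidth;
        # the as-printed sigma = k/(2n) underflows exp() to exactly 0
        expect_true(all(st$K > 0 & st$K <= 1))
      } else {
        expect_true(all(st$K >= 0 & st$K <= 1))
      }
      expect_true(all(diag(st$K) == 1))
      expect_true(all(st$M > 0 & st$M <= 1))
    }
  }
  expect_error(minibatch_discrimination(matrix(c(1, NA), 1, 2),
                                        matrix(1, 2, 1), 0, 1), "finite")
})

test_that("trunk output is input/16 and zero input gives zero features", {
  set.seed(43)
  d <- small_disc()
  x <- ng_tensor(array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  tr <- ng_no_grad(disc_trunk(d, x, train = FALSE))
  expect_equal(dim(tr$features[[4]]$value)[1:2], c(2, 2))
  expect_equal(dim(tr$flat$value), c(2, 32 * 2 * 2))
  # zero input with zero biases and eval-mode norm stays zero
  z <- ng_tensor(array(0, c(32, 32, 3, 2)))
  trz <- ng_no_grad(disc_trunk(d, z, train = FALSE))
  for (k in 1:4) expect_true(all(trz$features[[k]]$value == 0))
  expect_error(disc_trunk(d, ng_tensor(array(0, c(30, 30, 3, 1)))),
               "divisible")
})

test_that("evaluation-mode scoring is deterministic and permutation-symmetric", {
  set.seed(44)
  d <- small_disc()
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  s1 <- disc_score(d, x)
  s2 <- disc_score(d, x)
  expect_identical(s1$per_sample, s2$per_sample)
  perm <- c(3, 1, 4, 2)
  s3 <- disc_score(d, x[, , , perm, drop = FALSE])
  expect_equal(s3$per_sample, s1$per_sample[perm], tolerance = 1e-9)
  # duplicated samples get equal scores
  xd <- x[, , , c(1, 1, 1, 1), drop = FALSE]
  sd <- disc_score(d, xd)
  expect_lt(diff(range(sd$per_sample)), 1e-12)
})

test_that("similarity M is higher for collapsed batches than diverse ones", {
  set.seed(45)
  d <- make_discriminator(disc_config(widths = c(4L, 8L, 16L, 32L),
                                      input_size = 32L,
                                      mb_sigma_mode = "fixed", mb_sigma = 1))
  diverse <- array(runif(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  collapsed <- diverse
  for (j in 2:6) collapsed[, , , j] <- collapsed[, , , 1]
  m_of <- function(x) {
    tr <- ng_no_grad(disc_trunk(d, ng_tensor(x), train = FALSE))
    sigma <- d$config$mb_sigma
    mean(minibatch_discrimination(tr$flat$value, d$mb$W$value,
                                  d$mb$beta$value, sigma)$M)
  }
  expect_gt(m_of(collapsed), m_of(diverse))
})

test_that("a zero-weight head scores every sample at its bias", {
  set.seed(46)
  d <- small_disc()
  d$head$w$value[] <- 0
  d$head$b$value[] <- 0.37
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  s <- disc_score(d, x)
  expect_equal(s$per_sample, rep(0.37, 3))
  expect_equal(s$batch_mean, 0.37)
})

test_that("weight clipping bounds every trainable parameter", {
  set.seed(47)
  d <- small_disc()
  params <- collect_params(d)
  params[[1]]$value[1] <- 0.5
  params[[2]]$value[1] <- -0.001
  clip_weights(d, c(-0.012, 0.012))
  expect_equal(params[[1]]$value[1], 0.012)
  expect_equal(params[[2]]$value[1], -0.001)
  expect_lte(max_abs_param(d), 0.012)
  expect_error(clip_weights(d, c(0.2, 0.1)), "lo < hi")
})

test_that("config validation rejects bad dropout, clipping and input size", {
  expect_error(disc_config(dropout_rate = 1), "dropout")
  expect_error(disc_config(clip_range = c(0.1, -0.1)), "lo < hi")
  expect_error(disc_config(input_size = 40L), "divisible by 16")
})
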