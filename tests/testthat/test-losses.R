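# The loss ledger: closed-form spot checks, brute-force per-pixel oracles,
# aggregation identities and consistency between the numeric forms and the
# differentiable training ops.

bce_oracle <- function(logits, label, w) {
  acc <- 0
  for (i in seq_along(logits)) {
    s <- 1 / (1 + exp(-logits[i]))
    acc <- acc - (w * label[i] * log(s) + (1 - label[i]) * log(1 - s))
  }
  acc
}

test_that("adversarial loss is the symmetric absolute difference", {
  expect_equal(adversarial_loss(0.3, 0.3), 0)
  expect_equal(adversarial_loss(0.7, 0.3), 0.4)
  expect_equal(adversarial_loss(0.2, 0.9), adversarial_loss(0.9, 0.2))
})

test_that("the balance weight is N_neg/N_pos with an empty-label fallback", {
  expect_equal(balanced_positive_weight(matrix(0, 8, 8)), 1)
  half <- matrix(c(rep(1, 32), rep(0, 32)), 8, 8)
  expect_equal(balanced_positive_weight(half), 1)
  lab <- matrix(0, 16, 16); lab[1:4] <- 1
  expect_equal(balanced_positive_weight(lab), 252 / 4)
})

test_that("weighted BCE matches closed forms and the brute-force oracle", {
  # single pixel, y = 1, logit 0, w = 1 -> log 2
  expect_equal(weighted_bce_level(matrix(0), matrix(1), 1), log(2))
  # perfect-prediction limit
  lab <- matrix(c(1, 0, 0, 1), 2, 2)
  strong <- (2 * lab - 1) * 40
  expect_lt(weighted_bce_level(strong, lab, 3), 1e-10)
  # random instances against the double loop
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:16, 1)
    logits <- matrix(rnorm(n * n, sd = 2), n, n)
    lab <- matrix(rbinom(n * n, 1, 0.3), n, n)
    w <- runif(1, 0.5, 20)
    expect_equal(weighted_bce_level(logits, lab, w),
                 bce_oracle(logits, lab, w), tolerance = 1e-9)
  }
  expect_error(weighted_bce_level(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("aggregated mask loss sums per-level terms with per-level weights", {
  set.seed(52)
  mask <- matrix(0L, 16, 16); mask[6:9, 6:9] <- 1L
  pyr <- build_pyramid(mask, levels = 4)
  logits <- lapply(pyr$levels, function(l) matrix(rnorm(length(l)), nrow(l)))
  out <- aggregated_mask_loss(logits, pyr)
  expect_equal(out$L_ds, sum(out$per_level))
  for (k in 1:4)
    expect_equal(out$per_level[k],
                 weighted_bce_level(logits[[k]], pyr$levels[[k]],
                                    balanced_positive_weight(pyr$levels[[k]])))
  # a coarse level with 1 positive of 4 pixels uses weight 3 at that level only
  lv2 <- list(matrix(0, 4, 4), matrix(0, 2, 2))
  lab2 <- list(matrix(0, 4, 4), matrix(c(1, 0, 0, 0), 2, 2))
  out2 <- aggregated_mask_loss(list(matrix(0, 4, 4), matrix(0, 2, 2)), lab2)
  expect_equal(out2$balance_weights, c(1, 3))
  # perfect prediction at all levels vanishes
  strong <- lapply(pyr$levels, function(l) (2 * l - 1) * 40)
  expect_lt(aggregated_mask_loss(strong, pyr)$L_ds, 1e-8)
  expect_error(aggregated_mask_loss(logits[1:3], pyr), "mismatch")
})

test_that("critic loss bookkeeping is -L_a - L_ds and monotone in L_a", {
  expect_equal(discriminator_loss(0.4, 0.6), -1)
  expect_equal(discriminator_loss(0, 0), 0)
  expect_lt(discriminator_loss(0.9, 0.5), discriminator_loss(0.1, 0.5))
})

test_that("edge loss is the weighted BCE sum against the edge pyramid", {
  set.seed(53)
  mask <- matrix(0L, 16, 16); mask[5:11, 5:11] <- 1L
  pyr <- build_pyramid(extract_edge_map(mask), kind = "edge")
  logits <- lapply(pyr$levels, function(l) matrix(rnorm(length(l)), nrow(l)))
  out <- edge_loss(logits, pyr)
  manual <- sum(vapply(1:4, function(k)
    weighted_bce_level(logits[[k]], pyr$levels[[k]],
                       balanced_positive_weight(pyr$levels[[k]])),
    numeric(1)))
  expect_equal(out$L_ge, manual, tolerance = 1e-9)
  # empty edge labels with strongly negative logits vanish
  empty <- lapply(pyr$levels, function(l) l * 0L)
  neg <- lapply(pyr$levels, function(l) matrix(-40, nrow(l), ncol(l)))
  expect_lt(aggregated_mask_loss(neg, empty)$L_ds, 1e-8)
})

test_that("Dice loss matches direct substitution", {
  a <- matrix(0, 8, 8); a[2:3, 2:3] <- 1
  expect_equal(dice_loss(a, a), 0, tolerance = 1e-6)
  b <- matrix(0, 8, 8); b[6:7, 6:7] <- 1
  expect_equal(dice_loss(a, b), 1, tolerance = 1e-6)
  # |truth| = 4, |pred| = 4, overlap 2 -> 0.5
  p <- matrix(0, 8, 8); p[2:3, 2:4] <- 1; p <- p * 0
  p[2, 2:5] <- 1          # 4 predicted
  y <- matrix(0, 8, 8); y[2, 4:7] <- 1  # 4 true, overlap 2
  expect_equal(dice_loss(p, y), 0.5, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("generator composite loss is the stated weighted sum", {
  expect_equal(generator_loss(0.1, 2.0, 0.5, loss_weights(1, 1)), 2.6)
  expect_equal(generator_loss(0.1, 2.0, 0.5, loss_weights(0, 0)), 0.1)
  # linearity in each term
  w <- loss_weights(0.7, 1.3)
  base <- generator_loss(0.2, 1.0, 0.4, w)
  expect_equal(generator_loss(0.2, 2.0, 0.4, w) - base, 0.7)
  expect_equal(generator_loss(0.2, 1.0, 1.4, w) - base, 1.3)
  expect_error(loss_weights(-1, 0), "nonnegative")
})

test_that("differentiable loss ops agree with the numeric ledger", {
  set.seed(54)
  # balanced BCE: tensor op (batch mean of per-image sums) vs numeric form
  for (rep in 1:5) {
    z <- array(rnorm(8 * 8 * 2, sd = 2), c(8, 8, 1, 2))
    y <- array(rbinom(8 * 8 * 2, 1, 0.2), c(8, 8, 1, 2))
    got <- t_bce_balanced(ng_tensor(z), y)$value
    want <- mean(vapply(1:2, function(n) {
      w <- balanced_positive_weight(y[, , 1, n])
      weighted_bce_level(z[, , 1, n], y[, , 1, n], w)
    }, numeric(1)))
    expect_equal(got, want, tolerance = 1e-9)
  }
  # Dice op vs numeric form
  p <- array(runif(8 * 8), c(8, 8, 1, 1))
  y <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  expect_equal(t_dice(ng_tensor(p), y)$value,
               dice_loss(p[, , 1, 1], y[, , 1, 1]), tolerance = 1e-9)
})

test_that("edge supervision concentrates gradient on true edge pixels", {
  set.seed(55)
  ratios <- vapply(1:5, function(s) {
    set.seed(100 + s)
    gen <- make_generator(gen_config(base_widths = c(4L, 8L, 16L, 32L)))
    mask <- matrix(0L, 32, 32)
    mask[10:22, 10:22] <- 1L
    pyr <- build_pyramid(extract_edge_map(mask), kind = "edge")
    x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
    fwd <- generator_forward(gen, x, train = TRUE)
    lab <- array(pyr$levels[[1]], c(32, 32, 1, 1))
    loss <- t_bce_balanced(fwd$side$native[[1]], lab)
    # gradient on the full-resolution side output logits
    s1 <- fwd$side$native[[1]]
    s1$retain <- TRUE
    ng_backward(loss)
    g <- abs(s1$grad[, , 1, 1])
    edge_px <- pyr$levels[[1]] == 1
    bg_px <- !edge_px & mask == 0
    mean(g[edge_px]) / mean(g[bg_px])
  }, numeric(1))
  # on-edge gradients dominate background gradients for untrained nets
  expect_gt(mean(ratios > 1), 0.8)
  expect_gt(mean(ratios), 2)
})
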