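# Differentiable operations on ng_tensor nodes. Feature maps use the
# [H, W, C, N] layout throughout (column-major, row index fastest); vectors
# of per-sample quantities are N x 1 matrices.

stable_sigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

# log(sigmoid(z)) without overflow
stable_logsigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- -log1p(exp(-z[pos]))
  out[!pos] <- z[!pos] - log1p(exp(z[!pos]))
  out
}

as_t <- function(x) if (is_tensor(x)) x else ng_tensor(x)

#' @rdname tensor-ops
#' @export
t_add <- function(a, b) {
  a <- as_t(a); b <- as_t(b)
  ng_node(a$value + b$value, list(a, b),
          function(g) list(g, g), "add")
}

#' @rdname tensor-ops
#' @export
t_sub <- function(a, b) {
  a <- as_t(a); b <- as_t(b)
  ng_node(a$value - b$value, list(a, b),
          function(g) list(g, -g), "sub")
}

#' @rdname tensor-ops
#' @export
t_mul <- function(a, b) {
  a <- as_t(a); b <- as_t(b)
  av <- a$value; bv <- b$value
  ng_node(av * bv, list(a, b),
          function(g) list(g * bv, g * av), "mul")
}

#' @rdname tensor-ops
#' @export
t_scale <- function(a, s) {
  ng_node(a$value * s, list(a), function(g) list(g * s), "scale")
}

#' @rdname tensor-ops
#' @export
t_abs <- function(a) {
  sgn <- sign(a$value)
  ng_node(abs(a$value), list(a), function(g) list(g * sgn), "abs")
}

#' @rdname tensor-ops
#' @export
t_mean <- function(a) {
  n <- length(a$value)
  ng_node(mean(a$value), list(a),
          function(g) list(array(as.numeric(g) / n, dim = dim(a$value) %||% n)),
          "mean")
}

#' @rdname tensor-ops
#' @export
t_sum <- function(a) {
  ng_node(sum(a$value), list(a),
          function(g) list(array(as.numeric(g), dim = dim(a$value) %||% length(a$value))),
          "sum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname tensor-ops
#' @export
t_relu <- function(a) {
  keep <- a$value > 0
  ng_node(a$value * keep, list(a), function(g) list(g * keep), "relu")
}

#' @rdname tensor-ops
#' @export
t_leaky_relu <- function(a, slope = 0.2) {
  pos <- a$value > 0
  mult <- ifelse(pos, 1, slope)
  ng_node(a$value * mult, list(a), function(g) list(g * mult), "lrelu")
}

#' @rdname tensor-ops
#' @export
t_sigmoid <- function(a) {
  s <- stable_sigmoid(a$value)
  ng_node(s, list(a), function(g) list(g * s * (1 - s)), "sigmoid")
}

#' Dropout (inverted scaling)
#'
#' Active only when `train = TRUE`; identity in evaluation mode. Uses the
#' global R RNG so training remains reproducible under a seed.
#'
#' @param a input tensor.
#' @param rate drop probability in [0, 1).
#' @param train logical, training mode flag.
#' @rdname tensor-ops
#' @export
t_dropout <- function(a, rate, train = TRUE) {
  if (!train || rate <= 0) return(a)
  keep <- (stats::runif(length(a$value)) >= rate) / (1 - rate)
  dim(keep) <- dim(a$value)
  ng_node(a$value * keep, list(a), function(g) list(g * keep), "dropout")
}

#' Grouped 2-D convolution
#'
#' @param x input tensor, dim `[H, W, C, N]`.
#' @param w weight tensor, dim `[KH, KW, C/groups, Cout]`.
#' @param b bias tensor, length `Cout`.
#' @param stride,pad,groups convolution geometry.
#' @rdname tensor-ops
#' @export
t_conv2d <- function(x, w, b, stride = 1L, pad = 1L, groups = 1L) {
  xv <- x$value; wv <- w$value
  y <- cpp_conv2d_fwd(xv, wv, b$value, as.integer(stride), as.integer(pad),
                      as.integer(groups))
  xdim <- dim(xv); wdim <- dim(wv)
  ng_node(y, list(x, w, b), function(g) {
    gx <- if (isTRUE(x$requires_grad))
      cpp_conv2d_bwd_input(g, wv, xdim, as.integer(stride), as.integer(pad),
                           as.integer(groups)) else NULL
    gw <- cpp_conv2d_bwd_weight(g, xv, wdim, as.integer(stride),
                                as.integer(pad), as.integer(groups))
    gb <- apply(g, 3, sum)
    list(gx, gw, gb)
  }, "conv2d")
}

#' @rdname tensor-ops
#' @export
t_maxpool2 <- function(x) {
  fw <- cpp_maxpool2_fwd(x$value)
  xdim <- dim(x$value)
  idx <- fw$index
  ng_node(fw$value, list(x),
          function(g) list(cpp_maxpool2_bwd(g, idx, xdim)), "maxpool2")
}

#' Bilinear resize to a target spatial size
#'
#' Half-pixel coordinate convention; exact identity when sizes match.
#'
#' @param x input tensor `[H, W, C, N]`.
#' @param out_h,out_w target spatial size.
#' @rdname tensor-ops
#' @export
t_upsample <- function(x, out_h, out_w = out_h) {
  d <- dim(x$value)
  if (d[1] == out_h && d[2] == out_w) return(x)
  y <- cpp_bilinear_fwd(x$value, as.integer(out_h), as.integer(out_w))
  ng_node(y, list(x),
          function(g) list(cpp_bilinear_bwd(g, d[1], d[2])), "upsample")
}

#' Flatten feature maps to a sample-by-feature matrix
#'
#' `[H, W, C, N]` becomes `[N, H*W*C]`.
#' @rdname tensor-ops
#' @export
t_flatten <- function(x) {
  d <- dim(x$value)
  m <- t(matrix(x$value, prod(d[1:3]), d[4]))
  ng_node(m, list(x), function(g) {
    gx <- t(g)
    dim(gx) <- d
    list(gx)
  }, "flatten")
}

#' Global average pooling to a `[N, C]` matrix
#' @rdname tensor-ops
#' @export
t_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- t(matrix(colMeans(matrix(x$value, hw, d[3] * d[4])), d[3], d[4]))
  ng_node(m, list(x), function(g) {
    # g is [N, C]; broadcast g/(H*W) over the spatial grid
    gx <- array(rep(as.vector(t(g)) / hw, each = hw), dim = d)
    list(gx)
  }, "gap")
}

#' Affine (fully connected) layer op: `X %*% W + b`
#'
#' @param x tensor, `[N, F]` matrix.
#' @param w tensor, `[F, K]` matrix.
#' @param b tensor, length-K bias.
#' @rdname tensor-ops
#' @export
t_linear <- function(x, w, b) {
  xv <- x$value; wv <- w$value
  y <- xv %*% wv + matrix(b$value, nrow(xv), length(b$value), byrow = TRUE)
  ng_node(y, list(x, w, b), function(g) {
    gx <- if (isTRUE(x$requires_grad)) g %*% t(wv) else NULL
    list(gx, t(xv) %*% g, colSums(g))
  }, "linear")
}

#' Column-bind per-sample descriptor matrices
#' @param ... tensors, each an `[N, k_i]` matrix.
#' @rdname tensor-ops
#' @export
t_cbind <- function(...) {
  parts <- lapply(list(...), as_t)
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  y <- do.call(cbind, lapply(parts, function(p) p$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ng_node(y, parts, function(g) {
    lapply(seq_along(parts), function(i) g[, starts[i]:ends[i], drop = FALSE])
  }, "cbind")
}

#' Stack single-channel maps along the channel axis
#' @param maps list of tensors, each `[H, W, 1, N]`.
#' @rdname tensor-ops
#' @export
t_cat_channels <- function(maps) {
  d <- dim(maps[[1]]$value)
  K <- length(maps)
  y <- array(0, c(d[1], d[2], K, d[4]))
  for (k in seq_len(K)) y[, , k, ] <- maps[[k]]$value
  ng_node(y, maps, function(g) {
    lapply(seq_len(K), function(k) {
      gk <- g[, , k, , drop = FALSE]
      dim(gk) <- d
      gk
    })
  }, "cat_channels")
}

#' Softmax across the channel axis (per pixel, per sample)
#' @rdname tensor-ops
#' @export
t_softmax_channels <- function(x) {
  d <- dim(x$value)
  K <- d[3]
  # permute channels first so each column of the K x (H*W*N) matrix is a pixel
  ap <- aperm(x$value, c(3, 1, 2, 4))
  m <- matrix(ap, K)
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  sm <- aperm(array(m, c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
  ng_node(sm, list(x), function(g) {
    gp <- matrix(aperm(g, c(3, 1, 2, 4)), K)
    dot <- colSums(m * gp)
    gx <- m * sweep(gp, 2, dot)
    list(aperm(array(gx, c(K, d[1], d[2], d[4])), c(2, 3, 1, 4)))
  }, "softmax_c")
}

#' Scale each channel by a trainable scalar
#'
#' @param x tensor `[H, W, K, N]`.
#' @param w tensor, length-K parameter vector.
#' @rdname tensor-ops
#' @export
t_channel_scale <- function(x, w) {
  d <- dim(x$value)
  K <- d[3]
  wv <- as.vector(w$value)
  y <- x$value
  for (k in seq_len(K)) y[, , k, ] <- y[, , k, , drop = FALSE] * wv[k]
  ng_node(y, list(x, w), function(g) {
    gx <- g
    gw <- numeric(K)
    for (k in seq_len(K)) {
      gx[, , k, ] <- g[, , k, , drop = FALSE] * wv[k]
      gw[k] <- sum(g[, , k, ] * x$value[, , k, ])
    }
    list(gx, gw)
  }, "channel_scale")
}

#' Sum over the channel axis, keeping a singleton channel
#' @rdname tensor-ops
#' @export
t_sum_channels <- function(x) {
  d <- dim(x$value)
  y <- array(0, c(d[1], d[2], 1, d[4]))
  for (k in seq_len(d[3])) y <- y + x$value[, , k, , drop = FALSE]
  ng_node(y, list(x), function(g) {
    gx <- array(0, d)
    for (k in seq_len(d[3])) gx[, , k, ] <- g
    list(gx)
  }, "sum_channels")
}

#' Gate per-channel features with a `[N, C]` matrix of scalars
#'
#' Used by the squeeze-excitation step of the inverted residual block:
#' every channel map of sample n is multiplied by `gate[n, c]`.
#' @rdname tensor-ops
#' @export
t_channel_gate <- function(x, gate) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  gv <- gate$value
  ge <- array(rep(as.vector(t(gv)), each = hw), dim = d)
  ng_node(x$value * ge, list(x, gate), function(g) {
    gx <- g * ge
    # gate gradient: sum of g * x over each channel's spatial grid -> [N, C]
    gg <- t(matrix(colSums(matrix(g * x$value, hw, d[3] * d[4])), d[3], d[4]))
    list(gx, gg)
  }, "channel_gate")
}

#' Mask a composite with a single-channel map
#'
#' Element-wise product of `x` (`[H, W, C, N]`) with `m` (`[H, W, 1, N]`),
#' broadcasting the mask over channels. This realises the masked regions
#' fed to the critic.
#' @rdname tensor-ops
#' @export
t_mask_apply <- function(x, m) {
  d <- dim(x$value)
  C <- d[3]
  mv <- m$value
  y <- x$value
  for (c in seq_len(C)) y[, , c, ] <- y[, , c, , drop = FALSE] * mv
  ng_node(y, list(x, m), function(g) {
    gx <- g
    gm <- array(0, dim(mv))
    for (c in seq_len(C)) {
      gx[, , c, ] <- g[, , c, , drop = FALSE] * mv
      gm <- gm + g[, , c, , drop = FALSE] * x$value[, , c, , drop = FALSE]
    }
    list(gx, gm)
  }, "mask_apply")
}

#' Gaussian-kernel minibatch discrimination (differentiable op)
#'
#' Projects flattened critic features `X` (`[b, n]`) with `W` (`[n, k]`) and
#' bias `beta`, computes the pairwise squared-distance matrix of the
#' projections, a Gaussian similarity kernel with bandwidth `sigma`, and the
#' per-sample mean similarity vector `M` returned as a `[b, 1]` matrix.
#'
#' @param x tensor `[b, n]`.
#' @param w tensor `[n, k]`.
#' @param beta tensor, length-k bias.
#' @param sigma kernel bandwidth (positive scalar).
#' @rdname tensor-ops
#' @export
t_mbdisc <- function(x, w, beta, sigma) {
  st <- minibatch_discrimination(x$value, w$value, beta$value, sigma)
  b <- nrow(st$Z)
  Z <- st$Z; K <- st$K
  ng_node(matrix(st$M, ncol = 1), list(x, w, beta), function(g) {
    gv <- as.vector(g)
    # dL/dz_p = (1/(b sigma^2)) * sum_j (g_p + g_j) * K[p, j] * (z_j - z_p)
    gZ <- matrix(0, b, ncol(Z))
    for (p in seq_len(b)) {
      coef <- (gv[p] + gv) * K[p, ]           # length b
      diff <- sweep(Z, 2, Z[p, ])             # z_j - z_p
      gZ[p, ] <- colSums(coef * diff) / (b * sigma^2)
    }
    gX <- if (isTRUE(x$requires_grad)) gZ %*% t(w$value) else NULL
    list(gX, t(x$value) %*% gZ, colSums(gZ))
  }, "mbdisc")
}

#' Class-balanced binary cross-entropy with logits (differentiable op)
#'
#' Implements the self-balanced BCE used for deep supervision: for each
#' sample the positive term is weighted by `N_neg/N_pos` computed from that
#' sample's label (1 when the label is empty), the per-pixel terms are
#' summed (not averaged), and the batch is reduced by the mean.
#'
#' @param logits tensor `[H, W, 1, N]`.
#' @param labels binary array of the same dim (plain array, not a tensor).
#' @return scalar tensor.
#' @rdname tensor-ops
#' @export
t_bce_balanced <- function(logits, labels) {
  d <- dim(logits$value)
  N <- d[4]
  z <- logits$value
  y <- labels
  wpos <- numeric(N)
  for (n in seq_len(N)) {
    yn <- y[, , , n]
    npos <- sum(yn)
    wpos[n] <- if (npos > 0) (length(yn) - npos) / npos else 1
  }
  wmap <- array(rep(wpos, each = d[1] * d[2] * d[3]), dim = d)
  lsig <- stable_logsigmoid(z)
  lsig_neg <- stable_logsigmoid(-z)
  loss <- -sum(wmap * y * lsig + (1 - y) * lsig_neg) / N
  ng_node(loss, list(logits), function(g) {
    s <- stable_sigmoid(z)
    gx <- (wmap * y * (s - 1) + (1 - y) * s) * (as.numeric(g) / N)
    list(gx)
  }, "bce_balanced")
}

#' Soft Dice loss (differentiable op)
#'
#' One minus the soft Dice coefficient between a probability map and a
#' binary truth, computed per sample and averaged over the batch. A small
#' smoothing constant keeps the empty/empty case finite.
#'
#' @param prob tensor `[H, W, 1, N]` of probabilities.
#' @param truth binary array with the same dim.
#' @param eps smoothing constant.
#' @rdname tensor-ops
#' @export
t_dice <- function(prob, truth, eps = 1e-6) {
  d <- dim(prob$value)
  N <- d[4]
  p <- prob$value
  num <- den <- numeric(N)
  for (n in seq_len(N)) {
    pn <- p[, , , n]; yn <- truth[, , , n]
    num[n] <- 2 * sum(pn * yn) + eps
    den[n] <- sum(pn) + sum(yn) + eps
  }
  loss <- mean(1 - num / den)
  ng_node(loss, list(prob), function(g) {
    gx <- array(0, d)
    for (n in seq_len(N)) {
      yn <- truth[, , , n]
      gx[, , , n] <- -(2 * yn * den[n] - num[n]) / den[n]^2
    }
    list(gx * (as.numeric(g) / N))
  }, "dice")
}
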