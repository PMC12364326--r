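# Four-layer convolutional critic with feature matching and Gaussian-kernel
# minibatch discrimination. The critic scores masked composites x*y (real)
# against x*yhat (predicted); its parameters are clipped to a small interval
# after every update to keep it Lipschitz.

#' Discriminator configuration
#'
#' @param widths channel counts of the four stride-2 convolution stages.
#' @param dropout_rate dropout applied after every stage (default 20%).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param mb_out_dim projection dimension k of the minibatch-discrimination
#'   layer.
#' @param mb_sigma_mode `"as_printed"` sets the Gaussian bandwidth to
#'   `k / (2 n)` where `n` is the flattened feature dimension; `"fixed"`
#'   uses `mb_sigma`.
#' @param mb_sigma bandwidth used when `mb_sigma_mode = "fixed"`.
#' @param use_mb enable the minibatch-discrimination layer.
#' @param clip_range two-element numeric, weight-clipping interval.
#' @param in_channels input channels (3 for pseudo-colour composites).
#' @param input_size spatial size of the input (must be divisible by 16).
#' @return a `disc_config` list.
#' @export
disc_config <- function(widths = c(16L, 32L, 64L, 128L),
                        dropout_rate = 0.2,
                        leaky_slope = 0.2,
                        mb_out_dim = 8L,
                        mb_sigma_mode = c("as_printed", "fixed"),
                        mb_sigma = 1.0,
                        use_mb = TRUE,
                        clip_range = c(-0.012, 0.012),
                        in_channels = 3L,
                        input_size = 128L) {
  mb_sigma_mode <- match.arg(mb_sigma_mode)
  stopifnot(length(widths) == 4, all(widths >= 1))
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (clip_range[1] >= clip_range[2])
    stop("clip_range must satisfy lo < hi")
  if (input_size %% 16 != 0)
    stop("input_size must be divisible by 16 (four stride-2 stages)")
  structure(list(widths = as.integer(widths), dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope, mb_out_dim = as.integer(mb_out_dim),
                 mb_sigma_mode = mb_sigma_mode, mb_sigma = mb_sigma,
                 use_mb = isTRUE(use_mb), clip_range = clip_range,
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size)),
            class = "disc_config")
}

#' Build the critic
#'
#' Four stride-2 convolution stages (conv 4x4, batch norm, LeakyReLU,
#' dropout), a minibatch-discrimination layer on the flattened final
#' features, and a linear score head over pooled per-stage descriptors
#' concatenated with the pooled input (feature matching) and the similarity
#' vector M.
#'
#' @param config a [disc_config()].
#' @return a discriminator module list.
#' @export
make_discriminator <- function(config = disc_config()) {
  w <- config$widths
  ic <- config$in_channels
  stages <- list()
  prev <- ic
  for (i in 1:4) {
    stages[[i]] <- list(conv = conv_layer(prev, w[i], k = 4L, stride = 2L, pad = 1L),
                        bn = batchnorm_layer(w[i]))
    prev <- w[i]
  }
  final_hw <- config$input_size %/% 16L
  n_flat <- final_hw * final_hw * w[4]
  k <- config$mb_out_dim
  mb <- list(W = ng_tensor(matrix(stats::rnorm(n_flat * k, sd = sqrt(1 / n_flat)),
                                  n_flat, k), requires_grad = TRUE),
             beta = ng_tensor(numeric(k), requires_grad = TRUE))
  desc_dim <- sum(w) + ic + if (config$use_mb) 1L else 0L
  head <- linear_layer(desc_dim, 1L)
  structure(list(config = config, stages = stages, mb = mb, head = head,
                 n_flat = n_flat),
            class = "nodulegan_discriminator")
}

mb_bandwidth <- function(config, n_flat) {
  if (config$mb_sigma_mode == "as_printed") config$mb_out_dim / (2 * n_flat)
  else config$mb_sigma
}

#' Critic trunk: four convolution stages
#'
#' @param disc a discriminator from [make_discriminator()].
#' @param x input tensor `[H, W, C, N]` (a masked composite).
#' @param train training-mode flag (enables batch statistics and dropout).
#' @return list with `features` (per-stage tensors) and `flat`
#'   (`[N, n]` tensor of flattened final features).
#' @export
disc_trunk <- function(disc, x, train = TRUE) {
  d <- dim(x$value)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("discriminator input spatial size must be divisible by 16")
  if (d[3] != disc$config$in_channels)
    stop("discriminator input channel count does not match config")
  feats <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    st <- disc$stages[[i]]
    h <- conv_fwd(st$conv, h)
    h <- batchnorm_fwd(st$bn, h, train = train)
    h <- t_leaky_relu(h, disc$config$leaky_slope)
    h <- t_dropout(h, disc$config$dropout_rate, train = train)
    feats[[i]] <- h
  }
  list(features = feats, flat = t_flatten(h))
}

#' Gaussian-kernel minibatch discrimination (reference computation)
#'
#' Projects the flattened feature matrix `X` (`b x n`) to `Z = X W + beta`
#' (`b x k`), computes the pairwise squared Euclidean distance matrix `D`,
#' the Gaussian similarity kernel `K = exp(-D / (2 sigma^2))` and the
#' per-sample mean similarity `M_i = mean_j K_ij`. This is the exported,
#' plain-matrix form used both by the critic and as the behavioural contract
#' for the differentiable layer.
#'
#' @param X numeric matrix `b x n` of flattened per-sample features.
#' @param W numeric projection matrix `n x k`.
#' @param beta numeric length-k bias vector.
#' @param sigma positive kernel bandwidth.
#' @return a `minibatch_state` list with fields `X`, `W`, `beta`, `Z`, `D`,
#'   `K`, `M`, `sigma`.
#' @export
minibatch_discrimination <- function(X, W, beta, sigma) {
  X <- as.matrix(X)
  if (!all(is.finite(X)))
    stop("minibatch_discrimination: non-finite values in feature matrix X")
  if (nrow(X) < 1) stop("minibatch_discrimination: need at least one sample")
  if (sigma <= 0) stop("minibatch_discrimination: sigma must be positive")
  Z <- X %*% W + matrix(beta, nrow(X), length(beta), byrow = TRUE)
  rs <- rowSums(Z^2)
  D <- outer(rs, rs, "+") - 2 * Z %*% t(Z)
  D <- pmax(D, 0)
  diag(D) <- 0
  K <- exp(-D / (2 * sigma^2))
  M <- rowMeans(K)
  structure(list(X = X, W = W, beta = beta, Z = Z, D = D, K = K, M = M,
                 sigma = sigma),
            class = "minibatch_state")
}

#' Critic forward pass: per-sample scores
#'
#' The per-sample descriptor concatenates global-average-pooled features of
#' every trunk stage, the pooled input (feature matching) and, when enabled,
#' the minibatch similarity entry `M_i`; a linear head maps it to a scalar
#' realism score.
#'
#' @param disc a discriminator module.
#' @param x input tensor or `[H, W, C, N]` array (masked composites).
#' @param train training-mode flag.
#' @return list with `scores` (`[N, 1]` tensor), `mean_score` (scalar
#'   tensor), and `mb` (the minibatch similarity tensor or `NULL`).
#' @export
disc_forward <- function(disc, x, train = TRUE) {
  if (!is_tensor(x)) x <- ng_tensor(x)
  tr <- disc_trunk(disc, x, train = train)
  pooled <- lapply(tr$features, t_gap)
  pooled[[length(pooled) + 1L]] <- t_gap(x)
  mb_t <- NULL
  if (disc$config$use_mb) {
    sigma <- mb_bandwidth(disc$config, disc$n_flat)
    mb_t <- t_mbdisc(tr$flat, disc$mb$W, disc$mb$beta, sigma)
    pooled[[length(pooled) + 1L]] <- mb_t
  }
  desc <- do.call(t_cbind, pooled)
  scores <- linear_fwd(disc$head, desc)
  list(scores = scores, mean_score = t_mean(scores), mb = mb_t)
}

#' Score a batch of masked composites
#'
#' Evaluation-mode convenience wrapper around [disc_forward()].
#'
#' @param disc a discriminator module.
#' @param images `[H, W, C, N]` array of masked composites.
#' @return list with numeric `per_sample` scores and their `batch_mean`.
#' @export
disc_score <- function(disc, images) {
  out <- ng_no_grad(disc_forward(disc, ng_tensor(images), train = FALSE))
  list(per_sample = as.vector(out$scores$value),
       batch_mean = as.numeric(out$mean_score$value))
}

#' Clip every trainable parameter of a module to an interval
#'
#' Applied to the critic after each optimizer update to enforce a Lipschitz
#' constraint (weight clipping).
#'
#' @param module any module whose parameters are found by
#'   [collect_params()].
#' @param clip_range numeric `(lo, hi)` with `lo < hi`.
#' @return the module, invisibly (parameters are modified in place).
#' @export
clip_weights <- function(module, clip_range = c(-0.012, 0.012)) {
  if (clip_range[1] >= clip_range[2]) stop("clip_range must satisfy lo < hi")
  for (p in collect_params(module))
    p$value <- pmin(pmax(p$value, clip_range[1]), clip_range[2])
  invisible(module)
}

#' Largest absolute parameter value of a module
#'
#' Bookkeeping helper used to verify the clipping postcondition.
#' @param module a module list.
#' @return max of `abs(parameter)` over all trainable parameters.
#' @export
max_abs_param <- function(module) {
  max(vapply(collect_params(module), function(p) max(abs(p$value)), numeric(1)))
}
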