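# Layer constructors and the optimizer. A layer is a plain list holding its
# parameter tensors (and, for batch norm, an environment with running
# statistics); forward passes are explicit functions so the whole network
# stays inspectable.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Convolution layer constructor
#'
#' @param in_ch,out_ch channel counts.
#' @param k kernel size (square).
#' @param stride,pad,groups geometry; `pad` defaults to "same" for stride 1.
#' @return layer list with parameter tensors `w`, `b`.
#' @keywords internal
conv_layer <- function(in_ch, out_ch, k = 3L, stride = 1L,
                       pad = as.integer(k %/% 2), groups = 1L) {
  fan_in <- k * k * in_ch / groups
  list(type = "conv",
       w = ng_tensor(he_init(c(k, k, in_ch %/% groups, out_ch), fan_in),
                     requires_grad = TRUE),
       b = ng_tensor(numeric(out_ch), requires_grad = TRUE),
       stride = as.integer(stride), pad = as.integer(pad),
       groups = as.integer(groups))
}

conv_fwd <- function(layer, x) {
  t_conv2d(x, layer$w, layer$b, layer$stride, layer$pad, layer$groups)
}

#' Linear layer constructor
#' @keywords internal
linear_layer <- function(in_f, out_f, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / in_f)
  list(type = "linear",
       w = ng_tensor(matrix(stats::rnorm(in_f * out_f, sd = sd), in_f, out_f),
                     requires_grad = TRUE),
       b = ng_tensor(numeric(out_f), requires_grad = TRUE))
}

linear_fwd <- function(layer, x) t_linear(x, layer$w, layer$b)

#' Batch normalization layer constructor
#'
#' Keeps running mean/variance in an environment so evaluation-mode forward
#' passes are deterministic.
#' @keywords internal
batchnorm_layer <- function(ch, momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  list(type = "batchnorm",
       gamma = ng_tensor(rep(1, ch), requires_grad = TRUE),
       beta = ng_tensor(numeric(ch), requires_grad = TRUE),
       state = st, momentum = momentum, eps = eps, ch = ch)
}

batchnorm_fwd <- function(layer, x, train = TRUE) {
  d <- dim(x$value)
  ch <- d[3]
  eps <- layer$eps
  # channel-major reshape: rows index (H, W, N), columns index channels
  to_mat <- function(a) matrix(aperm(a, c(1, 2, 4, 3)), ncol = ch)
  from_mat <- function(m) aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  xm <- to_mat(x$value)
  m <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    layer$state$running_mean <- (1 - layer$momentum) * layer$state$running_mean +
      layer$momentum * mu
    layer$state$running_var <- (1 - layer$momentum) * layer$state$running_var +
      layer$momentum * v * m / max(m - 1, 1)
  } else {
    mu <- layer$state$running_mean
    v <- layer$state$running_var
    xc <- sweep(xm, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  gamma <- layer$gamma; beta <- layer$beta
  y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  ng_node(from_mat(y), list(x, gamma, beta), function(g) {
    gm <- to_mat(g)
    gxhat <- sweep(gm, 2, gamma$value, "*")
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    if (train) {
      # standard batch-norm backward through the batch statistics
      s1 <- colSums(gxhat)
      s2 <- colSums(gxhat * xhat)
      gx <- sweep(gxhat, 2, s1 / m) - sweep(xhat, 2, s2 / m, "*")
      gx <- sweep(gx, 2, inv_sd, "*")
    } else {
      gx <- sweep(gxhat, 2, inv_sd, "*")
    }
    list(from_mat(gx), ggamma, gbeta)
  }, "batchnorm")
}

#' Collect all parameter tensors of a (nested) module
#'
#' Walks a nested list structure and returns every `ng_tensor` with
#' `requires_grad = TRUE`, depth-first, with stable names.
#'
#' @param module nested list of layers.
#' @return named list of parameter tensors.
#' @export
collect_params <- function(module) {
  out <- list()
  walk <- function(x, prefix) {
    if (is_tensor(x)) {
      if (isTRUE(x$requires_grad)) out[[prefix]] <<- x
      return(invisible())
    }
    if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste(prefix, nm, sep = "."))
      }
    }
  }
  walk(module, "p")
  out
}

#' Extract / restore the numeric state of a module
#'
#' `module_state()` returns all parameter values and batch-norm running
#' statistics as plain numeric arrays; `load_module_state()` writes them
#' back. Used by checkpointing.
#'
#' @param module nested list of layers.
#' @return named list of arrays.
#' @export
module_state <- function(module) {
  params <- lapply(collect_params(module), function(p) p$value)
  buffers <- list()
  walk <- function(x, prefix) {
    if (is.list(x) && !is_tensor(x)) {
      if (identical(x$type, "batchnorm")) {
        buffers[[paste0(prefix, ".running_mean")]] <<- x$state$running_mean
        buffers[[paste0(prefix, ".running_var")]] <<- x$state$running_var
      }
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        if (is.list(x[[i]]) && !is_tensor(x[[i]]))
          walk(x[[i]], paste(prefix, nm, sep = "."))
      }
    }
  }
  walk(module, "b")
  list(params = params, buffers = buffers)
}

#' @rdname module_state
#' @param state a list produced by `module_state()`.
#' @export
load_module_state <- function(module, state) {
  params <- collect_params(module)
  stopifnot(identical(sort(names(params)), sort(names(state$params))))
  for (nm in names(params)) params[[nm]]$value <- state$params[[nm]]
  walk <- function(x, prefix) {
    if (is.list(x) && !is_tensor(x)) {
      if (identical(x$type, "batchnorm")) {
        x$state$running_mean <- state$buffers[[paste0(prefix, ".running_mean")]]
        x$state$running_var <- state$buffers[[paste0(prefix, ".running_var")]]
      }
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        if (is.list(x[[i]]) && !is_tensor(x[[i]]))
          walk(x[[i]], paste(prefix, nm, sep = "."))
      }
    }
  }
  walk(module, "b")
  invisible(module)
}

#' Adam optimizer
#'
#' @param params named list of parameter tensors.
#' @param lr learning rate.
#' @param betas first/second moment decay rates.
#' @param eps numerical stabilizer.
#' @return optimizer object (environment).
#' @export
adam_optimizer <- function(params, lr = 1e-3, betas = c(0.9, 0.999),
                           eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$beta1 <- betas[1]
  opt$beta2 <- betas[2]
  opt$eps <- eps
  opt$t <- 0
  opt$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  opt$v <- opt$m
  class(opt) <- "ng_adam"
  opt
}

#' Perform one Adam update
#'
#' @param opt optimizer from [adam_optimizer()].
#' @param lr optional learning-rate override for this step (scheduler hook).
#' @export
adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    p$value <- p$value - step
  }
  invisible(opt)
}

#' Cosine-annealed learning rate
#'
#' Standard cosine annealing from `lr0` down to `lr_floor` over `total`
#' scheduling units (epochs here).
#'
#' @param step current unit, 0-based.
#' @param total annealing period.
#' @param lr0 initial learning rate.
#' @param lr_floor final learning rate.
#' @return the learning rate for `step`.
#' @export
cosine_lr <- function(step, total, lr0 = 1e-3, lr_floor = 1e-5) {
  if (total <= 1) return(lr0)
  frac <- min(max(step / (total - 1), 0), 1)
  lr_floor + 0.5 * (lr0 - lr_floor) * (1 + cos(pi * frac))
}
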