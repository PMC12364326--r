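# Alternating adversarial training. Each iteration takes one critic step
# (minimise L_d = -L_a on masked real vs predicted regions, then clip the
# critic's weights) and one generator step (minimise
# L_g = L_a + w_e*L_ge + w_s*L_gs, plus the multi-level mask term L_ds,
# whose gradient only exists through the generator). All randomness flows
# from the config seed, so runs are reproducible and resumable.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001
#' and momenta (0.9, 0.999), batch size 64, cosine-annealed learning rate,
#' critic weight clipping to `[-0.012, 0.012]`. Ablation flags switch between
#' plain U-Net, deeply supervised U-Net, and the adversarial variants with
#' and without minibatch discrimination and inverted residual stem.
#'
#' @param batch_size samples per iteration (>= 2 when `use_mb`).
#' @param lr initial learning rate (> 0).
#' @param betas Adam momentum parameters.
#' @param epochs training epochs (cosine annealing period).
#' @param seed master seed for all randomness.
#' @param image_size composite size; divisible by 16.
#' @param channels 1 (single slice) or 3 (pseudo-colour).
#' @param use_gan adversarial training on/off.
#' @param use_mb minibatch discrimination in the critic.
#' @param use_ir inverted residual stem in the generator.
#' @param use_hed side outputs + attention fusion (off = plain U-Net).
#' @param use_lds multi-level mask supervision.
#' @param use_lge multi-level edge supervision.
#' @param omega_e,omega_s loss weights (edge, Dice).
#' @param clip_range critic weight-clipping interval.
#' @param lr_floor cosine annealing floor.
#' @param gen_widths,disc_widths network stage widths.
#' @param max_iters optional hard cap on iterations (smoke runs).
#' @param literal_lds_in_disc record L_ds inside L_d (literal bookkeeping);
#'   it contributes no critic gradient either way.
#' @param mb_sigma_mode,mb_sigma critic kernel bandwidth, see
#'   [disc_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 64L, lr = 1e-3, betas = c(0.9, 0.999),
                         epochs = 10L, seed = 1L, image_size = 128L,
                         channels = 3L, use_gan = TRUE, use_mb = TRUE,
                         use_ir = TRUE, use_hed = TRUE, use_lds = TRUE,
                         use_lge = TRUE, omega_e = 1, omega_s = 1,
                         clip_range = c(-0.012, 0.012), lr_floor = 1e-5,
                         gen_widths = c(32L, 64L, 128L, 256L),
                         disc_widths = c(16L, 32L, 64L, 128L),
                         max_iters = NULL, literal_lds_in_disc = FALSE,
                         mb_sigma_mode = "fixed", mb_sigma = 1.0) {
  if (lr <= 0) stop("lr must be positive")
  if (isTRUE(use_mb) && isTRUE(use_gan) && batch_size < 2)
    stop("batch_size must be >= 2 when minibatch discrimination is enabled")
  if (!channels %in% c(1, 3)) stop("channels must be 1 or 3")
  structure(list(batch_size = as.integer(batch_size), lr = lr, betas = betas,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 use_gan = isTRUE(use_gan), use_mb = isTRUE(use_mb),
                 use_ir = isTRUE(use_ir), use_hed = isTRUE(use_hed),
                 use_lds = isTRUE(use_lds), use_lge = isTRUE(use_lge),
                 omega_e = omega_e, omega_s = omega_s,
                 clip_range = clip_range, lr_floor = lr_floor,
                 gen_widths = as.integer(gen_widths),
                 disc_widths = as.integer(disc_widths),
                 max_iters = if (is.null(max_iters)) NULL else as.integer(max_iters),
                 literal_lds_in_disc = isTRUE(literal_lds_in_disc),
                 mb_sigma_mode = mb_sigma_mode, mb_sigma = mb_sigma),
            class = "train_config")
}

#' Ablation presets
#'
#' Named model-architecture configurations: `"unet"` (plain U-Net, no
#' adversary), `"hed_unet"` (deep supervision, no adversary), `"gan"`
#' (adversarial, no minibatch discrimination), `"gan_mb"` (+ minibatch
#' discrimination), `"gan_mb_ir"` (+ inverted residual stem); and loss
#' configurations `"loss_adv_dice"`, `"loss_adv_lds_dice"`, `"loss_full"`
#' toggling the supervision terms on the full model.
#'
#' @param name preset name.
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
ablation_config <- function(name = c("unet", "hed_unet", "gan", "gan_mb",
                                     "gan_mb_ir", "loss_adv_dice",
                                     "loss_adv_lds_dice", "loss_full"), ...) {
  name <- match.arg(name)
  flags <- switch(name,
    unet = list(use_gan = FALSE, use_hed = FALSE, use_ir = FALSE,
                use_mb = FALSE, use_lds = FALSE, use_lge = FALSE),
    hed_unet = list(use_gan = FALSE, use_hed = TRUE, use_ir = FALSE,
                    use_mb = FALSE, use_lds = TRUE, use_lge = TRUE),
    gan = list(use_gan = TRUE, use_hed = TRUE, use_ir = FALSE,
               use_mb = FALSE),
    gan_mb = list(use_gan = TRUE, use_hed = TRUE, use_ir = FALSE,
                  use_mb = TRUE),
    gan_mb_ir = list(use_gan = TRUE, use_hed = TRUE, use_ir = TRUE,
                     use_mb = TRUE),
    loss_adv_dice = list(use_gan = TRUE, use_hed = TRUE, use_mb = TRUE,
                         use_ir = TRUE, use_lds = FALSE, use_lge = FALSE),
    loss_adv_lds_dice = list(use_gan = TRUE, use_hed = TRUE, use_mb = TRUE,
                             use_ir = TRUE, use_lds = TRUE, use_lge = FALSE),
    loss_full = list(use_gan = TRUE, use_hed = TRUE, use_mb = TRUE,
                     use_ir = TRUE, use_lds = TRUE, use_lge = TRUE))
  do.call(train_config, modifyList(flags, list(...)))
}

# stack composite samples into batch arrays for the given indices
assemble_batch <- function(dataset, idx, channels) {
  sz <- dim(dataset[[1]]$image)[1]
  n <- length(idx)
  x <- array(0, c(sz, sz, channels, n))
  y <- array(0, c(sz, sz, 1L, n))
  for (j in seq_along(idx)) {
    im <- dataset[[idx[j]]]$image
    x[, , , j] <- if (channels == 3) im else im[, , 2]
    y[, , 1, j] <- dataset[[idx[j]]]$mask
  }
  lv_dims <- vapply(dataset[[1]]$y_d$levels, nrow, integer(1))
  stack_pyr <- function(field) {
    lapply(seq_len(4), function(k) {
      a <- array(0, c(lv_dims[k], lv_dims[k], 1L, n))
      for (j in seq_along(idx))
        a[, , 1, j] <- dataset[[idx[j]]][[field]]$levels[[k]]
      a
    })
  }
  list(x = x, y = y, y_d = stack_pyr("y_d"), y_g = stack_pyr("y_g"))
}

# build generator/critic modules and their optimizers from a train_config
init_model <- function(config) {
  gcfg <- gen_config(in_channels = config$channels,
                     base_widths = config$gen_widths,
                     use_inverted_residual = config$use_ir,
                     use_hed = config$use_hed)
  gen <- make_generator(gcfg)
  disc <- NULL
  if (config$use_gan) {
    dcfg <- disc_config(widths = config$disc_widths,
                        use_mb = config$use_mb,
                        clip_range = config$clip_range,
                        in_channels = config$channels,
                        input_size = config$image_size,
                        mb_sigma_mode = config$mb_sigma_mode,
                        mb_sigma = config$mb_sigma)
    disc <- make_discriminator(dcfg)
  }
  opt_g <- adam_optimizer(collect_params(gen), lr = config$lr,
                          betas = config$betas)
  opt_d <- if (!is.null(disc))
    adam_optimizer(collect_params(disc), lr = config$lr, betas = config$betas)
  else NULL
  structure(list(gen = gen, disc = disc, opt_g = opt_g, opt_d = opt_d,
                 config = config, iter = 0L,
                 history = list()),
            class = "nodulegan_model")
}

# compute the supervised tensor losses for the generator step
supervised_losses <- function(fwd, batch, config) {
  out <- list(L_ds = NULL, L_ge = NULL, L_gs = NULL, L_seg = NULL)
  out$L_gs <- t_dice(fwd$prob, batch$y)
  if (config$use_hed) {
    if (config$use_lds) {
      terms <- lapply(1:4, function(k)
        t_bce_balanced(fwd$side$native[[k]], batch$y_d[[k]]))
      out$L_ds <- Reduce(t_add, terms)
    }
    if (config$use_lge) {
      terms <- lapply(1:4, function(k)
        t_bce_balanced(fwd$side$native[[k]], batch$y_g[[k]]))
      out$L_ge <- Reduce(t_add, terms)
    }
  } else {
    # plain U-Net has no side outputs; supervise the single head directly
    out$L_seg <- t_bce_balanced(fwd$logit, batch$y)
  }
  out
}

check_finite_losses <- function(row, model, iter) {
  vals <- unlist(row)
  bad <- is.nan(vals) | is.infinite(vals)  # NA marks an unused term
  if (!any(bad)) return(invisible())
  norms <- vapply(collect_params(model$gen),
                  function(p) sqrt(sum(p$value^2)), numeric(1))
  stop(sprintf(
    "non-finite loss at iteration %d: %s | generator parameter norm range [%.3g, %.3g]",
    iter, paste(names(vals)[bad], collapse = ", "),
    min(norms), max(norms)))
}

#' Train the segmentation model
#'
#' Runs alternating critic/generator optimization (or plain supervised
#' training when `use_gan = FALSE`) on a list of preprocessed composites.
#'
#' @param dataset list of `composite_sample` objects (see
#'   [preprocess_dataset()]).
#' @param config a [train_config()].
#' @param resume optional checkpoint (from [load_checkpoint()] or a
#'   previous [train_model()] result) to continue from; config is taken
#'   from the checkpoint.
#' @param epochs optional override of the number of additional epochs when
#'   resuming.
#' @return a `nodulegan_model` with the trained modules, the config and a
#'   per-iteration `history` data frame (losses, learning rate, critic
#'   parameter bound).
#' @export
train_model <- function(dataset, config = train_config(), resume = NULL,
                        epochs = NULL) {
  if (!length(dataset)) stop("empty dataset")
  if (!is.null(resume)) {
    model <- resume
    config <- model$config
    assign(".Random.seed", model$rng, envir = globalenv())
  } else {
    set.seed(config$seed)
    model <- init_model(config)
  }
  n <- length(dataset)
  bs <- min(config$batch_size, n)
  iters_per_epoch <- max(1L, n %/% bs)
  total_epochs <- if (!is.null(epochs)) epochs else config$epochs
  total_iters <- if (!is.null(config$max_iters)) config$max_iters
  else iters_per_epoch * total_epochs
  start_iter <- model$iter
  gen <- model$gen; disc <- model$disc
  history <- model$history
  while (model$iter < start_iter + total_iters) {
    it <- model$iter + 1L
    epoch <- (it - 1L) %/% iters_per_epoch
    lr_t <- cosine_lr(epoch, max(config$epochs, 1L), config$lr, config$lr_floor)
    idx <- sample.int(n, bs, replace = n < bs)
    batch <- assemble_batch(dataset, idx, config$channels)
    row <- list(iter = it, epoch = epoch + 1L, lr = lr_t, L_a = NA_real_,
                L_ds = NA_real_, L_d = NA_real_, L_ge = NA_real_,
                L_gs = NA_real_, L_g = NA_real_, d_max_param = NA_real_)
    x_t <- ng_tensor(batch$x)
    if (config$use_gan) {
      # ---- critic step: generator output treated as a constant ----
      yhat_const <- ng_no_grad(generator_forward(gen, x_t, train = TRUE))$prob$value
      fake_in <- ng_tensor(batch$x)
      real_in <- ng_tensor(batch$x)
      f_t <- t_mask_apply(fake_in, ng_tensor(yhat_const))
      r_t <- t_mask_apply(real_in, ng_tensor(batch$y))
      sf <- disc_forward(disc, f_t, train = TRUE)
      sr <- disc_forward(disc, r_t, train = TRUE)
      L_a_d <- t_abs(t_sub(sf$mean_score, sr$mean_score))
      L_d <- t_scale(L_a_d, -1)
      ng_zero_grad(model$opt_d$params)
      ng_backward(L_d)
      adam_step(model$opt_d, lr = lr_t)
      clip_weights(disc, config$clip_range)
      row$d_max_param <- max_abs_param(disc)
    }
    # ---- generator step ----
    fwd <- generator_forward(gen, x_t, train = TRUE)
    sup <- supervised_losses(fwd, batch, config)
    L_g_t <- t_scale(sup$L_gs, config$omega_s)
    row$L_gs <- as.numeric(sup$L_gs$value)
    if (config$use_gan) {
      sf2 <- disc_forward(disc, t_mask_apply(x_t, fwd$prob), train = TRUE)
      r_plain <- mask_apply_plain(batch$x, batch$y)
      sr2 <- disc_forward(disc, ng_tensor(r_plain), train = TRUE)
      L_a_g <- t_abs(t_sub(sf2$mean_score, sr2$mean_score))
      L_g_t <- t_add(L_g_t, L_a_g)
      row$L_a <- as.numeric(L_a_g$value)
    }
    if (!is.null(sup$L_ge)) {
      L_g_t <- t_add(L_g_t, t_scale(sup$L_ge, config$omega_e))
      row$L_ge <- as.numeric(sup$L_ge$value)
    }
    if (!is.null(sup$L_ds)) {
      # gradient of the multi-level mask loss only exists through the
      # generator; apply it in this step regardless of the bookkeeping
      L_g_t <- t_add(L_g_t, sup$L_ds)
      row$L_ds <- as.numeric(sup$L_ds$value)
    }
    if (!is.null(sup$L_seg)) L_g_t <- t_add(L_g_t, sup$L_seg)
    row$L_g <- as.numeric(L_g_t$value)
    if (config$use_gan) {
      row$L_d <- -(if (is.na(row$L_a)) 0 else row$L_a) -
        (if (config$literal_lds_in_disc && !is.na(row$L_ds)) row$L_ds else 0)
    }
    ng_zero_grad(model$opt_g$params)
    if (!is.null(model$opt_d)) ng_zero_grad(model$opt_d$params)
    ng_backward(L_g_t)
    adam_step(model$opt_g, lr = lr_t)
    if (!is.null(model$opt_d)) ng_zero_grad(model$opt_d$params)
    check_finite_losses(row[c("L_a", "L_ds", "L_ge", "L_gs", "L_g", "L_d")],
                        model, it)
    history[[length(history) + 1L]] <- row
    model$iter <- it
  }
  model$history <- history
  model$rng <- get(".Random.seed", globalenv())
  model$gen <- gen
  model$disc <- disc
  model
}

mask_apply_plain <- function(x, m) {
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c, ] <- out[, , c, , drop = FALSE] * m
  out
}

#' Training history as a data frame
#'
#' @param model a `nodulegan_model`.
#' @return data frame with one row per iteration.
#' @export
training_history <- function(model) {
  do.call(rbind, lapply(model$history, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Predict nodule masks
#'
#' Deterministic inference: dropout off, norm layers in running-statistics
#' mode, binarisation at 0.5.
#'
#' @param model a trained `nodulegan_model` (or loaded checkpoint).
#' @param composites list of `composite_sample` objects or a
#'   `[H, W, C, N]` array.
#' @param threshold binarisation threshold.
#' @return list with `prob` (`[H, W, N]` array) and `masks`
#'   (list of binary matrices).
#' @export
predict_masks <- function(model, composites, threshold = 0.5) {
  config <- model$config
  if (is.list(composites) && !is.array(composites)) {
    sz <- dim(composites[[1]]$image)[1]
    x <- array(0, c(sz, sz, config$channels, length(composites)))
    for (j in seq_along(composites)) {
      im <- composites[[j]]$image
      x[, , , j] <- if (config$channels == 3) im else im[, , 2]
    }
  } else x <- composites
  fwd <- ng_no_grad(generator_forward(model$gen, ng_tensor(x), train = FALSE))
  d <- dim(fwd$prob$value)
  prob <- array(fwd$prob$value, c(d[1], d[2], d[4]))
  masks <- lapply(seq_len(d[4]), function(j) {
    m <- (prob[, , j] >= threshold) * 1L
    matrix(as.integer(m), d[1], d[2])
  })
  list(prob = prob, masks = masks)
}

#' Save a training checkpoint
#'
#' Serialises the architecture config, all parameter values and running
#' statistics, the optimizer state and the RNG state, so training can
#' resume bit-identically.
#'
#' @param model a `nodulegan_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  ckpt <- list(config = model$config,
               gen_state = module_state(model$gen),
               disc_state = if (!is.null(model$disc)) module_state(model$disc),
               opt_g = list(m = model$opt_g$m, v = model$opt_g$v,
                            t = model$opt_g$t),
               opt_d = if (!is.null(model$opt_d))
                 list(m = model$opt_d$m, v = model$opt_d$v, t = model$opt_d$t),
               iter = model$iter, rng = model$rng,
               history = model$history,
               package_version = as.character(utils::packageVersion("nodulegan")))
  saveRDS(ckpt, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return a `nodulegan_model` ready for [predict_masks()] or for resuming
#'   via `train_model(resume = )`.
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  model <- init_model(ckpt$config)
  load_module_state(model$gen, ckpt$gen_state)
  if (!is.null(model$disc)) {
    if (is.null(ckpt$disc_state))
      stop("checkpoint does not match config: critic state missing")
    load_module_state(model$disc, ckpt$disc_state)
  }
  model$opt_g$m <- ckpt$opt_g$m; model$opt_g$v <- ckpt$opt_g$v
  model$opt_g$t <- ckpt$opt_g$t
  if (!is.null(model$opt_d)) {
    model$opt_d$m <- ckpt$opt_d$m; model$opt_d$v <- ckpt$opt_d$v
    model$opt_d$t <- ckpt$opt_d$t
  }
  model$iter <- ckpt$iter
  model$rng <- ckpt$rng
  model$history <- ckpt$history
  model
}
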