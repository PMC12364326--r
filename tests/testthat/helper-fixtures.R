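# Shared fixtures: tiny phantoms and preprocessed datasets built in code.

tiny_phantom_config <- function(..., seed = 11L) {
  phantom_config(volume_shape = c(5L, 48L, 48L),
                 nodule_radius_range = c(5, 9),
                 n_vessels = 2L, seed = seed, ...)
}

# small, high-contrast solid phantoms preprocessed to 32x32 composites
smoke_dataset <- function(n = 12L, seed = 7L, size = 32L) {
  pcfg <- phantom_config(volume_shape = c(5L, 48L, 48L),
                         nodule_radius_range = c(5, 9),
                         nodule_kind = "solid", n_vessels = 2L)
  preprocess_dataset(generate_dataset(n, pcfg, seed = seed), size = size)
}

smoke_train_config <- function(..., seed = 3L) {
  train_config(batch_size = 8L, epochs = 4L, image_size = 32L,
               gen_widths = c(8L, 16L, 32L, 64L),
               disc_widths = c(8L, 16L, 32L, 64L),
               seed = seed, ...)
}

# finite-difference gradient comparison used by the engine tests
fd_gradient <- function(make_loss, param, indices, eps = 1e-5) {
  vapply(indices, function(i) {
    v0 <- param$value[i]
    param$value[i] <- v0 + eps
    lp <- ng_no_grad(make_loss())$value
    param$value[i] <- v0 - eps
    lm <- ng_no_grad(make_loss())$value
    param$value[i] <- v0
    (lp - lm) / (2 * eps)
  }, numeric(1))
}
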