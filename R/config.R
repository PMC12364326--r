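# Run configuration: one nested list materialising every tunable default,
# serialised losslessly as YAML. Unknown keys are rejected so typos cannot
# silently fall back to defaults.

#' Default run configuration
#'
#' Nested sections `data`, `preprocessing`, `generator`, `discriminator`,
#' `losses`, `training`, `evaluation`, holding every tunable default of the
#' pipeline.
#'
#' @return a `run_config` nested list.
#' @export
run_config <- function() {
  structure(list(
    data = list(
      n_samples = 64L,
      volume_shape = c(9L, 160L, 160L),
      nodule_radius_range = c(3, 15),
      nodule_kind = "solid",
      n_vessels = 4L,
      vessel_radius_range = c(1, 3),
      background_hu = c(-800, 40),
      seed = 1L),
    preprocessing = list(
      window_level = -600,
      window_width = 1200,
      roi_size = 128L,
      edge_method = "boundary"),
    generator = list(
      in_channels = 3L,
      base_widths = c(32L, 64L, 128L, 256L),
      expansion_factor = 4L,
      use_inverted_residual = TRUE,
      use_hed = TRUE),
    discriminator = list(
      widths = c(16L, 32L, 64L, 128L),
      dropout_rate = 0.2,
      leaky_slope = 0.2,
      mb_out_dim = 8L,
      mb_sigma_mode = "fixed",
      mb_sigma = 1.0,
      use_mb = TRUE,
      clip_range = c(-0.012, 0.012)),
    losses = list(
      omega_e = 1,
      omega_s = 1,
      use_lds = TRUE,
      use_lge = TRUE),
    training = list(
      batch_size = 64L,
      lr = 1e-3,
      betas = c(0.9, 0.999),
      epochs = 10L,
      lr_floor = 1e-5,
      seed = 1L,
      max_iters = NULL),
    evaluation = list(
      threshold = 0.5,
      aggregate = "macro")),
    class = "run_config")
}

# recursively check cfg against the reference structure; unknown keys error
check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref))
      stop("unknown configuration key: ", here)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        length(names(ref[[nm]])) > 0) {
      if (!is.list(cfg[[nm]]))
        stop("configuration key ", here, " must be a section")
      check_known_keys(cfg[[nm]], ref[[nm]], here)
    }
  }
  invisible(TRUE)
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the defaults of [run_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- run_config()
  check_known_keys(user, base)
  merged <- modifyList(base, user)
  class(merged) <- "run_config"
  merged
}

#' Write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Changes whenever any field changes; recorded in provenance and logs.
#'
#' @param config any serialisable object.
#' @return character hash.
#' @export
config_hash <- function(config) digest::digest(unclass(config))

#' Build a [train_config()] from a run configuration
#'
#' @param config a `run_config`.
#' @return a `train_config`.
#' @export
as_train_config <- function(config) {
  train_config(
    batch_size = config$training$batch_size,
    lr = config$training$lr,
    betas = config$training$betas,
    epochs = config$training$epochs,
    seed = config$training$seed,
    image_size = config$preprocessing$roi_size,
    channels = config$generator$in_channels,
    use_mb = config$discriminator$use_mb,
    use_ir = config$generator$use_inverted_residual,
    use_hed = config$generator$use_hed,
    use_lds = config$losses$use_lds,
    use_lge = config$losses$use_lge,
    omega_e = config$losses$omega_e,
    omega_s = config$losses$omega_s,
    clip_range = config$discriminator$clip_range,
    lr_floor = config$training$lr_floor,
    gen_widths = config$generator$base_widths,
    disc_widths = config$discriminator$widths,
    max_iters = config$training$max_iters,
    mb_sigma_mode = config$discriminator$mb_sigma_mode,
    mb_sigma = config$discriminator$mb_sigma)
}
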