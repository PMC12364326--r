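# Seeded synthetic thoracic-CT phantoms: HU-valued volumes containing an
# air-dominated parenchyma background, tubular vessels that persist across
# slices, and one approximately spherical nodule (solid or ground-glass)
# concentrated on a single slice. These phantoms exercise every downstream
# stage of the pipeline without external data.

#' Phantom configuration
#'
#' @param volume_shape integer `(n_slices, height, width)`; every dimension
#'   must be at least 16 and `n_slices >= 3` so a three-slice composite can
#'   be formed.
#' @param nodule_radius_range in-plane nodule radius range in pixels;
#'   defaults to 3--15 px, the typical diameter range of pulmonary nodules
#'   in millimetres at ~1 mm spacing.
#' @param nodule_kind `"solid"` (sharp step edge) or `"ggo"` (ground-glass:
#'   intensity decays smoothly into the background).
#' @param n_vessels number of tubular vessels to draw.
#' @param vessel_radius_range vessel tube radius range in pixels.
#' @param background_hu `(mean, sd)` of the lung parenchyma background in
#'   Hounsfield units; default -800 HU, air-dominated tissue.
#' @param nodule_hu mean nodule intensity in HU; defaults to +50 HU for
#'   solid nodules and -450 HU for ground-glass nodules.
#' @param seed integer RNG seed; phantoms are pure functions of the config.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(9L, 160L, 160L),
                           nodule_radius_range = c(3, 15),
                           nodule_kind = c("solid", "ggo"),
                           n_vessels = 4L,
                           vessel_radius_range = c(1, 3),
                           background_hu = c(-800, 40),
                           nodule_hu = NULL,
                           seed = 1L) {
  nodule_kind <- match.arg(nodule_kind)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape[2:3] < 16))
    stop("volume_shape must be (slices, rows, cols) with in-plane extent >= 16")
  if (volume_shape[1] < 3)
    stop("volume_shape needs n_slices >= 3 for a composite")
  if (nodule_radius_range[1] < 1 ||
      nodule_radius_range[2] > min(volume_shape[2:3]) / 2)
    stop("nodule radius range exceeds half the in-plane extent")
  if (n_vessels < 0) stop("n_vessels must be >= 0")
  if (is.null(nodule_hu))
    nodule_hu <- if (nodule_kind == "solid") 50 else -450
  structure(list(volume_shape = volume_shape,
                 nodule_radius_range = as.numeric(nodule_radius_range),
                 nodule_kind = nodule_kind,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range = as.numeric(vessel_radius_range),
                 background_hu = as.numeric(background_hu),
                 nodule_hu = as.numeric(nodule_hu),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# low-frequency noise field: coarse white noise bilinearly upscaled
smooth_noise <- function(h, w, sd, grain = 8L) {
  ch <- max(2L, as.integer(ceiling(h / grain)))
  cw <- max(2L, as.integer(ceiling(w / grain)))
  coarse <- array(stats::rnorm(ch * cw, sd = sd), c(ch, cw, 1L, 1L))
  out <- cpp_bilinear_fwd(coarse, as.integer(h), as.integer(w))
  matrix(out, h, w)
}

#' Generate one synthetic phantom
#'
#' Deterministic for a fixed config (including its seed). The volume holds
#' HU values; `mask_volume` marks the nodule (an oblate ellipsoid whose
#' central slice is a disc of the sampled radius, so most of its voxels lie
#' on one slice); `vessel_volume` labels vessel voxels, whose tubes cross
#' the full slice stack.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_sample` list with `volume`, `mask_volume`,
#'   `vessel_volume` (all `(slice, row, col)` arrays), `nodule_center`,
#'   `nodule_radius` and `metadata`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_local_seed(config$seed, {
    ns <- config$volume_shape[1]
    h <- config$volume_shape[2]
    w <- config$volume_shape[3]
    bg_mean <- config$background_hu[1]
    bg_sd <- config$background_hu[2]
    vol <- array(0, c(ns, h, w))
    for (s in seq_len(ns)) {
      vol[s, , ] <- bg_mean + smooth_noise(h, w, bg_sd) +
        matrix(stats::rnorm(h * w, sd = bg_sd / 2), h, w)
    }
    vessel_vol <- array(0L, c(ns, h, w))
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    # vessels: tubes crossing every slice, axis biased along the slice axis,
    # with a mild sinusoidal in-plane drift
    if (config$n_vessels > 0) {
      for (v in seq_len(config$n_vessels)) {
        r0 <- stats::runif(1, 8, h - 8)
        c0 <- stats::runif(1, 8, w - 8)
        drift_r <- stats::runif(1, -1.5, 1.5)
        drift_c <- stats::runif(1, -1.5, 1.5)
        amp <- stats::runif(1, 0, 2)
        phase <- stats::runif(1, 0, 2 * pi)
        vr <- stats::runif(1, config$vessel_radius_range[1],
                           config$vessel_radius_range[2])
        vhu <- stats::rnorm(1, 30, 10)
        for (s in seq_len(ns)) {
          cr <- min(max(r0 + drift_r * (s - 1) + amp * sin(0.6 * s + phase), 2), h - 1)
          cc <- min(max(c0 + drift_c * (s - 1) + amp * cos(0.6 * s + phase), 2), w - 1)
          inside <- (rows - cr)^2 + (cols - cc)^2 <= vr^2
          if (!any(inside)) {
            # radius below the pixel grid: mark the nearest pixel so the
            # tube still persists through the slice
            inside <- rows == round(cr) & cols == round(cc)
          }
          vslice <- vol[s, , ]
          vslice[inside] <- vhu + stats::rnorm(sum(inside), sd = 10)
          vol[s, , ] <- vslice
          vl <- vessel_vol[s, , ]
          vl[inside] <- 1L
          vessel_vol[s, , ] <- vl
        }
      }
    }
    # nodule: oblate ellipsoid, in-plane radius r, short axis along slices
    r <- stats::runif(1, config$nodule_radius_range[1],
                      config$nodule_radius_range[2])
    slice_choices <- 2:(ns - 1)
    cs <- slice_choices[sample.int(length(slice_choices), 1)]
    margin <- ceiling(r) + 2
    crow <- stats::runif(1, margin, h - margin)
    ccol <- stats::runif(1, margin, w - margin)
    cz <- 1.1  # slice semi-axis: neighbours carry only a thin cap
    mask_vol <- array(0L, c(ns, h, w))
    for (s in seq_len(ns)) {
      dz <- (s - cs) / cz
      if (abs(dz) >= 1) next
      rs <- r * sqrt(1 - dz^2)
      inside <- (rows - crow)^2 + (cols - ccol)^2 <= rs^2
      ml <- mask_vol[s, , ]
      ml[inside] <- 1L
      mask_vol[s, , ] <- ml
    }
    if (sum(mask_vol) == 0) {  # tiny radius: guarantee a nonempty mask
      mask_vol[cs, round(crow), round(ccol)] <- 1L
    }
    # nodule intensity: solid = step edge; ggo = smooth Gaussian falloff
    if (config$nodule_kind == "solid") {
      for (s in seq_len(ns)) {
        sel <- mask_vol[s, , ] == 1L
        if (!any(sel)) next
        vslice <- vol[s, , ]
        vslice[sel] <- config$nodule_hu + stats::rnorm(sum(sel), sd = 15)
        vol[s, , ] <- vslice
      }
    } else {
      amp <- config$nodule_hu - bg_mean
      for (s in seq_len(ns)) {
        dz <- (s - cs) / cz
        if (abs(dz) >= 1.5) next
        d2 <- ((rows - crow)^2 + (cols - ccol)^2) / r^2 + dz^2
        vol[s, , ] <- vol[s, , ] + amp * exp(-2 * d2)
      }
    }
    structure(list(volume = vol,
                   mask_volume = mask_vol,
                   vessel_volume = vessel_vol,
                   nodule_center = c(slice = cs, row = crow, col = ccol),
                   nodule_radius = r,
                   metadata = list(seed = config$seed, config = config)),
              class = "phantom_sample")
  })
}

#' Generate a dataset of independent phantoms
#'
#' Per-sample seeds are `seed + i`, so sample i is identical across calls
#' with the same master seed.
#'
#' @param n_samples number of phantoms (>= 1).
#' @param config a [phantom_config()]; its `seed` field is overridden per
#'   sample.
#' @param seed master seed.
#' @return list of `phantom_sample` objects.
#' @export
generate_dataset <- function(n_samples, config = phantom_config(), seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  lapply(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    generate_phantom(cfg)
  })
}
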