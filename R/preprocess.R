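# Preprocessing: CT volume + mask -> model-ready pseudo-colour composites
# and the two auxiliary label pyramids (mask pyramid for the critic, edge
# pyramid for the generator). Coordinates are 1-based (row, col) throughout,
# following R convention.

#' HU windowing specification
#'
#' The default window is read as level -600 HU / width 1200 HU, i.e. the
#' interval `[-1200, 0]` HU (the standard lung window). A literal clip range
#' can be expressed through `level`/`width` directly.
#'
#' @param level window centre in HU.
#' @param width window width in HU (> 0).
#' @return a `window_spec` list.
#' @export
window_spec <- function(level = -600, width = 1200) {
  if (width <= 0) stop("window width must be positive")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Map HU values to `[0, 1]` through a display window
#'
#' Linear map of `[level - width/2, level + width/2]` onto `[0, 1]`, clipped
#' outside; monotone non-decreasing in HU.
#'
#' @param volume numeric array of HU values (any shape).
#' @param spec a [window_spec()].
#' @return array of the same shape with values in `[0, 1]`.
#' @export
window_hu <- function(volume, spec = window_spec()) {
  lo <- spec$level - spec$width / 2
  out <- (volume - lo) / spec$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Centroid of a binary mask from raw image moments
#'
#' Returns `(m10/m00, m01/m00)`, the intensity-weighted centroid used to
#' centre the region of interest.
#'
#' @param mask 2-D binary matrix.
#' @return numeric `(row, col)`, 1-based.
#' @export
mask_moment_center <- function(mask) {
  m00 <- sum(mask)
  if (m00 == 0) stop("mask_moment_center: mask is empty")
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  c(row = sum(rows * mask) / m00, col = sum(cols * mask) / m00)
}

#' Extract a square region of interest around a point
#'
#' Crops a `size x size` window whose geometric centre is the rounded
#' centroid; parts falling outside the source are zero-padded.
#'
#' @param slice_grid 2-D numeric matrix.
#' @param center numeric `(row, col)` centre (1-based, may be fractional).
#' @param size even crop size, >= 16.
#' @return `size x size` matrix.
#' @export
extract_roi <- function(slice_grid, center, size = 128L) {
  size <- as.integer(size)
  if (size %% 2 != 0 || size < 16) stop("ROI size must be even and >= 16")
  r0 <- as.integer(round(center[1] - (size - 1) / 2))
  c0 <- as.integer(round(center[2] - (size - 1) / 2))
  out <- matrix(0, size, size)
  rr <- max(r0, 1L):min(r0 + size - 1L, nrow(slice_grid))
  cc <- max(c0, 1L):min(c0 + size - 1L, ncol(slice_grid))
  if (length(rr) > 0 && length(cc) > 0 && rr[1] <= rr[length(rr)] &&
      cc[1] <= cc[length(cc)]) {
    out[rr - r0 + 1L, cc - c0 + 1L] <- slice_grid[rr, cc, drop = FALSE]
  }
  out
}

#' Encode three consecutive slices as a pseudo-colour composite
#'
#' The previous, current and next axial slices fill the R, G and B channels
#' of a three-channel image, giving a 2-D network inter-slice context. At
#' the volume ends the boundary slice is replicated for the missing
#' neighbour.
#'
#' @param volume01 windowed volume, `(slice, row, col)` array in `[0, 1]`.
#' @param slice_index 1-based index of the annotated (current) slice.
#' @param center ROI centre `(row, col)`.
#' @param size ROI size.
#' @return `size x size x 3` array (R = previous, G = current, B = next).
#' @export
encode_pseudocolor <- function(volume01, slice_index, center, size = 128L) {
  ns <- dim(volume01)[1]
  if (slice_index < 1 || slice_index > ns) stop("slice_index out of range")
  prev <- max(slice_index - 1L, 1L)
  nxt <- min(slice_index + 1L, ns)
  out <- array(0, c(size, size, 3L))
  out[, , 1] <- extract_roi(volume01[prev, , ], center, size)
  out[, , 2] <- extract_roi(volume01[slice_index, , ], center, size)
  out[, , 3] <- extract_roi(volume01[nxt, , ], center, size)
  out
}

#' Extract the boundary of a binary mask
#'
#' Default method returns the exact 1-pixel morphological boundary: mask
#' pixels with at least one 4-neighbour outside the mask (pixels beyond the
#' image border count as outside). On binary step edges this coincides with
#' the Canny result while being fully deterministic; a conventional Canny
#' detector (Gaussian sigma = 1, hysteresis 0.1/0.2 on the 0-1 mask) is
#' available behind `method = "canny"`.
#'
#' @param mask 2-D binary matrix.
#' @param method `"boundary"` (default) or `"canny"`.
#' @return binary matrix of the same shape; empty mask gives an empty map.
#' @export
extract_edge_map <- function(mask, method = c("boundary", "canny")) {
  method <- match.arg(method)
  if (method == "canny") return(canny_edges(mask))
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                 pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)])
  edge <- (inner == 1) & (nb_min == 0)
  mode(edge) <- "integer"
  edge
}

# small separable Gaussian blur
gaussian_blur <- function(img, sigma = 1) {
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (i in seq_along(k)) {
      off <- i - rad - 1L
      if (along_rows) {
        src <- pmin(pmax(seq_len(h) + off, 1L), h)
        out <- out + k[i] * m[src, , drop = FALSE]
      } else {
        src <- pmin(pmax(seq_len(w) + off, 1L), w)
        out <- out + k[i] * m[, src, drop = FALSE]
      }
    }
    out
  }
  conv1(conv1(img, TRUE), FALSE)
}

# classic Canny on a [0,1] image: blur, Sobel, non-max suppression,
# hysteresis thresholding
canny_edges <- function(img, sigma = 1, low = 0.1, high = 0.2) {
  img <- gaussian_blur(img, sigma)
  h <- nrow(img); w <- ncol(img)
  padi <- matrix(0, h + 2, w + 2)
  padi[2:(h + 1), 2:(w + 1)] <- img
  padi[1, ] <- padi[2, ]; padi[h + 2, ] <- padi[h + 1, ]
  padi[, 1] <- padi[, 2]; padi[, w + 2] <- padi[, w + 1]
  sub <- function(dr, dc) padi[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gr <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  gc <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) == 0) return(matrix(0L, h, w))
  ang <- atan2(gr, gc) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E, 1:NE, 2:N, 3:NW
  padm <- matrix(0, h + 2, w + 2)
  padm[2:(h + 1), 2:(w + 1)] <- mag
  subm <- function(dr, dc) padm[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  n1 <- subm(0, 1) * (sector == 0) + subm(1, 1) * (sector == 1) +
    subm(1, 0) * (sector == 2) + subm(1, -1) * (sector == 3)
  n2 <- subm(0, -1) * (sector == 0) + subm(-1, -1) * (sector == 1) +
    subm(-1, 0) * (sector == 2) + subm(-1, 1) * (sector == 3)
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high * max(mag)
  weak <- keep & mag >= low * max(mag)
  # hysteresis: grow strong edges into connected weak pixels
  cur <- strong
  repeat {
    padc <- matrix(FALSE, h + 2, w + 2)
    padc[2:(h + 1), 2:(w + 1)] <- cur
    nb <- padc[1:h, 1:w] | padc[1:h, 2:(w + 1)] | padc[1:h, 3:(w + 2)] |
      padc[2:(h + 1), 1:w] | padc[2:(h + 1), 3:(w + 2)] |
      padc[3:(h + 2), 1:w] | padc[3:(h + 2), 2:(w + 1)] | padc[3:(h + 2), 3:(w + 2)]
    nxt <- cur | (weak & nb)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- cur
  mode(out) <- "integer"
  out
}

#' Build a label pyramid by max-pool downsampling
#'
#' Level k is the source map max-pooled by factor `2^(k-1)`; max pooling
#' (rather than averaging) guarantees that one-pixel edges and very small
#' nodules survive to the coarsest level.
#'
#' @param map2d binary matrix whose side lengths are divisible by
#'   `2^(levels-1)`.
#' @param levels number of pyramid levels (default 4).
#' @param kind `"mask"` (critic auxiliary labels) or `"edge"` (generator
#'   auxiliary labels).
#' @return a `label_pyramid` list with fields `levels` (list of binary
#'   matrices) and `kind`.
#' @export
build_pyramid <- function(map2d, levels = 4L, kind = c("mask", "edge")) {
  kind <- match.arg(kind)
  fac <- 2^(levels - 1)
  if (nrow(map2d) %% fac != 0 || ncol(map2d) %% fac != 0)
    stop("map size must be divisible by 2^(levels-1)")
  out <- vector("list", levels)
  out[[1]] <- map2d
  cur <- map2d
  for (k in 2:levels) {
    h <- nrow(cur); w <- ncol(cur)
    a <- array(as.numeric(cur), c(h, w, 1L, 1L))
    p <- cpp_maxpool2_fwd(a)$value
    cur <- matrix(p, h / 2, w / 2)
    out[[k]] <- cur
  }
  out <- lapply(out, function(m) { mode(m) <- "integer"; m })
  structure(list(levels = out, kind = kind), class = "label_pyramid")
}

#' Preprocess one phantom (or volume + mask) into a training sample
#'
#' Runs the full pipeline: HU windowing, centroid of the annotated slice's
#' mask, ROI extraction, pseudo-colour encoding, and construction of the
#' mask and edge label pyramids.
#'
#' @param volume `(slice, row, col)` HU array.
#' @param mask_volume matching binary array.
#' @param slice_index annotated slice; defaults to the slice with the
#'   largest mask area.
#' @param size ROI size (divisible by 8).
#' @param spec a [window_spec()].
#' @param edge_method boundary extraction method, see [extract_edge_map()].
#' @return a `composite_sample` list with `image` (`size x size x 3`),
#'   `mask`, `y_d` (mask pyramid), `y_g` (edge pyramid), `center`,
#'   `slice_index`.
#' @export
preprocess_sample <- function(volume, mask_volume, slice_index = NULL,
                              size = 128L, spec = window_spec(),
                              edge_method = "boundary") {
  if (!all(dim(volume) == dim(mask_volume)))
    stop("volume and mask_volume must have identical shape")
  if (is.null(slice_index)) {
    areas <- apply(mask_volume, 1, sum)
    slice_index <- which.max(areas)
  }
  mask_slice <- mask_volume[slice_index, , ]
  center <- mask_moment_center(mask_slice)
  vol01 <- window_hu(volume, spec)
  image <- encode_pseudocolor(vol01, slice_index, center, size)
  mask <- extract_roi(mask_slice, center, size)
  mode(mask) <- "integer"
  y_d <- build_pyramid(mask, kind = "mask")
  y_g <- build_pyramid(extract_edge_map(mask, edge_method), kind = "edge")
  structure(list(image = image, mask = mask, y_d = y_d, y_g = y_g,
                 center = center, slice_index = slice_index, size = size),
            class = "composite_sample")
}

#' Preprocess a list of phantoms
#'
#' @param phantoms list of `phantom_sample` objects.
#' @param size ROI size.
#' @param ... passed to [preprocess_sample()].
#' @return list of `composite_sample` objects.
#' @export
preprocess_dataset <- function(phantoms, size = 128L, ...) {
  lapply(phantoms, function(ph)
    preprocess_sample(ph$volume, ph$mask_volume, size = size, ...))
}
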