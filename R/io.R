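# Volume and composite I/O. Volumes travel as MetaImage (.mhd header +
# .raw payload), the format LUNA16 ships; orientation is normalised to
# (slice, row, col). Preprocessed composites are stored as R-native RDS
# archives holding the image, mask, both label pyramids and provenance.

met_types <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L, MET_UCHAR = 1L)

#' Write a volume as MetaImage
#'
#' @param volume `(slice, row, col)` numeric array.
#' @param path output `.mhd` path; the `.raw` companion is written next to
#'   it.
#' @param spacing voxel spacing `(slice, row, col)` in mm.
#' @param element_type one of `MET_DOUBLE` (lossless for R numerics,
#'   default), `MET_FLOAT`, `MET_SHORT`, `MET_UCHAR`.
#' @return the `.mhd` path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1),
                         element_type = "MET_DOUBLE") {
  if (!element_type %in% names(met_types)) stop("unsupported element type")
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(volume)  # (slice, row, col)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),          # x y z
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            spacing[3], spacing[2], spacing[1]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(header, path)
  vals <- as.vector(aperm(volume, c(3, 2, 1)))  # x fastest
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (element_type %in% c("MET_SHORT", "MET_UCHAR")) {
    writeBin(as.integer(round(vals)), con, size = met_types[[element_type]],
             endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = met_types[[element_type]],
             endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage volume
#'
#' @param path `.mhd` header path.
#' @return list with `volume` (`(slice, row, col)` array) and `spacing`
#'   (`(slice, row, col)` numeric).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  if (grepl("\\.(nii|nii\\.gz)$", path))
    stop("read_volume: NIfTI input is not supported in this build; ",
         "convert to MetaImage (.mhd/.raw)")
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  get_field <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) return(default)
    vals[i]
  }
  dims <- as.integer(strsplit(get_field("DimSize"), "\\s+")[[1]])  # x y z
  etype <- get_field("ElementType", "MET_FLOAT")
  if (!etype %in% names(met_types)) stop("unsupported ElementType: ", etype)
  spacing_xyz <- as.numeric(strsplit(
    get_field("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  msb <- identical(toupper(get_field("BinaryDataByteOrderMSB", "False")), "TRUE")
  raw_name <- get_field("ElementDataFile")
  raw_path <- file.path(dirname(path), raw_name)
  if (!file.exists(raw_path))
    stop("read_volume: missing companion data file: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  sz <- met_types[[etype]]
  what <- if (etype %in% c("MET_SHORT", "MET_UCHAR")) "integer" else "numeric"
  vals_raw <- readBin(con, what, n = n, size = sz,
                      signed = !(etype == "MET_UCHAR"),
                      endian = if (msb) "big" else "little")
  if (length(vals_raw) < n)
    stop("read_volume: truncated data file: ", raw_path)
  vol <- aperm(array(as.numeric(vals_raw), dim = dims), c(3, 2, 1))
  list(volume = vol, spacing = rev(spacing_xyz))
}

#' Export a phantom as MetaImage volume + mask (+ optional previews)
#'
#' @param sample a `phantom_sample`.
#' @param prefix output path prefix; writes `<prefix>.mhd/.raw`,
#'   `<prefix>_mask.mhd/.raw` and optionally `<prefix>_s<k>.png`.
#' @param preview write 8-bit windowed per-slice PNG previews.
#' @param spec window used for previews.
#' @return the volume `.mhd` path, invisibly.
#' @export
export_phantom <- function(sample, prefix, preview = FALSE,
                           spec = window_spec()) {
  write_volume(sample$volume, paste0(prefix, ".mhd"))
  write_volume(sample$mask_volume, paste0(prefix, "_mask.mhd"),
               element_type = "MET_UCHAR")
  if (preview) {
    v01 <- window_hu(sample$volume, spec)
    for (s in seq_len(dim(v01)[1]))
      png::writePNG(v01[s, , ], sprintf("%s_s%02d.png", prefix, s))
  }
  invisible(paste0(prefix, ".mhd"))
}

#' Export a preprocessed composite archive
#'
#' The archive contains the image, mask, both label pyramids and a
#' provenance record (configuration hash, seed, source path), and
#' round-trips to machine precision via [import_composite()].
#'
#' @param sample a `composite_sample`.
#' @param path output `.rds` path.
#' @param config configuration list hashed into the provenance record.
#' @param seed seed recorded in the provenance record.
#' @param source source identifier (e.g. volume path).
#' @param preview optional path for an 8-bit RGB PNG preview of the
#'   composite (channels previous/current/next).
#' @return `path`, invisibly.
#' @export
export_composite <- function(sample, path, config = NULL, seed = NULL,
                             source = NULL, preview = NULL) {
  required <- c("image", "mask", "y_d", "y_g")
  missing <- required[!required %in% names(sample)]
  if (length(missing))
    stop("export_composite: incomplete sample, missing: ",
         paste(missing, collapse = ", "))
  provenance <- list(config_hash = digest::digest(config),
                     seed = seed, source = source,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  saveRDS(list(image = sample$image, mask = sample$mask,
               y_d = sample$y_d, y_g = sample$y_g,
               center = sample$center, slice_index = sample$slice_index,
               provenance = provenance), path)
  if (!is.null(preview)) png::writePNG(sample$image, preview)
  invisible(path)
}

#' Import a composite archive
#'
#' @param path `.rds` path written by [export_composite()].
#' @return a `composite_sample` with a `provenance` field.
#' @export
import_composite <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "composite_sample")
}
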