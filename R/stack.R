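#' Multi-channel confocal z-stack container
#'
#' A calibrated voxel array in `(z, y, x, channel)` order, the raw input of
#' the pipeline. Voxel values are stored as integers on the acquisition scale
#' (0-255 for the 8-bit stacks the pipeline targets). Coordinates follow the
#' image convention: 0-based voxel indices, y increasing downward, and the
#' physical position of voxel index `i` equal to `i * spacing`.
#'
#' @param data 4D numeric array with dimensions `(n_z, n_y, n_x, n_channels)`.
#' @param pixel_size_um Physical xy pixel size in micrometres.
#' @param z_step_um Optical section spacing in micrometres (2 for the
#'   acquisition settings the defaults mirror).
#' @param channels Character vector naming the channels, e.g.
#'   `c("dapi", "nanog", "py705", "tfcp2l1")`.
#' @param bit_depth Integer bit depth of the acquisition (default 8).
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_um, z_step_um, channels,
                        bit_depth = 8L) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  stopifnot(pixel_size_um > 0, z_step_um > 0)
  if (length(channels) != dim(data)[4]) {
    stop("length(channels) must equal dim(data)[4]", call. = FALSE)
  }
  structure(
    list(
      data = data,
      pixel_size_um = as.numeric(pixel_size_um),
      z_step_um = as.numeric(z_step_um),
      channels = as.character(channels),
      bit_depth = as.integer(bit_depth)
    ),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d slices x %dx%d px x %d channels (%s)\n",
    d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")
  ))
  cat(sprintf("  pixel %.3g um, z-step %.3g um, %d-bit\n",
              x$pixel_size_um, x$z_step_um, x$bit_depth))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Extract one 2D slice of one channel
#'
#' @param stack An `ImageStack`.
#' @param z Slice index (1-based array index).
#' @param channel Channel name or index.
#' @return Numeric matrix `(y, x)`.
#' @export
get_slice <- function(stack, z, channel) {
  ci <- resolve_channel(stack, channel)
  m <- stack$data[z, , , ci]
  dim(m) <- dim(stack$data)[2:3]
  m
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) {
      stop("unknown channel: ", channel, " (have: ",
           paste(stack$channels, collapse = ", "), ")", call. = FALSE)
    }
    ci
  } else {
    stopifnot(channel >= 1, channel <= length(stack$channels))
    as.integer(channel)
  }
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered z-major, channel-minor. Baseline TIFF carries no z
#' spacing or channel axis, so calibration and axis layout are written to
#' `<path>.json`; [read_stack()] consumes the pair.
#'
#' @param stack An `ImageStack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  maxval <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ci in seq_len(d[4])) {
      m <- stack$data[z, , , ci]
      dim(m) <- d[2:3]
      pages[[k]] <- m / maxval
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  meta <- list(
    kind = "ImageStack",
    n_z = d[1], n_y = d[2], n_x = d[3],
    channels = as.list(stack$channels),
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    bit_depth = stack$bit_depth,
    page_order = "z_major_channel_minor"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel z-stack from TIFF
#'
#' Calibration and the channel axis are resolved from the JSON sidecar
#' written by [write_stack()]; without a sidecar they must be supplied
#' explicitly, and a missing field is an error naming that field. Non-8-bit
#' data are rejected unless `allow_any_depth = TRUE`, mirroring the
#' acquisition contract of the pipeline.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um Calibration overrides (required when no
#'   sidecar exists).
#' @param channels Channel names override.
#' @param n_channels Number of channels (needed without sidecar or `channels`).
#' @param allow_any_depth Accept bit depths other than 8.
#' @return An `ImageStack`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       channels = NULL, n_channels = NULL,
                       allow_any_depth = FALSE) {
  if (!file.exists(path)) stop("cannot read stack: ", path, call. = FALSE)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    NULL
  }
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  z_step_um <- z_step_um %||% meta$z_step_um
  channels <- channels %||% meta$channels
  if (is.null(pixel_size_um)) {
    stop("missing metadata field: pixel_size_um (no sidecar and no override)",
         call. = FALSE)
  }
  if (is.null(z_step_um)) {
    stop("missing metadata field: z_step_um (no sidecar and no override)",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (bits != 8L && !allow_any_depth) {
    stop("stack is ", bits, "-bit; expected 8-bit ",
         "(use allow_any_depth = TRUE to accept)", call. = FALSE)
  }
  if (is.null(channels)) {
    if (is.null(n_channels)) {
      stop("missing metadata field: channels (supply channels= or n_channels=)",
           call. = FALSE)
    }
    channels <- paste0("ch", seq_len(n_channels))
  }
  nc <- length(channels)
  if (length(pages) %% nc != 0L) {
    stop("page count ", length(pages), " not divisible by ", nc, " channels",
         call. = FALSE)
  }
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  maxval <- 2^bits - 1
  arr <- array(0, dim = c(nz, ny, nx, nc))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ci in seq_len(nc)) {
      arr[z, , , ci] <- round(pages[[k]] * maxval)
      k <- k + 1L
    }
  }
  image_stack(arr, pixel_size_um, z_step_um, channels, bit_depth = bits)
}

#' Write a 3D region-of-interest mask as a single-channel TIFF
#'
#' @param roi Logical 3D array `(z, y, x)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  stopifnot(is.logical(roi), length(dim(roi)) == 3L)
  pages <- lapply(seq_len(dim(roi)[1]), function(z) {
    m <- roi[z, , ] * 1
    dim(m) <- dim(roi)[2:3]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a region-of-interest mask written by [write_roi()]
#' @param path TIFF path.
#' @return Logical 3D array `(z, y, x)`.
#' @export
read_roi <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  arr <- array(FALSE, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]] > 0.5
  arr
}

#' 3D nucleus label volume
#'
#' Integer voxel array in `(z, y, x)` order where 0 is background and label
#' `k > 0` marks the voxels of nucleus `k`; this is the mask used to measure
#' fluorescence per nucleus.
#'
#' @param data Integer 3D array.
#' @param pixel_size_um,z_step_um Calibration in micrometres.
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(data, pixel_size_um, z_step_um) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  structure(
    list(data = data, pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um)),
    class = "LabelVolume"
  )
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("LabelVolume: %d x %d x %d voxels, %d nuclei\n",
              d[1], d[2], d[3], max(x$data)))
  invisible(x)
}

#' Write a label volume as 16-bit TIFF (+ JSON sidecar)
#' @param labels A `LabelVolume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  d <- dim(labels$data)
  if (max(labels$data) > 65535) stop("more than 65535 labels", call. = FALSE)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- labels$data[z, , ]
    dim(m) <- d[2:3]
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(kind = "LabelVolume", pixel_size_um = labels$pixel_size_um,
               z_step_um = labels$z_step_um)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um Calibration overrides when no sidecar.
#' @return A `LabelVolume`.
#' @export
read_labels <- function(path, pixel_size_um = NULL, z_step_um = NULL) {
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    NULL
  }
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  z_step_um <- z_step_um %||% meta$z_step_um
  if (is.null(pixel_size_um) || is.null(z_step_um)) {
    stop("missing metadata field: pixel_size_um/z_step_um", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  arr <- array(0L, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(round(pages[[z]] * 65535))
  label_volume(arr, pixel_size_um, z_step_um)
}
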