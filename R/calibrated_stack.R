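#' Calibrated multi-channel image stack
#'
#' Container for a multi-channel 3D fluorescence volume with its spatial
#' calibration. Voxel data are stored as a 4D numeric array indexed
#' `[y, x, z, channel]` holding integer gray levels in `[0, bit_max]`.
#'
#' @param data 4D numeric array `[y, x, z, channel]`.
#' @param pixel_size_um lateral pixel size in micrometres per pixel (> 0).
#' @param z_step_um axial step between slices, micrometres.
#' @param bit_max maximum representable gray level (4096 for 12-bit data).
#' @param channels character vector of channel names, one per channel slab.
#'
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(data, pixel_size_um, z_step_um = 1.13,
                             bit_max = 4096,
                             channels = c("tmem119", "iba1")) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (dim(data)[4] != length(channels)) {
    stop("number of channel names must match the 4th array dimension")
  }
  if (min(data) < 0 || max(data) > bit_max) {
    stop("voxel values must lie in [0, bit_max]")
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         bit_max = bit_max, channels = channels),
    class = "calibrated_stack"
  )
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_stack> %d x %d px, %d z-slices, %d channel(s) [%s]\n",
    d[2], d[1], d[3], d[4], paste(x$channels, collapse = ", ")
  ))
  cat(sprintf("  pixel %.3g um/px, z-step %.3g um, bit_max %d\n",
              x$pixel_size_um, x$z_step_um, as.integer(x$bit_max)))
  invisible(x)
}

#' Maximum-intensity projection
#'
#' Collapses each channel of a calibrated stack to a 2D image by taking, for
#' every pixel, the maximum gray level across z. Channels are kept separate.
#'
#' @param stack a [calibrated_stack()].
#' @return Named list of 2D numeric matrices (one per channel), each carrying
#'   a `pixel_size_um` attribute.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$data)
  if (d[3] < 1) stop("stack must contain at least one z-slice")
  out <- lapply(seq_len(d[4]), function(ch) {
    m <- stack$data[, , 1, ch]
    for (z in seq_len(d[3])[-1]) m <- pmax(m, stack$data[, , z, ch])
    attr(m, "pixel_size_um") <- stack$pixel_size_um
    m
  })
  names(out) <- stack$channels
  out
}

#' Read a calibrated stack from a multi-page TIFF plus JSON sidecar
#'
#' The TIFF is channel-major (all z-slices of channel 1, then channel 2, ...);
#' the sidecar records `pixel_size_um`, `z_step_um`, `bit_max`, `n_channels`,
#' `n_z` and `channels`.
#'
#' @param path TIFF file path.
#' @param sidecar path to the JSON sidecar (default: `path` with `.json`
#'   extension).
#' @return A [calibrated_stack()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  if (!file.exists(sidecar)) {
    stop("calibration sidecar not found: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("pixel_size_um", "z_step_um", "bit_max", "n_channels", "n_z")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) {
    stop("sidecar is missing calibration fields: ", paste(miss, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_channels * meta$n_z) {
    stop(sprintf(
      "TIFF has %d pages but sidecar declares %d channels x %d slices",
      length(pages), meta$n_channels, meta$n_z
    ))
  }
  nr <- nrow(pages[[1]])
  nc <- ncol(pages[[1]])
  arr <- array(0, dim = c(nr, nc, meta$n_z, meta$n_channels))
  p <- 1L
  for (ch in seq_len(meta$n_channels)) {
    for (z in seq_len(meta$n_z)) {
      arr[, , z, ch] <- round(pages[[p]] * 65535)
      p <- p + 1L
    }
  }
  channels <- meta$channels %||% paste0("ch", seq_len(meta$n_channels))
  calibrated_stack(arr, pixel_size_um = meta$pixel_size_um,
                   z_step_um = meta$z_step_um, bit_max = meta$bit_max,
                   channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a list of 2D matrices of integer gray levels as 16-bit TIFF pages.
write_tiff_pages <- function(pages, path) {
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                  bits.per.sample = 16L, compression = "none")
}
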