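#' Pipeline configuration
#'
#' Parameters of the Iba1 preprocessing/segmentation chain and of the marker
#' channel preprocessing. The segmentation threshold is a constant gray level
#' applied unchanged to every image of a study (use [suggest_threshold()] to
#' derive one from a control image); all other values default to the standard
#' chain: rolling-ball radius 50 px for Iba1 and 20 px for the marker, one
#' pass of a 3 x 3 mean filter, unsharp mask with sigma 2 px and weight 0.6.
#'
#' @param threshold_gray constant segmentation cut-off (gray levels), required.
#' @param iba1_rolling_radius_px rolling-ball radius for the Iba1 channel.
#' @param tmem_rolling_radius_px rolling-ball radius for the marker channel.
#' @param smooth_kernel_px side of the mean filter (odd).
#' @param unsharp_radius_px Gaussian sigma of the unsharp mask.
#' @param unsharp_weight unsharp mask weight in (0, 1).
#' @param connectivity pixel connectivity for labeling, 4 or 8.
#' @param min_area_um2 components smaller than this are discarded as debris.
#' @param exclude_border drop components touching the image border.
#' @param soma_opening_radius_um disc radius used to cut ramifications when
#'   deriving the soma outline.
#' @param perimeter_method `"traced"` (corrected chain code) or `"crofton"`.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_gray,
                            iba1_rolling_radius_px = 50,
                            tmem_rolling_radius_px = 20,
                            smooth_kernel_px = 3,
                            unsharp_radius_px = 2,
                            unsharp_weight = 0.6,
                            connectivity = 8,
                            min_area_um2 = 20,
                            exclude_border = TRUE,
                            soma_opening_radius_um = 2,
                            perimeter_method = c("traced", "crofton")) {
  if (missing(threshold_gray)) stop("threshold_gray must be set")
  if (threshold_gray <= 0) stop("threshold_gray must be > 0")
  if (iba1_rolling_radius_px < 1 || tmem_rolling_radius_px < 1) {
    stop("rolling-ball radii must be >= 1")
  }
  if (unsharp_weight <= 0 || unsharp_weight >= 1) {
    stop("unsharp_weight must be in (0, 1)")
  }
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(
    list(threshold_gray = threshold_gray,
         iba1_rolling_radius_px = iba1_rolling_radius_px,
         tmem_rolling_radius_px = tmem_rolling_radius_px,
         smooth_kernel_px = smooth_kernel_px,
         unsharp_radius_px = unsharp_radius_px,
         unsharp_weight = unsharp_weight,
         connectivity = connectivity,
         min_area_um2 = min_area_um2,
         exclude_border = exclude_border,
         soma_opening_radius_um = soma_opening_radius_um,
         perimeter_method = match.arg(perimeter_method)),
    class = "pipeline_config"
  )
}

ball_structuring_element <- function(radius_px) {
  r <- floor(radius_px)
  d <- seq(-r, r)
  g <- expand.grid(dy = d, dx = d)
  keep <- g$dy^2 + g$dx^2 <= radius_px^2
  g <- g[keep, , drop = FALSE]
  list(dy = as.integer(g$dy), dx = as.integer(g$dx),
       h = sqrt(radius_px^2 - g$dy^2 - g$dx^2))
}

ball_opening <- function(image, radius_px) {
  se <- ball_structuring_element(radius_px)
  er <- cpp_gray_erode(image, se$dy, se$dx, se$h)
  cpp_gray_dilate(er, se$dy, se$dx, se$h)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a ball
#' structuring element of the given radius (the rolling-ball model) and
#' subtracts it. For radii above 16 px, the image is first reduced by a block
#' minimum (factor 2/4/8 by radius), the ball is rolled on the reduced image
#' and the background enlarged back by bilinear interpolation and clamped
#' under the image, following the standard large-radius approximation. Output
#' is non-negative everywhere; a constant image maps to zero exactly.
#'
#' @param image 2D numeric matrix.
#' @param radius_px ball radius in pixels (>= 1).
#' @param shrink integer reduction factor; `NULL` selects it from the radius
#'   (1 up to radius 16, then 2, 4, 8). Use 1 to force the exact opening.
#' @return Background-subtracted matrix, same size as `image`.
#' @export
subtract_background_rolling <- function(image, radius_px, shrink = NULL) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (2 * floor(radius_px) + 1 > min(dim(image))) {
    stop("rolling-ball radius larger than the image")
  }
  if (is.null(shrink)) {
    shrink <- if (radius_px <= 16) 1L
    else if (radius_px <= 32) 2L
    else if (radius_px <= 100) 4L
    else 8L
  }
  if (shrink > 1) {
    small <- block_min(image, shrink)
    bg_small <- ball_opening(small, radius_px / shrink)
    bg <- enlarge_bilinear(bg_small, nrow(image), ncol(image), shrink)
    bg <- pmin(bg, image)
  } else {
    bg <- ball_opening(image, radius_px)
  }
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Mean (box) smoothing filter
#'
#' One pass of a `kernel_px` x `kernel_px` uniform mean filter with
#' reflective border handling.
#'
#' @param image 2D numeric matrix.
#' @param kernel_px odd kernel side, default 3.
#' @return Smoothed matrix.
#' @export
smooth_mean <- function(image, kernel_px = 3) {
  if (kernel_px < 1 || kernel_px %% 2 != 1) {
    stop("kernel_px must be a positive odd integer")
  }
  if (kernel_px == 1) return(image)
  k <- kernel_px %/% 2
  p <- pad_reflect(image, k)
  kk <- min(k, nrow(image) - 1L, ncol(image) - 1L)
  f <- EBImage::filter2(p, matrix(1 / kernel_px^2, kernel_px, kernel_px))
  crop_center(f, kk, nrow(image), ncol(image))
}

#' Unsharp mask filter
#'
#' Sharpens by subtracting a weighted Gaussian blur:
#' `out = (I - w * G_sigma(I)) / (1 - w)`, with negative values clipped to
#' zero. A constant image is returned unchanged (up to floating-point
#' convolution error).
#'
#' @param image 2D numeric matrix.
#' @param radius_px Gaussian sigma in pixels.
#' @param weight mask weight in (0, 1).
#' @return Sharpened matrix.
#' @export
unsharp_mask <- function(image, radius_px = 2, weight = 0.6) {
  if (radius_px <= 0) stop("radius_px must be > 0")
  if (weight <= 0 || weight >= 1) stop("weight must be in (0, 1)")
  b <- gaussian_blur_reflect(image, radius_px)
  out <- (image - weight * b) / (1 - weight)
  out[out < 0] <- 0
  out
}

#' Suggest a constant segmentation threshold from a reference image
#'
#' Returns the stated quantile of a preprocessed reference (control) image;
#' used to fix the constant gray-level cut-off that is then applied unchanged
#' to every image in a study.
#'
#' @param reference_image preprocessed 2D matrix (e.g. a control field).
#' @param quantile_p quantile in `[0, 1]`, default 0.99.
#' @return A single gray level.
#' @export
suggest_threshold <- function(reference_image, quantile_p = 0.99) {
  stopifnot(quantile_p >= 0, quantile_p <= 1)
  unname(quantile(as.numeric(reference_image), probs = quantile_p))
}

#' Preprocess the Iba1 channel
#'
#' Applies the segmentation chain: rolling-ball background subtraction,
#' mean smoothing, unsharp masking, in this order.
#'
#' @param image 2D projection of the Iba1 channel.
#' @param config a [pipeline_config()].
#' @return Preprocessed matrix.
#' @export
preprocess_iba1 <- function(image, config) {
  image |>
    subtract_background_rolling(config$iba1_rolling_radius_px) |>
    smooth_mean(config$smooth_kernel_px) |>
    unsharp_mask(config$unsharp_radius_px, config$unsharp_weight)
}

#' Preprocess the marker (Tmem119) channel
#'
#' The marker channel only receives rolling-ball background subtraction with
#' the marker radius before quantification; it never goes through the Iba1
#' smoothing/sharpening chain.
#'
#' @inheritParams preprocess_iba1
#' @return Background-subtracted matrix.
#' @export
preprocess_marker <- function(image, config) {
  subtract_background_rolling(image, config$tmem_rolling_radius_px)
}

#' Segment Iba1-positive cells by a constant threshold
#'
#' Thresholds the preprocessed image at the constant gray-level cut-off,
#' labels connected components under the configured connectivity, removes
#' components smaller than `min_area_um2` and (optionally) components
#' touching the border, and relabels the survivors 1..n in scan order. An
#' empty result is returned as an all-zero mask, not an error.
#'
#' @param image preprocessed 2D matrix.
#' @param config a [pipeline_config()].
#' @param pixel_size_um lateral calibration, um/pixel.
#' @return Integer label matrix of class `label_mask` with attribute
#'   `pixel_size_um`; 0 is background, k the k-th cell.
#' @export
segment_cells <- function(image, config, pixel_size_um) {
  stopifnot(inherits(config, "pipeline_config"), pixel_size_um > 0)
  binary <- image >= config$threshold_gray
  lab <- cpp_label(binary, as.integer(config$connectivity))
  n <- max(lab)
  if (n > 0) {
    keep <- rep(TRUE, n)
    counts <- tabulate(lab, nbins = n)
    keep[counts * pixel_size_um^2 < config$min_area_um2] <- FALSE
    if (config$exclude_border) {
      edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      keep[edge[edge > 0]] <- FALSE
    }
    map <- integer(n)
    map[keep] <- seq_len(sum(keep))
    lab[lab > 0] <- map[lab[lab > 0]]
  }
  structure(lab, pixel_size_um = pixel_size_um, class = "label_mask")
}
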