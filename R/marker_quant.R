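#' Mean gray value within a mask
#'
#' @param image 2D numeric matrix (normally the background-subtracted marker
#'   projection).
#' @param mask logical (or 0/1) matrix of the same size.
#' @return Arithmetic mean of the image over the mask pixels.
#' @export
mean_in_mask <- function(image, mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  if (!all(dim(image) == dim(mask))) stop("image and mask sizes differ")
  mean(image[mask])
}

#' Soma outline of a cell by cutting its ramifications
#'
#' Morphological opening of the cell mask with a disc of the given radius
#' removes structures thinner than the disc (the processes); the largest
#' remaining connected component is the soma. A cell that is a pure disc of
#' radius at least the opening radius is returned unchanged. If the opening
#' erases the cell entirely, an all-`FALSE` mask with attribute
#' `empty = TRUE` is returned.
#'
#' @param cell_mask logical matrix of one connected cell.
#' @param pixel_size_um lateral calibration, um/pixel.
#' @param opening_radius_um disc radius in um (default 2: about twice a
#'   process half-width, well under a soma radius).
#' @return Logical matrix (subset of `cell_mask`) with attribute `empty`.
#' @export
soma_mask <- function(cell_mask, pixel_size_um, opening_radius_um = 2) {
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop("empty mask")
  r_px <- opening_radius_um / pixel_size_um
  kern <- disc_kernel(r_px)
  # pad so the opening is not clipped at the mask bounding box
  k <- nrow(kern) %/% 2 + 1L
  nr <- nrow(cell_mask)
  nc <- ncol(cell_mask)
  p <- matrix(FALSE, nr + 2L * k, nc + 2L * k)
  p[(k + 1L):(k + nr), (k + 1L):(k + nc)] <- cell_mask
  op <- EBImage::opening(p * 1, kern) > 0
  op <- op[(k + 1L):(k + nr), (k + 1L):(k + nc), drop = FALSE]
  if (!any(op)) {
    out <- op
    attr(out, "empty") <- TRUE
    return(out)
  }
  lab <- cpp_label(op, 8L)
  counts <- tabulate(lab, nbins = max(lab))
  out <- lab == which.max(counts)
  out <- out & cell_mask
  attr(out, "empty") <- FALSE
  out
}

#' Soma / ramification decomposition of marker intensity in one cell
#'
#' Measures the marker channel within the full cell outline, within the soma
#' outline derived by [soma_mask()], and within the ramification pixels
#' (cell minus soma). Two ramification measures are reported: the direct
#' per-pixel mean over ramification pixels (`mean_ramification`, the primary
#' output, which satisfies the pixel-weighted reconstruction
#' `n_soma * mean_soma + n_ram * mean_ramification = n_total * mean_total`)
#' and the literal difference of means `ramification_literal =
#' mean_total - mean_soma`. Cells whose soma vanishes under the opening
#' report the soma-dependent fields as `NA` with `soma_empty = TRUE`.
#'
#' @param cell_mask logical matrix of one connected cell.
#' @param image marker channel projection, already background-subtracted
#'   with the marker rolling-ball radius.
#' @param pixel_size_um lateral calibration, um/pixel.
#' @param opening_radius_um soma opening radius, um.
#' @return One-row tibble: `mean_total`, `mean_soma`, `mean_ramification`,
#'   `ramification_literal`, `n_pixels_total`, `n_pixels_soma`,
#'   `n_pixels_ramification`, `soma_empty`.
#' @export
decompose_intensity <- function(cell_mask, image, pixel_size_um,
                                opening_radius_um = 2) {
  cell_mask <- cell_mask > 0
  soma <- soma_mask(cell_mask, pixel_size_um, opening_radius_um)
  ram <- cell_mask & !soma
  n_tot <- sum(cell_mask)
  n_soma <- sum(soma)
  n_ram <- sum(ram)
  mean_total <- mean_in_mask(image, cell_mask)
  if (isTRUE(attr(soma, "empty")) || n_soma == 0) {
    return(tibble::tibble(
      mean_total = mean_total, mean_soma = NA_real_,
      mean_ramification = if (n_ram > 0) mean_in_mask(image, ram) else NA_real_,
      ramification_literal = NA_real_,
      n_pixels_total = n_tot, n_pixels_soma = 0L, n_pixels_ramification = n_ram,
      soma_empty = TRUE
    ))
  }
  mean_soma <- mean_in_mask(image, soma)
  mean_ram <- if (n_ram > 0) mean_in_mask(image, ram) else NA_real_
  tibble::tibble(
    mean_total = mean_total, mean_soma = mean_soma,
    mean_ramification = mean_ram,
    ramification_literal = mean_total - mean_soma,
    n_pixels_total = n_tot, n_pixels_soma = n_soma,
    n_pixels_ramification = n_ram,
    soma_empty = FALSE
  )
}

#' Analysis window (region of interest) specification
#'
#' A named rectangular analysis window, optionally placed at a stated
#' distance from a lesion-edge anchor along a direction into intact tissue.
#' With the defaults of [lesion_rois()], the standard windows are `edge`
#' (offset 0), `intermediate` (350 um) and `distance` (700 um).
#'
#' @param name window name.
#' @param x_um,y_um window origin (top-left corner), um.
#' @param width_um,height_um window size, um (default 210 x 210).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(name, x_um, y_um, width_um = 210, height_um = 210) {
  if (width_um <= 0 || height_um <= 0) stop("window size must be positive")
  structure(list(name = name, x_um = x_um, y_um = y_um,
                 width_um = width_um, height_um = height_um),
            class = "roi_spec")
}

#' Standard lesion-distance windows
#'
#' Builds square analysis windows at stated offsets from a lesion-edge
#' anchor point, along an axis-aligned unit direction into intact tissue.
#' Each window starts at `anchor + direction * offset` and extends one
#' window length along the direction, centred on the anchor in the
#' perpendicular axis.
#'
#' @param anchor_um numeric `(x, y)` of the lesion-edge anchor, um.
#' @param direction axis-aligned unit vector, e.g. `c(1, 0)`.
#' @param offsets_um distances from the anchor, um.
#' @param names window names.
#' @param window_um square window side, um.
#' @return List of [roi_spec()] objects.
#' @export
lesion_rois <- function(anchor_um = c(0, 0), direction = c(1, 0),
                        offsets_um = c(0, 350, 700),
                        names = c("edge", "intermediate", "distance"),
                        window_um = 210) {
  if (!all(sort(abs(direction)) == c(0, 1))) {
    stop("direction must be an axis-aligned unit vector")
  }
  stopifnot(length(offsets_um) == length(names), all(offsets_um >= 0))
  purrr::map2(offsets_um, names, function(off, nm) {
    ox <- anchor_um[1] + direction[1] * off
    oy <- anchor_um[2] + direction[2] * off
    if (direction[1] != 0) {
      if (direction[1] < 0) ox <- ox - window_um
      oy <- anchor_um[2] - window_um / 2
    } else {
      if (direction[2] < 0) oy <- oy - window_um
      ox <- anchor_um[1] - window_um / 2
    }
    roi_spec(nm, ox, oy, window_um, window_um)
  })
}

roi_contains <- function(roi, x_um, y_um) {
  x_um >= roi$x_um & x_um < roi$x_um + roi$width_um &
    y_um >= roi$y_um & y_um < roi$y_um + roi$height_um
}

#' Per-cell records for one scene
#'
#' Computes, for every cell of a label mask, the shape descriptors, the
#' morphological class and the marker intensity decomposition, producing the
#' per-cell table the group summaries are built from.
#'
#' @param labels `label_mask` from [segment_cells()].
#' @param marker_image marker projection after [preprocess_marker()].
#' @param config a [pipeline_config()].
#' @param pixel_size_um lateral calibration; defaults to the label attribute.
#' @return Tibble with one row per cell: identifiers, centroid, shape
#'   descriptors, class, infiltration flag and marker intensities.
#' @export
cell_records <- function(labels, marker_image, config,
                         pixel_size_um = attr(labels, "pixel_size_um")) {
  n <- max(labels)
  desc <- descriptors_table(labels, pixel_size_um,
                            perimeter_method = config$perimeter_method)
  if (n == 0) {
    return(empty_cell_records())
  }
  desc <- classify_morphology(desc)
  crops <- label_crops(labels)
  intens <- purrr::map_dfr(seq_len(n), function(id) {
    cr <- crops[[id]]
    img_sub <- marker_image[cr$i0:(cr$i0 + nrow(cr$mask) - 1L),
                            cr$j0:(cr$j0 + ncol(cr$mask) - 1L), drop = FALSE]
    decompose_intensity(cr$mask, img_sub, pixel_size_um,
                        config$soma_opening_radius_um)
  })
  dplyr::bind_cols(desc, intens) |>
    dplyr::rename(
      mean_tmem_total = "mean_total",
      mean_tmem_soma = "mean_soma",
      mean_tmem_ramification = "mean_ramification"
    )
}

empty_cell_records <- function() {
  tibble::tibble(
    cell_id = integer(), centroid_x_px = numeric(), centroid_y_px = numeric(),
    area_um2 = numeric(), perimeter_um = numeric(), circularity = numeric(),
    class = factor(character(),
                   levels = c("ramified", "hypertrophic", "ameboid")),
    putative_infiltrated = logical(),
    mean_tmem_total = numeric(), mean_tmem_soma = numeric(),
    mean_tmem_ramification = numeric(), ramification_literal = numeric(),
    n_pixels_total = integer(), n_pixels_soma = integer(),
    n_pixels_ramification = integer(), soma_empty = logical()
  )
}

#' Restrict per-cell quantification to an analysis window
#'
#' Keeps the cells whose centroid falls inside the window (membership by
#' centroid avoids double counting across adjacent windows) and tags the
#' records with the window name.
#'
#' @param labels `label_mask` from [segment_cells()].
#' @param marker_image marker projection after [preprocess_marker()].
#' @param roi a [roi_spec()].
#' @param config a [pipeline_config()].
#' @param pixel_size_um lateral calibration; defaults to the label attribute.
#' @return Per-cell tibble as [cell_records()], plus a `roi` column; empty
#'   (but well-formed) if no centroid falls inside.
#' @export
quantify_roi <- function(labels, marker_image, roi, config,
                         pixel_size_um = attr(labels, "pixel_size_um")) {
  stopifnot(inherits(roi, "roi_spec"))
  rec <- cell_records(labels, marker_image, config, pixel_size_um)
  cx_um <- (rec$centroid_x_px + 0.5) * pixel_size_um
  cy_um <- (rec$centroid_y_px + 0.5) * pixel_size_um
  keep <- roi_contains(roi, cx_um, cy_um)
  dplyr::mutate(rec[keep, , drop = FALSE], roi = roi$name, .before = 1)
}

#' Read analysis windows from a YAML file
#'
#' The file holds a list of entries with fields `name`, `x_um`, `y_um` and
#' optional `width_um`, `height_um`.
#'
#' @param path YAML file path.
#' @return List of [roi_spec()] objects.
#' @export
read_rois <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(r) {
    roi_spec(r$name, r$x_um, r$y_um,
             r$width_um %||% 210, r$height_um %||% 210)
  })
}
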