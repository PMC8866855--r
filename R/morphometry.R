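# Perimeter of a connected mask by Moore-neighbour boundary tracing through
# pixel centres, in pixel units. Diagonal steps carry the standard corrected
# chain-code weight (Kulpa-type, 1.340) so smooth outlines are measured
# without the systematic excess of raw sqrt(2) weighting; straight steps
# count 1, so axis-aligned polygons keep their exact geometric perimeter.
trace_perimeter_px <- function(mask, diag_weight = 1.340) {
  n_px <- sum(mask)
  if (n_px == 0) stop("empty mask")
  if (n_px == 1) return(4)
  m <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(m)
  start <- which(m)[1] # column-major scan: north neighbour is background
  si <- (start - 1L) %% nr + 1L
  sj <- (start - 1L) %/% nr + 1L
  # clockwise Moore neighbourhood (row down, column right): N NE E SE S SW W NW
  di <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dj <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  ci <- si
  cj <- sj
  bdir <- 1L # backtrack direction (towards a background neighbour)
  per <- 0
  steps <- 0L
  first_i <- NA_integer_
  first_j <- NA_integer_
  max_steps <- 8L * n_px + 8L
  repeat {
    # next foreground neighbour, scanning clockwise from just past backtrack
    prev_d <- bdir
    hit <- 0L
    for (k in 1:8) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      ni <- ci + di[d]
      nj <- cj + dj[d]
      if (m[ni, nj]) {
        hit <- d
        break
      }
      prev_d <- d
    }
    if (hit == 0L) break # isolated pixel (cannot happen for n_px > 1)
    ni <- ci + di[hit]
    nj <- cj + dj[hit]
    if (steps > 0L && ci == si && cj == sj &&
        ni == first_i && nj == first_j) {
      break # Jacob's criterion: leaving the start the same way again
    }
    if (steps == 0L) {
      first_i <- ni
      first_j <- nj
    }
    per <- per + if (di[hit] != 0L && dj[hit] != 0L) diag_weight else 1
    # new backtrack: points at the background neighbour examined last
    pi_ <- ci + di[prev_d]
    pj_ <- cj + dj[prev_d]
    ci <- ni
    cj <- nj
    bdir <- which(di == (pi_ - ci) & dj == (pj_ - cj))
    steps <- steps + 1L
    if (steps > max_steps) break
  }
  per
}

# Cauchy-Crofton perimeter estimate from intercept counts in 4 directions,
# pixel units.
perimeter_crofton_px <- function(mask) {
  if (sum(mask) == 0) stop("empty mask")
  m <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  c0 <- sum(m[, -1] != m[, -ncol(m)])
  c90 <- sum(m[-1, ] != m[-nrow(m), ])
  c45 <- sum(m[-nrow(m), -ncol(m)] != m[-1, -1])
  c135 <- sum(m[-nrow(m), -1] != m[-1, -ncol(m)])
  (pi / 4) * (c0 / 2 + c90 / 2 + (c45 / 2 + c135 / 2) / sqrt(2))
}

#' Shape descriptors of a single cell mask
#'
#' Area, perimeter and circularity of one connected binary mask. Area is the
#' pixel count scaled by the squared pixel size; the perimeter is the length
#' of the traced polygonal boundary of the 8-connected outline (corrected
#' chain code; a Crofton estimator is available as an alternative);
#' circularity is `4 * pi * area / perimeter^2`, clipped to 1 (digitized
#' small shapes can otherwise exceed 1).
#'
#' @param mask logical (or 0/1) matrix holding one connected cell.
#' @param pixel_size_um lateral calibration, um/pixel.
#' @param perimeter_method `"traced"` or `"crofton"`.
#' @return One-row tibble: `area_um2`, `perimeter_um`, `circularity`.
#' @export
shape_descriptors <- function(mask, pixel_size_um,
                              perimeter_method = c("traced", "crofton")) {
  perimeter_method <- match.arg(perimeter_method)
  mask <- mask > 0
  n_px <- sum(mask)
  if (n_px == 0) stop("empty mask")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  per_px <- switch(perimeter_method,
    traced = trace_perimeter_px(mask),
    crofton = perimeter_crofton_px(mask)
  )
  area <- n_px * pixel_size_um^2
  per <- per_px * pixel_size_um
  tibble::tibble(
    area_um2 = area,
    perimeter_um = per,
    circularity = min(1, 4 * pi * area / per^2)
  )
}

#' Shape descriptors for every cell of a label mask
#'
#' @param labels a `label_mask` from [segment_cells()] (or any integer label
#'   matrix with a `pixel_size_um` attribute / explicit argument).
#' @param pixel_size_um lateral calibration; defaults to the attribute.
#' @param perimeter_method `"traced"` or `"crofton"`.
#' @return Tibble with one row per label: `cell_id`, centroid (0-based pixel
#'   coordinates), `area_um2`, `perimeter_um`, `circularity`.
#' @export
descriptors_table <- function(labels,
                              pixel_size_um = attr(labels, "pixel_size_um"),
                              perimeter_method = c("traced", "crofton")) {
  perimeter_method <- match.arg(perimeter_method)
  if (is.null(pixel_size_um)) stop("pixel_size_um is required")
  crops <- label_crops(labels)
  purrr::map_dfr(seq_along(crops), function(id) {
    cr <- crops[[id]]
    d <- shape_descriptors(cr$mask, pixel_size_um, perimeter_method)
    tibble::tibble(
      cell_id = id,
      centroid_x_px = cr$centroid_x_px,
      centroid_y_px = cr$centroid_y_px,
      area_um2 = d$area_um2, perimeter_um = d$perimeter_um,
      circularity = d$circularity
    )
  })
}

#' Morphological classification of Iba1-positive cells
#'
#' Applies the activation-state gates: hypertrophic if area >= 250 um2;
#' otherwise ameboid if circularity > 0.16, else ramified. Cells with
#' circularity > 0.5 are additionally flagged as putative infiltrated
#' myeloid cells. The boundary cases (area exactly 250, circularity exactly
#' 0.16) are assigned to hypertrophic and ramified respectively so the three
#' gates form a true partition.
#'
#' @param descriptors tibble with columns `area_um2` and `circularity`
#'   (e.g. from [descriptors_table()]).
#' @param area_cutoff_um2 hypertrophic area gate, default 250.
#' @param circularity_cutoff ameboid circularity gate, default 0.16.
#' @param infiltrated_cutoff infiltration flag gate, default 0.5.
#' @return The input tibble with `class` (factor: ramified, hypertrophic,
#'   ameboid) and `putative_infiltrated` columns appended.
#' @export
classify_morphology <- function(descriptors, area_cutoff_um2 = 250,
                                circularity_cutoff = 0.16,
                                infiltrated_cutoff = 0.5) {
  stopifnot(all(c("area_um2", "circularity") %in% names(descriptors)))
  cls <- ifelse(
    descriptors$area_um2 >= area_cutoff_um2, "hypertrophic",
    ifelse(descriptors$circularity > circularity_cutoff, "ameboid", "ramified")
  )
  dplyr::mutate(
    tibble::as_tibble(descriptors),
    class = factor(cls, levels = c("ramified", "hypertrophic", "ameboid")),
    putative_infiltrated = .data$circularity > infiltrated_cutoff
  )
}

#' Population composition by morphological class
#'
#' @param cells tibble with a `class` column (factor or character over the
#'   three morphological classes).
#' @return Tibble with one row per class: `class`, `n`, `percent`
#'   (percentages sum to 100).
#' @export
population_fractions <- function(cells) {
  if (nrow(cells) == 0) stop("at least one cell is required")
  cl <- factor(as.character(cells$class),
               levels = c("ramified", "hypertrophic", "ameboid"))
  tab <- table(cl)
  tibble::tibble(
    class = factor(names(tab), levels = levels(cl)),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / nrow(cells)
  )
}
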