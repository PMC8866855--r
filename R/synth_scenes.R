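#' Specification of a synthetic two-channel scene
#'
#' Describes a synthetic confocal volume emulating the acquisition geometry
#' the pipeline is designed for: a 210 x 210 x 12 um two-channel
#' (Tmem119, Iba1) volume at 0.2 um/pixel and 1.13 um z-step, 12-bit gray
#' levels. Cells of the three morphological classes are placed without
#' overlap; the marker (Tmem119) channel is painted with class-dependent
#' soma and process levels while Iba1 is uniform over each footprint.
#'
#' Per-class intensity arguments accept either a scalar (recycled) or a
#' named vector over `ramified`, `hypertrophic`, `ameboid`.
#'
#' @param width_um,height_um,depth_um scene extent in micrometres.
#' @param pixel_size_um lateral calibration, um/pixel.
#' @param z_step_um axial step, um.
#' @param bit_max maximum gray level (12-bit default, 4096).
#' @param n_cells named integer vector: cells per class.
#' @param iba1_mean Iba1 signal level painted over the whole footprint.
#' @param tmem_soma_mean,tmem_process_mean Tmem119 signal painted on soma and
#'   process pixels, per class.
#' @param background_level constant background offset (gray levels).
#' @param background_gradient_amplitude peak deviation of the planar
#'   background gradient (gray levels).
#' @param gaussian_noise_sd additive read-noise SD (gray levels).
#' @param poisson_scaling photon scaling s of the shot-noise model
#'   `Poisson(value * s) / s`; 0 disables shot noise.
#' @param psf_sigma_um Gaussian PSF sigma applied per slice; 0 disables blur.
#' @param ameboid_round_fraction fraction of ameboid cells drawn as smooth
#'   ellipses (circularity > 0.5); the remainder are rough star shapes with
#'   circularity in (0.16, 0.5].
#' @param seed integer seed making the scene fully reproducible.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_um = 210, height_um = 210, depth_um = 12,
                       pixel_size_um = 0.2, z_step_um = 1.13, bit_max = 4096,
                       n_cells = c(ramified = 20, hypertrophic = 20,
                                   ameboid = 20),
                       iba1_mean = 1200,
                       tmem_soma_mean = c(ramified = 300, hypertrophic = 250,
                                          ameboid = 60),
                       tmem_process_mean = c(ramified = 900,
                                             hypertrophic = 700,
                                             ameboid = 60),
                       background_level = 100,
                       background_gradient_amplitude = 30,
                       gaussian_noise_sd = 20,
                       poisson_scaling = 0.25,
                       psf_sigma_um = 0.15,
                       ameboid_round_fraction = 0.5,
                       seed = 1L) {
  classes <- c("ramified", "hypertrophic", "ameboid")
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 3), classes)
    if (!all(classes %in% names(x))) {
      stop(what, " must be a scalar or named over all three classes")
    }
    x[classes]
  }
  n_cells <- expand(n_cells, "n_cells")
  iba1_mean <- expand(iba1_mean, "iba1_mean")
  tmem_soma_mean <- expand(tmem_soma_mean, "tmem_soma_mean")
  tmem_process_mean <- expand(tmem_process_mean, "tmem_process_mean")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (any(n_cells < 0)) stop("cell counts must be >= 0")
  means <- c(iba1_mean, tmem_soma_mean, tmem_process_mean, background_level)
  if (any(means < 0) || any(means > bit_max)) {
    stop("intensity means must lie within [0, bit_max]")
  }
  if (ameboid_round_fraction < 0 || ameboid_round_fraction > 1) {
    stop("ameboid_round_fraction must be in [0, 1]")
  }
  structure(
    list(width_um = width_um, height_um = height_um, depth_um = depth_um,
         pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         bit_max = bit_max, n_cells = n_cells, iba1_mean = iba1_mean,
         tmem_soma_mean = tmem_soma_mean,
         tmem_process_mean = tmem_process_mean,
         background_level = background_level,
         background_gradient_amplitude = background_gradient_amplitude,
         gaussian_noise_sd = gaussian_noise_sd,
         poisson_scaling = poisson_scaling, psf_sigma_um = psf_sigma_um,
         ameboid_round_fraction = ameboid_round_fraction,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Shared per-class shape distributions (um). Parameter ranges are chosen so
# each class straddles nothing: ramified land clearly under both gates,
# hypertrophic clearly above the area gate, ameboid inside the
# high-circularity / sub-area gate.
class_shape_params <- function(class_label) {
  switch(class_label,
    ramified = list(soma_d = c(6, 8), n_proc = 5:8, len = c(10, 25),
                    w0 = c(0.8, 1.0), taper = 0.4),
    hypertrophic = list(soma_d = c(16.5, 19), n_proc = 4:6, len = c(9, 14),
                        w0 = c(2.4, 3.0), taper = 0.6),
    ameboid = list(area = c(80, 230))
  )
}

# Rasterize a tapered process stroke (3-segment polyline) into a logical
# grid. Coordinates in um; pixel centre of (i, j) is ((j-0.5) px, (i-0.5) px).
stamp_process <- function(mask, px, start, theta, length_um, w0, w1) {
  nseg <- 3L
  seg_len <- length_um / nseg
  p0 <- start
  dir <- theta
  total <- 0
  for (s in seq_len(nseg)) {
    p1 <- p0 + seg_len * c(cos(dir), sin(dir))
    half0 <- (w0 + (w1 - w0) * total / length_um) / 2
    half1 <- (w0 + (w1 - w0) * (total + seg_len) / length_um) / 2
    pad <- max(half0, half1) + px
    ilo <- max(1, floor((min(p0[2], p1[2]) - pad) / px))
    ihi <- min(nrow(mask), ceiling((max(p0[2], p1[2]) + pad) / px))
    jlo <- max(1, floor((min(p0[1], p1[1]) - pad) / px))
    jhi <- min(ncol(mask), ceiling((max(p0[1], p1[1]) + pad) / px))
    if (ilo > ihi || jlo > jhi) {
      p0 <- p1
      dir <- dir + runif(1, -0.45, 0.45)
      total <- total + seg_len
      next
    }
    ii <- seq(ilo, ihi)
    jj <- seq(jlo, jhi)
    ym <- matrix((ii - 0.5) * px, length(ii), length(jj))
    xm <- matrix((jj - 0.5) * px, length(ii), length(jj), byrow = TRUE)
    dx <- p1[1] - p0[1]
    dy <- p1[2] - p0[2]
    len2 <- dx^2 + dy^2
    t <- pmin(pmax(((xm - p0[1]) * dx + (ym - p0[2]) * dy) / len2, 0), 1)
    distx <- xm - (p0[1] + t * dx)
    disty <- ym - (p0[2] + t * dy)
    halfw <- half0 + (half1 - half0) * t
    hit <- distx^2 + disty^2 <= halfw^2
    mask[ii, jj] <- mask[ii, jj] | hit
    p0 <- p1
    dir <- dir + runif(1, -0.45, 0.45)
    total <- total + seg_len
  }
  mask
}

# Rasterize an ameboid blob (smooth wobbly ellipse or rough star) of the
# requested area on its own local grid.
ameboid_blob <- function(area, round_shape, px) {
  ext <- 2 * sqrt(area / pi) * 1.8
  n <- ceiling(ext / px)
  cx <- cy <- n / 2 * px
  ii <- seq_len(n)
  ym <- matrix((ii - 0.5) * px - cy, n, n)
  xm <- matrix((ii - 0.5) * px - cx, n, n, byrow = TRUE)
  if (round_shape) {
    q <- runif(1, 0.75, 1)
    th <- runif(1, 0, pi)
    a_ax <- sqrt(area / pi) / sqrt(q)
    b_ax <- sqrt(area / pi) * sqrt(q)
    xr <- xm * cos(th) + ym * sin(th)
    yr <- -xm * sin(th) + ym * cos(th)
    wobble <- runif(1, 0, 0.05)
    k <- sample(6:9, 1)
    phi <- runif(1, 0, 2 * pi)
    ang <- atan2(yr, xr)
    foot <- (xr / a_ax)^2 + (yr / b_ax)^2 <=
      (1 + wobble * cos(k * ang + phi))^2
  } else {
    amp <- runif(1, 0.25, 0.4)
    k <- sample(5:6, 1)
    phi <- runif(1, 0, 2 * pi)
    r0 <- sqrt(area / (pi * (1 + amp^2 / 2)))
    ang <- atan2(ym, xm)
    rr <- sqrt(xm^2 + ym^2)
    foot <- rr <= r0 * (1 + amp * cos(k * ang + phi))
  }
  foot
}

#' Draw one synthetic cell footprint with soma/process decomposition
#'
#' Generates a binary footprint for one cell of the requested morphological
#' class, together with its soma and process sub-masks. Shape parameters are
#' sampled so each class lands inside its area/circularity gate: ramified
#' cells are a 6-8 um soma with 5-8 thin tapering processes 12-25 um long
#' (area in 60-240 um2, circularity well below 0.16); hypertrophic cells a
#' 16.5-19 um soma with 4-6 thick (2.4-3 um) processes (area > 250 um2);
#' ameboid cells a smooth ellipse or rough star (area 80-230 um2,
#' circularity > 0.16, above 0.5 for the smooth variant).
#'
#' @param class_label one of `"ramified"`, `"hypertrophic"`, `"ameboid"`.
#' @param pixel_size_um lateral calibration, um/pixel.
#' @param seed optional integer seed for a reproducible single shape.
#' @param ameboid_round if `TRUE`/`FALSE`, force the ameboid sub-shape
#'   (ellipse vs star); `NULL` picks at random with probability 0.5.
#'
#' @return List with logical matrices `footprint`, `soma`, `process`
#'   (`soma | process == footprint`, `soma & process` empty) and the soma
#'   diameter in um.
#' @export
make_cell_shape <- function(class_label, pixel_size_um, seed = NULL,
                            ameboid_round = NULL) {
  classes <- c("ramified", "hypertrophic", "ameboid")
  if (!is.character(class_label) || length(class_label) != 1 ||
      !(class_label %in% classes)) {
    stop("unknown class label: ", paste(class_label, collapse = ", "),
         " (expected ramified, hypertrophic or ameboid)")
  }
  if (!is.null(seed)) set.seed(seed)
  px <- pixel_size_um
  prm <- class_shape_params(class_label)

  if (class_label == "ameboid") {
    area <- runif(1, prm$area[1], prm$area[2])
    round_shape <- if (is.null(ameboid_round)) runif(1) < 0.5 else ameboid_round
    foot <- ameboid_blob(area, round_shape, px)
    soma <- foot
    process <- foot & FALSE
    soma_d <- 2 * sqrt(area / pi)
  } else {
    soma_d <- runif(1, prm$soma_d[1], prm$soma_d[2])
    n_proc <- sample(prm$n_proc, 1)
    len <- runif(n_proc, prm$len[1], prm$len[2])
    w0 <- runif(n_proc, prm$w0[1], prm$w0[2])
    w1 <- prm$taper * w0
    r <- soma_d / 2
    ext <- 2 * (r + max(len)) + 2
    n <- ceiling(ext / px)
    cx <- cy <- n / 2 * px
    ii <- seq_len(n)
    ym <- matrix((ii - 0.5) * px - cy, n, n)
    xm <- matrix((ii - 0.5) * px - cx, n, n, byrow = TRUE)
    soma <- xm^2 + ym^2 <= r^2
    foot <- soma
    thetas <- 2 * pi * (seq_len(n_proc) - 1) / n_proc +
      runif(n_proc, -pi / n_proc * 0.7, pi / n_proc * 0.7)
    for (p in seq_len(n_proc)) {
      start <- c(cx, cy) + 0.8 * r * c(cos(thetas[p]), sin(thetas[p]))
      foot <- stamp_process(foot, px, start, thetas[p], len[p], w0[p], w1[p])
    }
    process <- foot & !soma
  }

  rows <- which(rowSums(foot) > 0)
  cols <- which(colSums(foot) > 0)
  r0 <- max(1L, min(rows) - 2L)
  r1 <- min(nrow(foot), max(rows) + 2L)
  c0 <- max(1L, min(cols) - 2L)
  c1 <- min(ncol(foot), max(cols) + 2L)
  list(footprint = foot[r0:r1, c0:c1, drop = FALSE],
       soma = soma[r0:r1, c0:c1, drop = FALSE],
       process = process[r0:r1, c0:c1, drop = FALSE],
       soma_diameter_um = soma_d)
}

#' Render a synthetic scene with per-cell ground truth
#'
#' Cell placement works in two phases, mimicking how microglial territories
#' interdigitate in tissue: first every soma (and every ameboid blob) is
#' placed by rejection sampling with a 1.5 um clearance to all previously
#' painted pixels; then processes are grown stroke by stroke, each stroke
#' re-sampled (and eventually shortened) until it avoids every other cell by
#' the same clearance. Footprints of distinct cells therefore never share a
#' pixel. Both channels are painted over a small range of z-slices per cell,
#' a planar background gradient is added, a Gaussian PSF applied per slice,
#' then Poisson-Gaussian noise; values are rounded and clipped to
#' `[0, bit_max]`. The same spec (which includes the seed) always reproduces
#' the identical stack bit for bit.
#'
#' Painted values are background + signal, so with background, noise and
#' blur all zero the channel mean over a truth mask equals the painted
#' signal mean exactly. Truth means recorded in the truth table are
#' signal-only (what an ideal background-subtracted measurement recovers).
#'
#' @param spec a [scene_spec()].
#' @param max_retries placement attempts per soma before failing; process
#'   strokes get `max_retries / 40` attempts each before being dropped.
#' @return List of class `iba1_scene` with elements `stack`
#'   (a [calibrated_stack()]) and `truth` (class `scene_truth`: tibble
#'   `cells`, label matrices `footprint_labels` and `soma_labels`, and the
#'   generating `spec`).
#' @export
render_scene <- function(spec, max_retries = 2000L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  nx <- round(spec$width_um / px)
  ny <- round(spec$height_um / px)
  nz <- max(1L, round(spec$depth_um / spec$z_step_um))

  clearance_px <- max(1L, round(2 / px))
  border_px <- max(2L, round(2 / px))
  clear_kern <- disc_kernel(clearance_px)

  lab_all <- matrix(0L, ny, nx)
  cells <- list()
  cell_id <- 0L

  in_border <- function(i0, i1, j0, j1) {
    i0 > border_px && j0 > border_px &&
      i1 <= ny - border_px && j1 <= nx - border_px
  }

  place_blob <- function(local_mask, id, kern = clear_kern) {
    dil <- EBImage::dilate(local_mask * 1, kern) > 0
    hr <- nrow(dil)
    hc <- ncol(dil)
    if (hr + 2 * border_px >= ny || hc + 2 * border_px >= nx) {
      return(NULL)
    }
    for (try_i in seq_len(max_retries)) {
      i0 <- sample.int(ny - hr - 2L * border_px, 1L) + border_px
      j0 <- sample.int(nx - hc - 2L * border_px, 1L) + border_px
      win <- lab_all[i0:(i0 + hr - 1L), j0:(j0 + hc - 1L)]
      if (!any(dil & win != 0L)) {
        idx <- which(local_mask)
        li <- (idx - 1L) %% nrow(local_mask) + i0
        lj <- (idx - 1L) %/% nrow(local_mask) + j0
        lin <- li + (lj - 1L) * ny
        lab_all[lin] <<- id
        return(lin)
      }
    }
    NULL
  }

  # ---- phase 1: somata and ameboid blobs (largest first) ----
  for (cl in c("hypertrophic", "ameboid", "ramified")) {
    prm <- class_shape_params(cl)
    n_needed <- spec$n_cells[[cl]]
    for (c_i in seq_len(n_needed)) {
      cell_id <- cell_id + 1L
      if (cl == "ameboid") {
        area <- runif(1, prm$area[1], prm$area[2])
        round_shape <- runif(1) < spec$ameboid_round_fraction
        local <- ameboid_blob(area, round_shape, px)
        soma_d <- 2 * sqrt(area / pi)
        kern <- clear_kern
      } else {
        soma_d <- runif(1, prm$soma_d[1], prm$soma_d[2])
        r_px <- soma_d / 2 / px
        local <- disc_kernel(r_px) > 0
        # reserve breathing room around somata so processes can grow later
        kern <- disc_kernel(clearance_px + round(5 / px))
      }
      lin <- place_blob(local, cell_id, kern)
      if (is.null(lin)) {
        stop(sprintf(
          "failed to place %d '%s' cells after %d retries (placed %d)",
          n_needed, cl, max_retries, c_i - 1L
        ))
      }
      i_all <- (lin - 1L) %% ny + 1L
      j_all <- (lin - 1L) %/% ny + 1L
      cells[[cell_id]] <- list(
        class = cl, lin_soma = lin, soma_d = soma_d,
        center = c(mean(i_all), mean(j_all))
      )
    }
  }

  # ---- phase 2: grow processes stroke by stroke ----
  arm_retries <- max(5L, as.integer(max_retries / 40L))

  grow_arms <- function(id) {
    cell <- cells[[id]]
    prm <- class_shape_params(cell$class)
    n_proc <- sample(prm$n_proc, 1)
    r <- cell$soma_d / 2
    reach_um <- r + prm$len[2] + max(prm$w0) + 1
    half <- ceiling(reach_um / px)
    ci <- round(cell$center[1])
    cj <- round(cell$center[2])
    i0 <- max(1L, ci - half)
    j0 <- max(1L, cj - half)
    win_r <- i0:min(ny, ci + half)
    win_c <- j0:min(nx, cj + half)
    # soma centre in local um coordinates of the window
    c_local <- c((cj - j0 + 0.5) * px, (ci - i0 + 0.5) * px)
    base <- 2 * pi * (seq_len(n_proc) - 1) / n_proc + runif(1, 0, 2 * pi)

    try_arm <- function(theta, len, w0) {
      blank <- matrix(FALSE, length(win_r), length(win_c))
      start <- c_local + 0.8 * r * c(cos(theta), sin(theta))
      arm <- stamp_process(blank, px, start, theta, len, w0,
                           prm$taper * w0)
      idx <- which(arm)
      if (length(idx) == 0) return(NULL)
      ai <- (idx - 1L) %% nrow(arm) + i0
      aj <- (idx - 1L) %/% nrow(arm) + j0
      if (!in_border(min(ai), max(ai), min(aj), max(aj))) return(NULL)
      dil <- EBImage::dilate(arm * 1, clear_kern) > 0
      win <- lab_all[win_r, win_c]
      if (any(dil & win != 0L & win != id)) return(NULL)
      new_px <- idx[win[idx] == 0L]
      # an arm must genuinely extend the cell, not retrace existing pixels
      if (length(new_px) < 0.5 * len * 0.7 * w0 / px^2) return(NULL)
      (ai[match(new_px, idx)]) + (aj[match(new_px, idx)] - 1L) * ny
    }

    arm_lin <- integer(0)
    n_placed <- 0L
    for (p in seq_len(n_proc)) {
      for (attempt in seq_len(arm_retries)) {
        theta <- if (attempt <= 3) {
          base[p] + runif(1, -pi / n_proc * 0.7, pi / n_proc * 0.7)
        } else {
          runif(1, 0, 2 * pi)
        }
        lmax <- if (attempt > arm_retries / 2) {
          prm$len[1] + 0.3 * diff(prm$len)
        } else {
          prm$len[2]
        }
        lin <- try_arm(theta, runif(1, prm$len[1], lmax),
                       runif(1, prm$w0[1], prm$w0[2]))
        if (!is.null(lin)) {
          lab_all[lin] <<- id
          arm_lin <- c(arm_lin, lin)
          n_placed <- n_placed + 1L
          break
        }
      }
    }
    # rescue: a cell must keep enough processes to stay in its gate, so
    # crowded cells fall back to short strokes in any free direction
    min_arms <- if (cell$class == "ramified") 3L else 2L
    extra <- 0L
    while (n_placed < min_arms && extra < 300L) {
      extra <- extra + 1L
      lin <- try_arm(runif(1, 0, 2 * pi),
                     runif(1, prm$len[1], prm$len[1] + 2),
                     runif(1, prm$w0[1], prm$w0[2]))
      if (!is.null(lin)) {
        lab_all[lin] <<- id
        arm_lin <- c(arm_lin, lin)
        n_placed <- n_placed + 1L
      }
    }
    list(arm_lin = arm_lin, n_placed = n_placed, min_arms = min_arms)
  }

  for (id in seq_along(cells)) {
    if (cells[[id]]$class == "ameboid") {
      cells[[id]]$lin_foot <- cells[[id]]$lin_soma
      next
    }
    arm_lin <- integer(0)
    # a cell stuck in a crowded pocket is relocated and regrown
    for (reloc in 0:2) {
      res <- grow_arms(id)
      arm_lin <- res$arm_lin
      if (res$n_placed >= res$min_arms || reloc == 2) break
      lab_all[cells[[id]]$lin_soma] <- 0L
      lab_all[arm_lin] <- 0L
      r_px <- cells[[id]]$soma_d / 2 / px
      new_lin <- place_blob(disc_kernel(r_px) > 0, id,
                            disc_kernel(clearance_px + round(5 / px)))
      if (is.null(new_lin)) {
        # nowhere better: restore the original placement
        lab_all[cells[[id]]$lin_soma] <- id
        lab_all[arm_lin] <- id
        break
      }
      i_all <- (new_lin - 1L) %% ny + 1L
      j_all <- (new_lin - 1L) %/% ny + 1L
      cells[[id]]$lin_soma <- new_lin
      cells[[id]]$center <- c(mean(i_all), mean(j_all))
      arm_lin <- integer(0)
    }
    cells[[id]]$lin_foot <- c(cells[[id]]$lin_soma, arm_lin)
  }

  footprint_labels <- lab_all
  soma_labels <- matrix(0L, ny, nx)
  for (id in seq_along(cells)) soma_labels[cells[[id]]$lin_soma] <- id

  # ---- painting ----
  xn <- matrix(seq_len(nx) / nx - 0.5, ny, nx, byrow = TRUE)
  yn <- matrix(seq_len(ny) / ny - 0.5, ny, nx)
  bg_plane <- function() {
    phi <- runif(1, 0, 2 * pi)
    p <- cos(phi) * xn + sin(phi) * yn
    pmx <- max(abs(p))
    if (pmx == 0) p else p / pmx
  }
  bg <- list(
    tmem119 = spec$background_level +
      spec$background_gradient_amplitude * bg_plane(),
    iba1 = spec$background_level +
      spec$background_gradient_amplitude * bg_plane()
  )

  vol <- array(0, dim = c(ny, nx, nz, 2))
  for (ch in 1:2) {
    for (z in seq_len(nz)) vol[, , z, ch] <- bg[[ch]]
  }
  plane_n <- ny * nx

  for (id in seq_along(cells)) {
    cell <- cells[[id]]
    span <- min(nz, max(2L, round(cell$soma_d / spec$z_step_um / 1.5)))
    z0 <- if (nz > span) sample.int(nz - span, 1L) else 1L
    zr <- z0:(z0 + span - 1L)
    lin_proc <- setdiff(cell$lin_foot, cell$lin_soma)
    for (z in zr) {
      zoff <- (z - 1L) * plane_n
      vol[cell$lin_soma + zoff] <- vol[cell$lin_soma + zoff] +
        spec$tmem_soma_mean[[cell$class]]
      if (length(lin_proc) > 0) {
        vol[lin_proc + zoff] <- vol[lin_proc + zoff] +
          spec$tmem_process_mean[[cell$class]]
      }
      ib_off <- nz * plane_n + zoff
      vol[cell$lin_foot + ib_off] <- vol[cell$lin_foot + ib_off] +
        spec$iba1_mean[[cell$class]]
    }
  }

  if (spec$psf_sigma_um > 0) {
    sig_px <- spec$psf_sigma_um / px
    for (ch in 1:2) {
      for (z in seq_len(nz)) {
        vol[, , z, ch] <- gaussian_blur_reflect(vol[, , z, ch], sig_px)
      }
    }
  }
  if (spec$poisson_scaling > 0) {
    s <- spec$poisson_scaling
    vol[] <- rpois(length(vol), pmax(vol, 0) * s) / s
  }
  if (spec$gaussian_noise_sd > 0) {
    vol[] <- vol + rnorm(length(vol), 0, spec$gaussian_noise_sd)
  }
  vol[] <- pmin(pmax(round(vol), 0), spec$bit_max)

  stack <- calibrated_stack(vol, pixel_size_um = px,
                            z_step_um = spec$z_step_um,
                            bit_max = spec$bit_max,
                            channels = c("tmem119", "iba1"))

  truth_cells <- purrr::map_dfr(seq_along(cells), function(id) {
    cell <- cells[[id]]
    mask <- matrix(FALSE, ny, nx)
    mask[cell$lin_foot] <- TRUE
    d <- shape_descriptors(mask, px)
    n_tot <- length(cell$lin_foot)
    n_soma <- length(cell$lin_soma)
    n_proc <- n_tot - n_soma
    sm <- spec$tmem_soma_mean[[cell$class]]
    pm <- spec$tmem_process_mean[[cell$class]]
    i_pix <- (cell$lin_foot - 1L) %% ny
    j_pix <- (cell$lin_foot - 1L) %/% ny
    tibble::tibble(
      cell_id = id, class = cell$class,
      centroid_x_px = mean(j_pix), centroid_y_px = mean(i_pix),
      area_um2 = d$area_um2, circularity = d$circularity,
      mean_iba1 = spec$iba1_mean[[cell$class]],
      mean_tmem_total = (n_soma * sm + n_proc * pm) / n_tot,
      mean_tmem_soma = sm,
      mean_tmem_process = if (n_proc > 0) pm else NA_real_
    )
  })

  truth <- structure(
    list(cells = truth_cells, footprint_labels = footprint_labels,
         soma_labels = soma_labels, spec = spec),
    class = "scene_truth"
  )
  structure(list(stack = stack, truth = truth), class = "iba1_scene")
}

#' Write a synthetic scene to disk
#'
#' Writes the stack as a channel-major multi-page 16-bit TIFF with a JSON
#' calibration sidecar, the truth footprint and soma label images as 16-bit
#' TIFFs, and the truth table as CSV. The result round-trips losslessly
#' through [read_stack()] / [read_scene_truth()].
#'
#' @param scene result of [render_scene()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_scene <- function(scene, out_dir) {
  stopifnot(inherits(scene, "iba1_scene"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  stack <- scene$stack
  d <- dim(stack$data)
  pages <- list()
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- stack$data[, , z, ch]
    }
  }
  paths <- c(
    stack = file.path(out_dir, "scene.tif"),
    sidecar = file.path(out_dir, "scene.json"),
    footprint = file.path(out_dir, "truth_footprint.tif"),
    soma = file.path(out_dir, "truth_soma.tif"),
    truth = file.path(out_dir, "truth.csv")
  )
  write_tiff_pages(pages, paths[["stack"]])
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
         bit_max = stack$bit_max, n_channels = d[4], n_z = d[3],
         channels = stack$channels, channel_order = "channel-major"),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA
  )
  write_tiff_pages(list(scene$truth$footprint_labels), paths[["footprint"]])
  write_tiff_pages(list(scene$truth$soma_labels), paths[["soma"]])
  truth_out <- scene$truth$cells
  num <- vapply(truth_out, is.numeric, logical(1))
  truth_out[num] <- lapply(truth_out[num], function(x) signif(x, 6))
  write.csv(truth_out, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read scene ground truth written by [write_scene()]
#'
#' @param dir directory containing `truth_footprint.tif`, `truth_soma.tif`
#'   and `truth.csv`.
#' @param pixel_size_um calibration of the label images.
#' @return A `scene_truth` object (without the generating spec).
#' @export
read_scene_truth <- function(dir, pixel_size_um) {
  fp <- round(tiff::readTIFF(file.path(dir, "truth_footprint.tif")) * 65535)
  sm <- round(tiff::readTIFF(file.path(dir, "truth_soma.tif")) * 65535)
  cells <- tibble::as_tibble(read.csv(file.path(dir, "truth.csv"),
                                      stringsAsFactors = FALSE))
  structure(
    list(cells = cells, footprint_labels = fp, soma_labels = sm,
         spec = NULL, pixel_size_um = pixel_size_um),
    class = "scene_truth"
  )
}
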