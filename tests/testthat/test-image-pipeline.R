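test_that("max projection equals the per-pixel maximum over z", {
  set.seed(1)
  arr <- array(sample(0:4096, 16 * 16 * 5 * 2, replace = TRUE),
               dim = c(16, 16, 5, 2))
  st <- calibrated_stack(arr, pixel_size_um = 0.2)
  proj <- max_project(st)
  brute <- apply(arr[, , , 1], c(1, 2), max)
  expect_equal(unname(proj$tmem119[, ]), brute, ignore_attr = TRUE)
  # single slice is the identity, all-zero stays all-zero
  st1 <- calibrated_stack(arr[, , 1, , drop = FALSE], pixel_size_um = 0.2)
  expect_equal(as.numeric(max_project(st1)$iba1), as.numeric(arr[, , 1, 2]))
  z <- calibrated_stack(array(0, c(4, 4, 3, 2)), pixel_size_um = 0.2)
  expect_true(all(max_project(z)$tmem119 == 0))
})

test_that("rolling-ball subtraction matches the brute-force opening oracle", {
  set.seed(2)
  toy <- matrix(round(runif(64 * 64, 0, 500)), 64, 64)
  for (r in c(3, 6)) {
    expect_equal(subtract_background_rolling(toy, r),
                 oracle_ball_subtract(toy, r), tolerance = 1e-12)
  }
  expect_true(all(subtract_background_rolling(matrix(100, 32, 32), 8) == 0))
})

test_that("rolling ball preserves small bright spots and flattens ramps", {
  img <- matrix(100, 64, 64)
  img[30:34, 30:34] <- 600
  out <- subtract_background_rolling(img, 10)
  expect_gt(max(out), 0.95 * 500)
  expect_lt(max(out[1:15, 1:15]), 1)
  # linear ramp: residual bounded by the ramp change across one ball diameter
  ramp <- matrix(rep(seq(0, 63), each = 64), 64, 64)
  res <- subtract_background_rolling(ramp, 5)
  expect_lt(max(res), 10 + 1)
  # second subtraction changes a background-only image by under one gray level
  bg <- matrix(50, 64, 64) + outer(seq(0, 5, length = 64),
                                   seq(0, 3, length = 64), "+")
  once <- subtract_background_rolling(bg, 10)
  expect_lt(max(abs(once - subtract_background_rolling(once, 10))), 1)
  expect_error(subtract_background_rolling(matrix(0, 10, 10), 20), "larger")
})

test_that("mean smoothing has exact impulse response and is linear", {
  imp <- matrix(0, 11, 11)
  imp[6, 6] <- 9
  sm <- smooth_mean(imp, 3)
  expect_equal(sm[5:7, 5:7], matrix(1, 3, 3), tolerance = 1e-9)
  expect_lt(max(abs(sm[-(5:7), ])), 1e-9)
  cst <- matrix(7, 20, 20)
  expect_equal(smooth_mean(cst, 3), cst, tolerance = 1e-9)
  set.seed(3)
  m <- matrix(runif(400), 20, 20)
  expect_equal(smooth_mean(3 * m, 3), 3 * smooth_mean(m, 3),
               tolerance = 1e-9)
})

test_that("unsharp mask keeps constants, approaches identity, sharpens edges", {
  cst <- matrix(42, 20, 20)
  expect_equal(unsharp_mask(cst, 2, 0.6), cst, tolerance = 1e-9)
  set.seed(4)
  m <- matrix(runif(400, 0, 100), 20, 20)
  expect_equal(unsharp_mask(m, 2, 1e-9), m, tolerance = 1e-5)
  # step edge overshoots above the high plateau
  step <- matrix(100, 20, 40)
  step[, 21:40] <- 500
  out <- unsharp_mask(step, 2, 0.6)
  expect_gt(max(out), 500)
  expect_lt(min(out[, 1:10]), 100 + 1e-6)
})

test_that("segmentation respects the threshold, connectivity and filters", {
  img <- matrix(0, 30, 30)
  img[5:10, 5:10] <- 800
  img[20:25, 20:25] <- 800
  img[11, 11] <- 800 # diagonal bridge pixel between nothing; single pixel
  cfg8 <- pipeline_config(threshold_gray = 500, connectivity = 8,
                          min_area_um2 = 0, exclude_border = FALSE)
  lab <- segment_cells(img, cfg8, 1)
  expect_true(all(img[lab > 0] >= 500))
  # empty result is not an error
  cfg_hi <- pipeline_config(threshold_gray = 1000, min_area_um2 = 0,
                            exclude_border = FALSE)
  expect_equal(max(segment_cells(img, cfg_hi, 1)), 0)

  # two squares joined by a 1-px diagonal bridge
  br <- matrix(0, 20, 20)
  br[3:8, 3:8] <- 900
  br[9, 9] <- 900
  br[10:15, 10:15] <- 900
  cfg4 <- pipeline_config(threshold_gray = 500, connectivity = 4,
                          min_area_um2 = 0, exclude_border = FALSE)
  expect_equal(max(segment_cells(br, cfg8, 1)), 1)
  expect_equal(max(segment_cells(br, cfg4, 1)), 3)
  # agreement with the flood-fill oracle
  expect_equal(max(segment_cells(br, cfg8, 1)),
               max(oracle_components(br >= 500, 8)))
  expect_equal(max(segment_cells(br, cfg4, 1)),
               max(oracle_components(br >= 500, 4)))

  # min-area filter and border exclusion
  cfg_min <- pipeline_config(threshold_gray = 500, min_area_um2 = 10,
                             exclude_border = FALSE)
  expect_equal(max(segment_cells(img, cfg_min, 1)), 2)
  bord <- matrix(0, 20, 20)
  bord[1:5, 8:12] <- 900
  bord[10:14, 8:12] <- 900
  cfg_b <- pipeline_config(threshold_gray = 500, min_area_um2 = 0,
                           exclude_border = TRUE)
  expect_equal(max(segment_cells(bord, cfg_b, 1)), 1)
})

test_that("segmentation recovers noiseless painted footprints exactly", {
  sc <- scene_noiseless()
  proj <- max_project(sc$stack)
  cfg <- pipeline_config(threshold_gray = 600, min_area_um2 = 0,
                         exclude_border = FALSE)
  # threshold applied between background (0) and painted level (1200)
  lab <- segment_cells(proj$iba1, cfg, sc$stack$pixel_size_um)
  tru <- sc$truth$footprint_labels
  expect_equal(max(lab), max(tru))
  for (id in seq_len(max(tru))) {
    tm <- tru == id
    sid <- unique(lab[tm])
    expect_length(sid, 1)
    expect_identical(unname(lab == sid), unname(tm))
  }
})

test_that("suggested thresholds are image quantiles", {
  cst <- matrix(5, 10, 10)
  expect_equal(suggest_threshold(cst, 0.99), 5)
  set.seed(6)
  m <- matrix(runif(100), 10, 10)
  expect_equal(suggest_threshold(m, 1), max(m))
  v <- sort(as.numeric(m))
  q <- 0.37
  h <- (length(v) - 1) * q
  expect_equal(suggest_threshold(m, q),
               v[floor(h) + 1] + (h - floor(h)) *
                 (v[floor(h) + 2] - v[floor(h) + 1]))
})

test_that("the preprocessing chain is deterministic end to end", {
  sc <- scene_small()
  cfg <- test_config()
  a <- segment_cells(preprocess_iba1(max_project(sc$stack)$iba1, cfg), cfg,
                     sc$stack$pixel_size_um)
  b <- segment_cells(preprocess_iba1(max_project(sc$stack)$iba1, cfg), cfg,
                     sc$stack$pixel_size_um)
  expect_identical(unclass(a), unclass(b))
})
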