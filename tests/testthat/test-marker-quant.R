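test_that("masked means equal the explicit-loop oracle", {
  set.seed(20)
  for (rep in seq_len(20)) {
    img <- matrix(runif(32 * 32, 0, 4096), 32, 32)
    mask <- matrix(runif(32 * 32) < 0.3, 32, 32)
    if (!any(mask)) mask[1, 1] <- TRUE
    acc <- 0
    n <- 0
    for (i in 1:32) {
      for (j in 1:32) {
        if (mask[i, j]) {
          acc <- acc + img[i, j]
          n <- n + 1
        }
      }
    }
    expect_identical(mean_in_mask(img, mask), acc / n)
  }
  expect_equal(mean_in_mask(matrix(7, 5, 5), matrix(TRUE, 5, 5)), 7)
  chk <- matrix(c(0, 10), 8, 8)
  expect_equal(mean_in_mask(chk, matrix(TRUE, 8, 8)), 5)
  expect_error(mean_in_mask(chk, matrix(FALSE, 8, 8)), "empty")
  expect_error(mean_in_mask(chk, matrix(TRUE, 4, 4)), "differ")
})

test_that("soma opening keeps discs and erases thin lines", {
  px <- 0.2
  disk <- disk_mask(10 / px) # 10 um radius disk
  sm <- soma_mask(disk, px, 2)
  expect_true(all(disk[sm])) # subset
  expect_gte(sum(sm & disk) / sum(sm | disk), 0.99)
  expect_false(attr(sm, "empty"))

  line <- matrix(FALSE, 20, 100)
  line[10, ] <- TRUE
  sm2 <- soma_mask(line, px, 2)
  expect_true(attr(sm2, "empty"))
  expect_equal(sum(sm2), 0)
  expect_error(soma_mask(matrix(FALSE, 5, 5), px), "empty")
})

test_that("soma recovery on generator truth is accurate", {
  set.seed(30)
  jac <- vapply(seq_len(15), function(i) {
    s <- make_cell_shape("ramified", 0.2)
    sm <- soma_mask(s$footprint, 0.2, 2)
    sum(sm & s$soma) / sum(sm | s$soma)
  }, numeric(1))
  expect_true(all(jac >= 0.8))
})

test_that("intensity decomposition is exact and pixel-weight consistent", {
  px <- 0.2
  s <- make_cell_shape("ramified", px, seed = 31)
  # uniform channel: all means equal, literal difference zero
  uni <- matrix(13, nrow(s$footprint), ncol(s$footprint))
  d <- decompose_intensity(s$footprint, uni, px)
  expect_equal(d$mean_total, 13)
  expect_equal(d$mean_soma, 13)
  expect_equal(d$mean_ramification, 13)
  expect_equal(d$ramification_literal, 0)

  # painted soma/process levels recovered exactly in the noiseless case
  sm <- soma_mask(s$footprint, px, 2)
  img <- matrix(0, nrow(s$footprint), ncol(s$footprint))
  img[sm] <- 50
  img[s$footprint & !sm] <- 250
  d2 <- decompose_intensity(s$footprint, img, px)
  expect_identical(d2$mean_soma, 50)
  expect_identical(d2$mean_ramification, 250)
  expect_equal(d2$ramification_literal, d2$mean_total - 50)
  expect_equal(d2$n_pixels_soma + d2$n_pixels_ramification, d2$n_pixels_total)
  expect_equal(
    d2$n_pixels_soma * d2$mean_soma +
      d2$n_pixels_ramification * d2$mean_ramification,
    d2$n_pixels_total * d2$mean_total
  )
  expect_equal(d2$mean_total, mean(img[s$footprint]))

  # noisy 3:1 process:soma contrast is recovered in >= 95% of cells
  set.seed(32)
  wins <- vapply(seq_len(50), function(i) {
    s <- make_cell_shape("ramified", px)
    img <- matrix(0, nrow(s$footprint), ncol(s$footprint))
    img[s$soma] <- 100
    img[s$process] <- 300
    img <- img + matrix(rnorm(length(img), 0, 40), nrow(img))
    d <- decompose_intensity(s$footprint, img, px)
    d$mean_ramification > d$mean_soma
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("empty-soma cells report missing soma fields", {
  line <- matrix(FALSE, 20, 100)
  line[10, ] <- TRUE
  img <- matrix(5, 20, 100)
  d <- decompose_intensity(line, img, 0.2)
  expect_true(d$soma_empty)
  expect_true(is.na(d$mean_soma))
  expect_true(is.na(d$ramification_literal))
  expect_equal(d$n_pixels_soma, 0L)
  expect_equal(d$mean_total, 5)
})

test_that("ROI restriction by centroid tiles the scene without double counting", {
  sc <- scene_small()
  cfg <- test_config()
  proj <- max_project(sc$stack)
  marker <- preprocess_marker(proj$tmem119, cfg)
  labels <- segment_cells(preprocess_iba1(proj$iba1, cfg), cfg,
                          sc$stack$pixel_size_um)
  all_rec <- cell_records(labels, marker, cfg, sc$stack$pixel_size_um)

  whole <- roi_spec("whole", 0, 0, 105, 105)
  rec_whole <- quantify_roi(labels, marker, whole, cfg)
  expect_equal(nrow(rec_whole), nrow(all_rec))

  none <- roi_spec("none", 300, 300, 50, 50)
  rec_none <- quantify_roi(labels, marker, none, cfg)
  expect_equal(nrow(rec_none), 0)
  expect_true(all(c("roi", "cell_id", "class") %in% names(rec_none)))

  left <- roi_spec("left", 0, 0, 52.5, 105)
  right <- roi_spec("right", 52.5, 0, 52.5, 105)
  rec_l <- quantify_roi(labels, marker, left, cfg)
  rec_r <- quantify_roi(labels, marker, right, cfg)
  expect_equal(nrow(rec_l) + nrow(rec_r), nrow(all_rec))
  expect_setequal(c(rec_l$cell_id, rec_r$cell_id), all_rec$cell_id)
})

test_that("standard lesion windows sit at the stated offsets", {
  rois <- lesion_rois(anchor_um = c(100, 500), direction = c(1, 0))
  expect_equal(vapply(rois, function(r) r$name, character(1)),
               c("edge", "intermediate", "distance"))
  expect_equal(vapply(rois, function(r) r$x_um, numeric(1)),
               c(100, 450, 800))
  expect_true(all(vapply(rois, function(r) r$y_um, numeric(1)) == 500 - 105))
  expect_error(lesion_rois(direction = c(1, 1)), "axis-aligned")
})
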