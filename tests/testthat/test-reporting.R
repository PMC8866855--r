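test_that("sample size follows the two-group normal-approximation formula", {
  # z_{0.975} + z_{0.8} = 1.95996 + 0.84162, squared ~ 7.849
  expect_equal(sample_size(1, 1)$f, (1.95996 + 0.84162)^2, tolerance = 1e-4)
  expect_equal(sample_size(1, 1)$n, 15.698, tolerance = 1e-3)
  expect_equal(sample_size(18.42, 42)$n, 3.02, tolerance = 1e-2)
  expect_equal(sample_size(18.42, 42)$n_ceiling, 4)
  # detecting an enormous difference needs (almost) no animals
  expect_lt(sample_size(1, 1e6)$n, 1e-6)
  # explicit f override
  expect_equal(sample_size(2, 4, f = 10)$n, 2 * 4 * 10 / 16)
  expect_error(sample_size(-1, 1), "sigma")
})

test_that("group summaries report textbook moments and quartiles", {
  rec <- tibble::tibble(
    roi = "all", class = "ramified",
    area_um2 = c(10, 20), circularity = c(0.1, 0.3),
    mean_tmem_total = c(5, 15)
  )
  s <- summarize_cells(rec, roi, class)
  expect_equal(unique(s$n), 2L)
  expect_equal(s$mean[s$variable == "area_um2"], 15)
  expect_equal(s$sd[s$variable == "area_um2"], sqrt((25 + 25) / 1))

  one <- summarize_cells(rec[1, ], roi, class)
  expect_equal(one$sd, rep(0, 3))
  expect_equal(one$mean[one$variable == "circularity"], 0.1)

  set.seed(60)
  x <- round(runif(10, 0, 100))
  rec10 <- tibble::tibble(roi = "all", class = "ameboid", area_um2 = x,
                          circularity = 0.5, mean_tmem_total = 1)
  s10 <- summarize_cells(rec10, roi, class)
  m <- sum(x) / 10
  expect_equal(s10$mean[s10$variable == "area_um2"], m)
  expect_equal(s10$sd[s10$variable == "area_um2"],
               sqrt(sum((x - m)^2) / 9))
  expect_equal(s10$median[s10$variable == "area_um2"],
               median(x))
})

test_that("the pipeline recovers noiseless scenes exactly and is rerunnable", {
  sc <- scene_noiseless()
  cfg <- pipeline_config(threshold_gray = 500)
  run <- run_pipeline(sc$stack, cfg)
  expect_equal(nrow(run$records), nrow(sc$truth$cells))
  got <- table(as.character(run$records$class))
  want <- table(as.character(sc$truth$cells$class))
  expect_equal(got[names(want)], want)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(sc$stack, cfg, out_dir = d1)
  run_pipeline(sc$stack, cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))
  expect_identical(readLines(file.path(d1, "groups.csv")),
                   readLines(file.path(d2, "groups.csv")))
  log <- jsonlite::read_json(file.path(d1, "run_log.json"))
  expect_equal(log$n_cells, nrow(run$records))
  expect_equal(log$config$threshold_gray, 500)
})

test_that("ROI-restricted runs produce well-formed (possibly empty) tables", {
  sc <- scene_noiseless()
  cfg <- pipeline_config(threshold_gray = 500)
  empty_roi <- roi_spec("nothing", 400, 400, 20, 20)
  run <- run_pipeline(sc$stack, cfg, rois = list(empty_roi))
  expect_equal(nrow(run$records), 0)
  expect_true(all(c("roi", "class", "mean_tmem_total") %in%
                    names(run$records)))
  expect_equal(nrow(run$summaries), 0)
})

test_that("evaluation matches truth-measured records on the diagonal", {
  sc <- scene_noiseless()
  cfg <- pipeline_config(threshold_gray = 500)
  run <- run_pipeline(sc$stack, cfg)
  ev <- evaluate_run(run, sc$truth)
  expect_equal(ev$n_matched, nrow(sc$truth$cells))
  expect_equal(ev$n_missed, 0)
  expect_equal(ev$n_spurious, 0)
  expect_equal(sum(diag(ev$confusion)), ev$n_matched)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.integer(table(factor(sc$truth$cells$class,
                 levels = c("ramified", "hypertrophic", "ameboid"))))))
  expect_gt(ev$mean_jaccard, 0.8)

  # permuting truth class labels moves exactly those cells off-diagonal
  perm_truth <- sc$truth
  k <- 4
  idx <- seq_len(k)
  relabel <- c(ramified = "ameboid", hypertrophic = "ramified",
               ameboid = "hypertrophic")
  perm_truth$cells$class[idx] <- relabel[perm_truth$cells$class[idx]]
  ev2 <- evaluate_run(run, perm_truth)
  expect_equal(sum(ev2$confusion) - sum(diag(ev2$confusion)), k)

  # disjoint truth: everything missed and spurious
  off_truth <- sc$truth
  off_truth$footprint_labels <- matrix(
    0L, nrow(sc$truth$footprint_labels), ncol(sc$truth$footprint_labels)
  )
  off_truth$footprint_labels[1:5, 1:5] <- 1L
  off_truth$cells <- sc$truth$cells[1, ]
  ev3 <- evaluate_run(run, off_truth)
  expect_equal(ev3$n_matched, 0)
  expect_equal(ev3$n_missed, 1)
  expect_equal(ev3$n_spurious, nrow(run$records))
})

test_that("segmentation recovers most cells with good overlap under noise", {
  sc <- scene_default() # 60 cells, default noise model
  run <- run_pipeline(sc$stack, test_config())
  ev <- evaluate_run(run, sc$truth, jaccard_floor = 0.3)
  good <- sum(ev$matches$jaccard >= 0.6)
  expect_gte(good / nrow(sc$truth$cells), 0.9)
  expect_lte(ev$n_spurious, 3)
})
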