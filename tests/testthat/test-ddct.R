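make_ct <- function(goi_treated, goi_control,
                    refs = list(a = 20, b = 21, c = 22)) {
  rows <- list()
  add <- function(sample, group, gene, role, ct) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_id = sample, group = group, gene = gene, role = role, ct = ct
    )
  }
  for (i in seq_along(goi_treated)) {
    s <- paste0("t", i)
    add(s, "treated", "goi", "GOI", goi_treated[i])
    for (g in names(refs)) add(s, "treated", g, "reference", refs[[g]])
  }
  for (i in seq_along(goi_control)) {
    s <- paste0("c", i)
    add(s, "control", "goi", "GOI", goi_control[i])
    for (g in names(refs)) add(s, "control", g, "reference", refs[[g]])
  }
  dplyr::bind_rows(rows)
}

test_that("reference CT is the mean of the reference genes", {
  tab <- make_ct(25, 25)
  expect_equal(reference_ct(tab)$ct_ref, c(21, 21))
  tab2 <- make_ct(25, 25, refs = list(a = 18.5, b = 19.5, c = 23.0))
  expect_equal(unique(reference_ct(tab2)$ct_ref), (18.5 + 19.5 + 23.0) / 3)
  tab3 <- make_ct(25, 25, refs = list(only = 20.5))
  expect_equal(unique(reference_ct(tab3)$ct_ref), 20.5)
})

test_that("delta-CT follows the reference-minus-gene sign convention", {
  d <- delta_ct(make_ct(25, 25))
  expect_equal(unique(d$dct), 21 - 25)
  d2 <- delta_ct(make_ct(21, 18))
  expect_equal(d2$dct[d2$group == "treated"], 0)
  expect_equal(d2$dct[d2$group == "control"], 3)
})

test_that("fold changes reproduce the classic 2^ddct identities", {
  # treated identical to control: every fold is 1
  f0 <- fold_changes(make_ct(c(25, 25), c(25, 25)))
  expect_equal(tidy(f0)$fold_change, rep(1, 4))
  expect_equal(glance(f0)$fold_change_group, 1)

  # one cycle earlier amplification = ddct +1 = fold 2 at E = 2
  f1 <- fold_changes(make_ct(24, 25))
  expect_equal(tidy(f1)$fold_change[tidy(f1)$group == "treated"], 2)
  f2 <- fold_changes(make_ct(26, 25))
  expect_equal(tidy(f2)$fold_change[tidy(f2)$group == "treated"], 0.5)

  # continuous efficiency: fold = E^ddct
  f3 <- fold_changes(make_ct(24, 25), efficiency = 1.957)
  expect_equal(tidy(f3)$fold_change[tidy(f3)$group == "treated"], 1.957)
})

test_that("swapping treated and control inverts the group fold exactly", {
  set.seed(50)
  for (rep in 1:5) {
    tab <- make_ct(25 + rnorm(4, 0, 2), 25 + rnorm(3, 0, 2))
    swapped <- dplyr::mutate(
      tab,
      group = ifelse(.data$group == "treated", "control", "treated")
    )
    f <- glance(fold_changes(tab))$fold_change_group
    fs <- glance(fold_changes(swapped))$fold_change_group
    expect_equal(f * fs, 1)
    # geometric mean of per-sample folds equals the group fold
    trt <- dplyr::filter(tidy(fold_changes(tab)), group == "treated")
    expect_equal(exp(mean(log(trt$fold_change))), f)
  }
})

test_that("shifting one reference gene uniformly leaves ddct unchanged", {
  set.seed(51)
  tab <- make_ct(25 + rnorm(3), 24 + rnorm(3))
  shifted <- dplyr::mutate(
    tab, ct = .data$ct + ifelse(.data$gene == "a", 1.5, 0)
  )
  f <- fold_changes(tab)
  fs <- fold_changes(shifted)
  expect_equal(reference_ct(shifted)$ct_ref,
               reference_ct(tab)$ct_ref + 1.5 / 3)
  expect_equal(tidy(fs)$ddct, tidy(f)$ddct)
  expect_equal(tidy(fs)$fold_change, tidy(f)$fold_change)
})

test_that("replicates are averaged and bad tables are rejected", {
  tab <- make_ct(25, 25)
  reps <- dplyr::bind_rows(
    tab,
    dplyr::mutate(dplyr::filter(tab, .data$role == "GOI",
                                .data$group == "treated"),
                  ct = .data$ct + 2)
  )
  d <- delta_ct(reps)
  expect_equal(d$ct_goi[d$group == "treated"], 26)

  no_ctrl <- dplyr::filter(tab, .data$group == "treated")
  expect_error(fold_changes(no_ctrl), "control")
  missing_goi <- dplyr::bind_rows(
    tab,
    tibble::tibble(sample_id = "t9", group = "treated", gene = "a",
                   role = "reference", ct = 21)
  )
  expect_warning(fold_changes(missing_goi), "t9")
  expect_error(fold_changes(dplyr::mutate(tab, role = "target")), "role")
  expect_error(fold_changes(tab, efficiency = 1), "efficiency")
})

test_that("simulated CT tables recover their programmed fold change", {
  tab <- simulate_ct_table(true_fold = 4.36, noise_sd = 0, seed = 2)
  f <- glance(fold_changes(tab))
  expect_equal(f$fold_change_group, 4.36, tolerance = 1e-10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  expect_equal(glance(fold_changes(read_ct_table(csv)))$fold_change_group,
               f$fold_change_group)
  out_csv <- withr::local_tempfile(fileext = ".csv")
  out <- write_fold_changes(fold_changes(tab), out_csv)
  expect_equal(nrow(out), 4)
  expect_named(out, c("sample_id", "ct_ref", "dct", "ddct", "fold_change"))
})
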