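#' Run the full per-cell quantification pipeline on a stack
#'
#' End-to-end chain: maximum-intensity projection and channel split; Iba1
#' channel preprocessing (rolling-ball 50 px, mean smoothing, unsharp mask)
#' and constant-threshold segmentation; marker channel rolling-ball 20 px
#' subtraction; per-cell morphometry, classification and marker intensity
#' decomposition; group summaries. Deterministic: the same stack and config
#' always produce identical tables.
#'
#' @param stack a [calibrated_stack()] with `tmem119` and `iba1` channels.
#' @param config a [pipeline_config()].
#' @param rois optional list of [roi_spec()]; when given, only cells whose
#'   centroid falls in a window are kept and tagged with its name.
#' @param out_dir optional directory; when given, writes `cells.csv`,
#'   `groups.csv` and `run_log.json`.
#' @param run_meta optional named list merged into the run log (e.g. the
#'   scene seed).
#' @return Object of class `iba1_run`: `records` (per-cell tibble),
#'   `summaries` (group summary tibble), `labels` (segmentation
#'   `label_mask`), `images` (preprocessed projections) and `config`.
#' @export
run_pipeline <- function(stack, config, rois = NULL, out_dir = NULL,
                         run_meta = list()) {
  stopifnot(inherits(stack, "calibrated_stack"),
            inherits(config, "pipeline_config"))
  if (!all(c("tmem119", "iba1") %in% stack$channels)) {
    stop("stack must contain 'tmem119' and 'iba1' channels")
  }
  proj <- max_project(stack)
  iba_img <- preprocess_iba1(proj$iba1, config)
  marker_img <- preprocess_marker(proj$tmem119, config)
  labels <- segment_cells(iba_img, config, stack$pixel_size_um)
  if (is.null(rois)) {
    records <- cell_records(labels, marker_img, config, stack$pixel_size_um)
    records <- dplyr::mutate(records, roi = "all", .before = 1)
  } else {
    records <- purrr::map_dfr(rois, function(roi) {
      quantify_roi(labels, marker_img, roi, config, stack$pixel_size_um)
    })
  }
  summaries <- summarize_cells(records, roi, class)
  run <- structure(
    list(records = records, summaries = summaries, labels = labels,
         images = list(iba1 = iba_img, tmem119 = marker_img),
         config = config, run_meta = run_meta),
    class = "iba1_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.iba1_run <- function(x, ...) {
  cat(sprintf("<iba1_run> %d cells segmented\n", nrow(x$records)))
  print(population_fractions_safe(x$records))
  invisible(x)
}

population_fractions_safe <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(class = character(), n = integer(),
                          percent = numeric()))
  }
  population_fractions(records)
}

# cells.csv column order is fixed and documented
cells_csv_columns <- c(
  "cell_id", "roi", "area_um2", "perimeter_um", "circularity", "class",
  "infiltrated_flag", "mean_tmem_total", "mean_tmem_soma",
  "mean_tmem_ramification", "ramification_literal"
)

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dplyr::mutate(
    run$records,
    class = as.character(.data$class),
    infiltrated_flag = .data$putative_infiltrated
  )
  cells <- cells[, cells_csv_columns, drop = FALSE]
  num <- vapply(cells, is.numeric, logical(1))
  cells[num] <- lapply(cells[num], function(x) signif(x, 6))
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  groups <- run$summaries
  num <- vapply(groups, is.numeric, logical(1))
  groups[num] <- lapply(groups[num], function(x) signif(x, 6))
  groups$class <- as.character(groups$class)
  write.csv(groups, file.path(out_dir, "groups.csv"), row.names = FALSE)
  log <- list(
    package = "iba1quant",
    version = as.character(utils::packageVersion("iba1quant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(run$config),
    n_cells = nrow(run$records),
    counts = as.list(table(as.character(run$records$class))),
    meta = run$run_meta
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate a scene and quantify it in one call
#'
#' Renders a synthetic scene from `spec` and runs the full pipeline on it.
#' The run log records the scene seed and spec, so a run can be reproduced
#' bit-identically from its log.
#'
#' @param spec a [scene_spec()].
#' @param config a [pipeline_config()].
#' @param rois,out_dir passed to [run_pipeline()].
#' @return List with elements `scene` (the `iba1_scene`) and `run`
#'   (the `iba1_run`).
#' @export
simulate_and_run <- function(spec, config, rois = NULL, out_dir = NULL) {
  scene <- render_scene(spec)
  meta <- list(seed = spec$seed,
               spec = unclass(spec))
  run <- run_pipeline(scene$stack, config, rois = rois, out_dir = out_dir,
                      run_meta = meta)
  list(scene = scene, run = run)
}

#' Group summaries of per-cell records
#'
#' Summarizes selected per-cell variables within groups: n, mean, SD,
#' median and quartiles (the "line at median and quartiles" layout of the
#' violin-plot figures).
#'
#' @param records per-cell tibble (e.g. from [run_pipeline()]).
#' @param ... grouping columns (tidy evaluation), e.g. `roi, class`.
#' @param .vars character vector of numeric columns to summarize.
#' @return Long tibble: grouping keys, `variable`, `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_cells <- function(records, ...,
                            .vars = c("area_um2", "circularity",
                                      "mean_tmem_total")) {
  .vars <- intersect(.vars, names(records))
  long <- tidyr::pivot_longer(
    dplyr::select(records, dplyr::all_of(.vars), ...),
    cols = dplyr::all_of(.vars),
    names_to = "variable", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, ..., .data$variable),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) sd(.data$value) else 0,
    median = median(.data$value),
    q25 = unname(quantile(.data$value, 0.25)),
    q75 = unname(quantile(.data$value, 0.75)),
    .groups = "drop"
  )
}

#' Pre-hoc group size from the two-group normal approximation
#'
#' `n = 2 * sigma^2 * f(alpha, beta) / delta^2` with
#' `f = (z_{1 - alpha/2} + z_{1 - beta})^2`. The factor `f` can be
#' overridden to reproduce alternative conventions.
#'
#' @param sigma common group standard deviation (> 0).
#' @param delta difference between groups to detect (> 0, same units).
#' @param alpha two-sided type I error rate.
#' @param beta type II error rate (power = 1 - beta).
#' @param f optional explicit `f(alpha, beta)` factor.
#' @return One-row tibble: `n` (unrounded), `n_ceiling`, `f`.
#' @export
sample_size <- function(sigma, delta, alpha = 0.05, beta = 0.2, f = NULL) {
  stopifnot(sigma > 0, delta > 0, alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (is.null(f)) f <- (qnorm(1 - alpha / 2) + qnorm(1 - beta))^2
  n <- 2 * sigma^2 * f / delta^2
  tibble::tibble(n = n, n_ceiling = ceiling(n), f = f)
}

#' Evaluate a pipeline run against scene ground truth
#'
#' Matches segmented cells to truth cells one-to-one by greedy maximal
#' Jaccard overlap (floor 0.3), then reports the truth-by-assigned confusion
#' matrix, per-class population-fraction errors, per-cell marker intensity
#' recovery errors on matched pairs, and segmentation match statistics.
#'
#' @param run an `iba1_run` produced without ROI filtering.
#' @param truth a `scene_truth` (from [render_scene()] or
#'   [read_scene_truth()]).
#' @param jaccard_floor minimum Jaccard index for a valid match.
#' @return Object of class `iba1_eval` with elements `confusion` (3 x 3
#'   matrix, rows = truth), `matches` (per-pair tibble), `fraction_error`
#'   (per-class tibble, percentage points), `n_matched`, `n_missed`,
#'   `n_spurious`, `mean_jaccard`.
#' @export
evaluate_run <- function(run, truth, jaccard_floor = 0.3) {
  stopifnot(inherits(run, "iba1_run"))
  seg <- unclass(run$labels)
  tru <- truth$footprint_labels
  stopifnot(all(dim(seg) == dim(tru)))
  classes <- c("ramified", "hypertrophic", "ameboid")
  n_tru <- max(tru)
  n_seg <- max(seg)
  both <- tru > 0 & seg > 0
  matches <- tibble::tibble(truth_id = integer(), seg_id = integer(),
                            jaccard = numeric())
  if (any(both) && n_seg > 0) {
    key <- (tru[both] - 1) * (n_seg + 1) + seg[both]
    ov <- table(key)
    kv <- as.numeric(names(ov))
    t_id <- kv %/% (n_seg + 1) + 1
    s_id <- kv %% (n_seg + 1)
    a_tru <- tabulate(tru[tru > 0], nbins = n_tru)
    a_seg <- tabulate(seg[seg > 0], nbins = n_seg)
    inter <- as.numeric(ov)
    jac <- inter / (a_tru[t_id] + a_seg[s_id] - inter)
    ord <- order(jac, decreasing = TRUE)
    used_t <- logical(n_tru)
    used_s <- logical(n_seg)
    rows <- list()
    for (i in ord) {
      if (jac[i] < jaccard_floor) break
      if (used_t[t_id[i]] || used_s[s_id[i]]) next
      used_t[t_id[i]] <- TRUE
      used_s[s_id[i]] <- TRUE
      rows[[length(rows) + 1L]] <- tibble::tibble(
        truth_id = as.integer(t_id[i]), seg_id = as.integer(s_id[i]),
        jaccard = jac[i]
      )
    }
    if (length(rows) > 0) matches <- dplyr::bind_rows(rows)
  }

  truth_class <- factor(truth$cells$class, levels = classes)
  confusion <- matrix(0L, 3, 3, dimnames = list(truth = classes,
                                                assigned = classes))
  if (nrow(matches) > 0) {
    rec <- run$records
    assigned <- as.character(rec$class[match(matches$seg_id, rec$cell_id)])
    tcl <- as.character(truth_class[matches$truth_id])
    for (i in seq_len(nrow(matches))) {
      confusion[tcl[i], assigned[i]] <- confusion[tcl[i], assigned[i]] + 1L
    }
    measured <- rec$mean_tmem_total[match(matches$seg_id, rec$cell_id)]
    truth_int <- truth$cells$mean_tmem_total[matches$truth_id]
    matches$truth_class <- tcl
    matches$assigned_class <- assigned
    matches$intensity_rel_error <- (measured - truth_int) / truth_int
  }

  est <- if (nrow(run$records) > 0) {
    population_fractions(run$records)
  } else {
    tibble::tibble(class = factor(classes, levels = classes),
                   n = 0L, percent = NA_real_)
  }
  tru_frac <- population_fractions(truth$cells)
  fraction_error <- tibble::tibble(
    class = tru_frac$class,
    truth_percent = tru_frac$percent,
    estimated_percent = est$percent[match(tru_frac$class, est$class)],
    error_pp = est$percent[match(tru_frac$class, est$class)] -
      tru_frac$percent
  )

  structure(
    list(confusion = confusion, matches = matches,
         fraction_error = fraction_error,
         n_matched = nrow(matches),
         n_missed = n_tru - nrow(matches),
         n_spurious = n_seg - nrow(matches),
         mean_jaccard = if (nrow(matches) > 0) mean(matches$jaccard)
                        else NA_real_),
    class = "iba1_eval"
  )
}

#' @export
print.iba1_eval <- function(x, ...) {
  cat(sprintf(
    "<iba1_eval> matched %d, missed %d, spurious %d; mean Jaccard %.3f\n",
    x$n_matched, x$n_missed, x$n_spurious, x$mean_jaccard
  ))
  print(x$confusion)
  invisible(x)
}

#' @describeIn evaluate_run Per-matched-pair tidy table.
#' @param x an `iba1_eval`.
#' @param ... unused.
#' @export
tidy.iba1_eval <- function(x, ...) {
  x$matches
}

#' @describeIn evaluate_run One-row summary (match counts, mean Jaccard,
#'   classification accuracy on matched pairs, mean absolute intensity
#'   relative error, max absolute fraction error).
#' @export
glance.iba1_eval <- function(x, ...) {
  acc <- if (x$n_matched > 0) sum(diag(x$confusion)) / x$n_matched
         else NA_real_
  tibble::tibble(
    n_matched = x$n_matched, n_missed = x$n_missed,
    n_spurious = x$n_spurious, mean_jaccard = x$mean_jaccard,
    class_accuracy = acc,
    mean_abs_intensity_rel_error = if (x$n_matched > 0) {
      mean(abs(x$matches$intensity_rel_error))
    } else {
      NA_real_
    },
    max_abs_fraction_error_pp = max(abs(x$fraction_error$error_pp))
  )
}
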