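#' Read a long-format qPCR CT table
#'
#' Expected columns: `sample_id`, `group` (`treated` / `control`), `gene`,
#' `role` (`GOI` / `reference`), `ct`.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_ct_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_ct_table(tab)
}

validate_ct_table <- function(tab) {
  req <- c("sample_id", "group", "gene", "role", "ct")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("CT table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(tab$role %in% c("GOI", "reference"))) {
    stop("role must be 'GOI' or 'reference'")
  }
  if (!all(tab$group %in% c("treated", "control"))) {
    stop("group must be 'treated' or 'control'")
  }
  if (any(!is.finite(tab$ct))) stop("CT values must be finite")
  tibble::as_tibble(tab)
}

# Technical replicates averaged per (sample, gene) before any delta.
collapse_replicates <- function(tab) {
  dplyr::summarise(
    dplyr::group_by(tab, .data$sample_id, .data$group, .data$gene,
                    .data$role),
    ct = mean(.data$ct), .groups = "drop"
  )
}

#' Per-sample reference CT
#'
#' Normalizes to multiple reference genes by averaging their CT values per
#' sample.
#'
#' @param ct_table long-format CT table (see [read_ct_table()]).
#' @return Tibble: `sample_id`, `group`, `ct_ref`.
#' @export
reference_ct <- function(ct_table) {
  tab <- collapse_replicates(validate_ct_table(ct_table))
  refs <- dplyr::filter(tab, .data$role == "reference")
  dplyr::summarise(
    dplyr::group_by(refs, .data$sample_id, .data$group),
    ct_ref = mean(.data$ct), .groups = "drop"
  )
}

#' Per-sample delta-CT
#'
#' Uses the reference-minus-gene sign convention
#' `dct = ct_ref - ct_goi`, so higher expression gives a higher delta-CT.
#'
#' @param ct_table long-format CT table.
#' @return Tibble: `sample_id`, `group`, `ct_ref`, `ct_goi`, `dct`. Samples
#'   missing the gene of interest or all reference genes are dropped with a
#'   warning.
#' @export
delta_ct <- function(ct_table) {
  tab <- collapse_replicates(validate_ct_table(ct_table))
  refs <- reference_ct(tab)
  goi <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tab, .data$role == "GOI"),
                    .data$sample_id, .data$group),
    ct_goi = mean(.data$ct), .groups = "drop"
  )
  all_samples <- unique(tab$sample_id)
  joined <- dplyr::inner_join(refs, goi, by = c("sample_id", "group"))
  dropped <- setdiff(all_samples, joined$sample_id)
  if (length(dropped) > 0) {
    warning("samples without GOI or reference CT skipped: ",
            paste(dropped, collapse = ", "))
  }
  dplyr::mutate(joined, dct = .data$ct_ref - .data$ct_goi)
}

#' Relative quantification by the delta-delta-CT method
#'
#' Computes, for every sample, `ddct = dct - dct_control` where
#' `dct_control` aggregates (mean by default, median optionally) the
#' control-group delta-CT values, and the fold change `E^ddct` with
#' amplification efficiency `E` (2 reproduces the classic `2^ddct`; any
#' efficiency in (1, 2] is supported).
#'
#' @param ct_table long-format CT table (see [read_ct_table()]).
#' @param efficiency amplification efficiency E (> 1), default 2.
#' @param control_aggregate `"mean"` or `"median"` over control samples.
#' @return Object of class `ddct_result`; use [tidy()] for the per-sample
#'   table and [glance()] for the group-level fold change.
#' @export
fold_changes <- function(ct_table, efficiency = 2,
                         control_aggregate = c("mean", "median")) {
  control_aggregate <- match.arg(control_aggregate)
  if (efficiency <= 1) stop("efficiency must be > 1")
  dct <- delta_ct(ct_table)
  ctrl <- dplyr::filter(dct, .data$group == "control")
  if (nrow(ctrl) == 0) stop("no control samples in CT table")
  agg <- switch(control_aggregate, mean = mean, median = median)
  dct_control <- agg(ctrl$dct)
  samples <- dplyr::mutate(
    dct,
    ddct = .data$dct - dct_control,
    fold_change = efficiency^.data$ddct
  )
  structure(
    list(samples = samples, dct_control = dct_control,
         efficiency = efficiency, control_aggregate = control_aggregate),
    class = "ddct_result"
  )
}

#' @export
print.ddct_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ddct_result> E = %.3f, %d treated / %d control samples\n",
    x$efficiency, g$n_treated, g$n_control
  ))
  cat(sprintf("  group fold change = %.4g (ddct = %.4g)\n",
              g$fold_change_group, g$mean_ddct_treated))
  invisible(x)
}

#' @describeIn fold_changes Per-sample tidy table (`sample_id`, `group`,
#'   `ct_ref`, `ct_goi`, `dct`, `ddct`, `fold_change`).
#' @param x a `ddct_result`.
#' @param ... unused.
#' @export
tidy.ddct_result <- function(x, ...) {
  x$samples
}

#' @describeIn fold_changes Group-level summary: treated/control counts,
#'   mean treated ddct and the group fold change
#'   `E^(mean dct_treated - dct_control)`.
#' @export
glance.ddct_result <- function(x, ...) {
  trt <- dplyr::filter(x$samples, .data$group == "treated")
  ctl <- dplyr::filter(x$samples, .data$group == "control")
  mean_ddct <- mean(trt$ddct)
  tibble::tibble(
    n_treated = nrow(trt), n_control = nrow(ctl),
    dct_control = x$dct_control,
    mean_ddct_treated = mean_ddct,
    fold_change_group = x$efficiency^mean_ddct
  )
}

#' Write per-treated-sample fold changes to CSV
#'
#' One row per treated sample with columns `sample_id`, `ct_ref`, `dct`,
#' `ddct`, `fold_change`.
#'
#' @param result a `ddct_result` from [fold_changes()].
#' @param path output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_fold_changes <- function(result, path) {
  stopifnot(inherits(result, "ddct_result"))
  out <- dplyr::select(
    dplyr::filter(result$samples, .data$group == "treated"),
    "sample_id", "ct_ref", "dct", "ddct", "fold_change"
  )
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Simulate a CT table with a known expression fold change
#'
#' Generates a long-format CT table for one gene of interest and three
#' reference genes, where the treated group's gene-of-interest CT is shifted
#' by `-log(true_fold, base = efficiency)` cycles so the expected
#' delta-delta-CT fold equals `true_fold`.
#'
#' @param n_treated,n_control samples per group.
#' @param true_fold expected fold change of treated over control.
#' @param efficiency amplification efficiency used for the shift.
#' @param ct_goi_control mean gene-of-interest CT in controls.
#' @param ct_refs mean CTs of the reference genes.
#' @param noise_sd per-well CT standard deviation.
#' @param seed integer seed.
#' @return Long-format CT tibble.
#' @export
simulate_ct_table <- function(n_treated = 4, n_control = 4, true_fold = 2,
                              efficiency = 2, ct_goi_control = 25,
                              ct_refs = c(Hprt1 = 21, Gapdh = 19, Ppia = 20),
                              noise_sd = 0.15, seed = 1L) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  shift <- -log(true_fold, base = efficiency)
  rows <- list()
  for (grp in c("control", "treated")) {
    n <- if (grp == "control") n_control else n_treated
    for (s in seq_len(n)) {
      sid <- paste0(grp, "_", s)
      goi_ct <- ct_goi_control + (grp == "treated") * shift +
        rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, group = grp, gene = "Tmem119", role = "GOI",
        ct = goi_ct
      )
      for (g in names(ct_refs)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sid, group = grp, gene = g, role = "reference",
          ct = ct_refs[[g]] + rnorm(1, 0, noise_sd)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
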