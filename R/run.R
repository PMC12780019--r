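#' Pipeline runners behind the command-line interface
#'
#' Thin, file-oriented wrappers over the analysis functions. Each reads the
#' documented CSV/PNG/TIFF formats, runs one module, writes CSV/JSON results
#' and returns the result invisibly. They are what the `morphotherm` script
#' in `inst/scripts/` dispatches to.
#'
#' @name runners
NULL

#' @rdname runners
#' @param mask_paths Character vector of mask files, or a single directory
#'   (all `.png/.tif/.tiff` inside are used).
#' @param out Output CSV path for per-instance records.
#' @param report_out Optional output CSV path for the group report
#'   (requires `groups_csv`).
#' @param calibration_json Optional calibration model JSON
#'   (see [write_calibration()]).
#' @param groups_csv Optional CSV keyed by `image_id` with `group`
#'   (and optionally `timepoint`, `tumour_id`) columns.
#' @param aggregate Passed to [group_report()].
#' @inheritParams measure_mask
#' @inheritParams as_mask
#' @export
run_measure <- function(mask_paths, out, min_area_px = 5, threshold = NULL,
                        calibration_json = NULL, groups_csv = NULL,
                        report_out = NULL, aggregate = "image") {
  if (length(mask_paths) == 1L && dir.exists(mask_paths)) {
    mask_paths <- list.files(mask_paths, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE)
  }
  if (length(mask_paths) == 0L) {
    warn("no mask files found; writing an empty report")
  }
  calibration <- if (!is.null(calibration_json)) read_calibration(calibration_json)
  records <- measure_masks(mask_paths, min_area_px = min_area_px,
                           calibration = calibration, threshold = threshold)
  write_records(records, out)
  if (!is.null(groups_csv) && !is.null(report_out)) {
    meta <- readr::read_csv(groups_csv, show_col_types = FALSE)
    readr::write_csv(group_report(records, meta, aggregate = aggregate),
                     report_out)
  }
  invisible(records)
}

#' @rdname runners
#' @param pairs_csv Two-column `x,y` CSV of calibration pairs.
#' @inheritParams fit_linear
#' @export
run_calibrate <- function(pairs_csv, out, through_origin = FALSE,
                          x_units = "px", y_units = "mm") {
  model <- fit_linear(read_calibration_pairs(pairs_csv),
                      through_origin = through_origin,
                      x_units = x_units, y_units = y_units)
  write_calibration(model, out)
  invisible(model)
}

#' @rdname runners
#' @param trace_csv Cooling-trace CSV (`time_s,temp_C[,phase]`).
#' @inheritParams photothermal_efficiency
#' @export
run_photothermal <- function(trace_csv, out, T_surr, T_max, A_808, I, m, c,
                             Q_dis = NULL, theta_min = 0.05) {
  trace <- read_trace(trace_csv)
  fit <- fit_time_constant(trace, T_surr = T_surr, T_max = T_max,
                           theta_min = theta_min)
  res <- conversion_efficiency(T_max = T_max, T_surr = T_surr, A_808 = A_808,
                               I = I, m = m, c = c, tau_s = fit$tau_s,
                               Q_dis = Q_dis %||% 0,
                               theta_fit_r2 = fit$r2,
                               n_points_used = fit$n_used)
  payload <- list(
    eta = res$eta, tau_s = res$tau_s, hs_mW_per_C = res$hs,
    Q_dis_mW = res$Q_dis, theta_fit_r2 = res$theta_fit_r2,
    n_points_used = res$n_points_used, warning_flag = res$warning_flag,
    theta = fit$data
  )
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(res)
}

#' @rdname runners
#' @param input Input CSV: a plate table for `kind = "hemolysis"` /
#'   `"viability"`; a `group,concentration` table for `"reduction"`; a
#'   `group,fluorescence` table for `"h2s"`.
#' @param kind Assay statistic to compute.
#' @param curve_json Calibration JSON (required for `kind = "h2s"`).
#' @param control Control group name for `kind = "reduction"`.
#' @export
run_assay <- function(input, out,
                      kind = c("hemolysis", "viability", "reduction", "h2s"),
                      curve_json = NULL, control = "PBS") {
  kind <- match.arg(kind)
  df <- readr::read_csv(input, show_col_types = FALSE)
  res <- switch(kind,
    hemolysis = plate_rates(df, "hemolysis"),
    viability = plate_rates(df, "viability"),
    reduction = reduction_table(df, control = control),
    h2s = {
      if (is.null(curve_json)) abort("`kind = \"h2s\"` needs `curve_json`.")
      quantify_h2s(df, read_calibration(curve_json))
    }
  )
  readr::write_csv(res, out)
  invisible(res)
}

#' @rdname runners
#' @param out_dir Directory to materialize the demo fixture set into.
#' @param seed Integer seed controlling every generator.
#' @export
run_simulate <- function(out_dir, seed = 0) {
  invisible(write_fixtures(out_dir, seed = seed))
}

#' Write morphometry records to CSV or JSON
#'
#' The format follows the file extension: `.csv` (default for anything
#' unrecognized) or `.json` (column-oriented, full precision).
#'
#' @param records Records from [measure_mask()]/[measure_masks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    readr::write_csv(records, path)
  }
  invisible(path)
}

#' Materialize a complete synthetic demo dataset
#'
#' Writes everything the analysis pipeline reads: two lesion masks (PNG)
#' with their ground-truth table, a calibration-pairs CSV, a cooling-trace
#' CSV, a blood-decay CSV, plate/fluorescence/group assay CSVs and a meta
#' CSV mapping images to treatment groups.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  sim1 <- make_mask(96, 96, list(
    shape_ellipse(c(30, 32), 18, 9, angle = 25),
    shape_blob(c(70, 68), 12, jitter = 0.2, seed = seed + 1L)
  ), speckle_density = 0.002, seed = seed)
  sim2 <- make_mask(96, 96, list(
    shape_ellipse(c(48, 48), 22, 14, angle = 110)
  ), seed = seed + 2L)
  write_mask(sim1$mask, p("mask_img1.png"))
  write_mask(sim2$mask, p("mask_img2.png"))
  readr::write_csv(
    dplyr::bind_rows(
      dplyr::mutate(sim1$truth, image_id = "mask_img1"),
      dplyr::mutate(sim2$truth, image_id = "mask_img2")
    ), p("mask_truth.csv"))
  readr::write_csv(
    tibble(image_id = c("mask_img1", "mask_img2"),
           group = c("PBS", "PfCC+NIR"), timepoint = c("d6", "d6")),
    p("groups.csv"))

  readr::write_csv(make_calibration_pairs(seed = seed), p("calibration_pairs.csv"))
  readr::write_csv(make_cooling_curve(sigma = 0.2, seed = seed), p("cooling_trace.csv"))
  readr::write_csv(make_decay_curve(sigma_rel = 0.05, seed = seed), p("blood_decay.csv"))

  tables <- make_assay_tables(seed = seed)
  readr::write_csv(tables$hemolysis, p("plate_hemolysis.csv"))
  readr::write_csv(tables$viability, p("plate_viability.csv"))
  readr::write_csv(tables$fluorescence_curve, p("fluorescence_curve.csv"))
  readr::write_csv(tables$h2s_groups, p("h2s_groups.csv"))

  paths <- c(
    mask1 = p("mask_img1.png"), mask2 = p("mask_img2.png"),
    truth = p("mask_truth.csv"), groups = p("groups.csv"),
    calibration = p("calibration_pairs.csv"),
    cooling = p("cooling_trace.csv"), decay = p("blood_decay.csv"),
    hemolysis = p("plate_hemolysis.csv"), viability = p("plate_viability.csv"),
    fluorescence = p("fluorescence_curve.csv"), h2s = p("h2s_groups.csv")
  )
  invisible(paths)
}
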