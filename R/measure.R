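#' Measure tumour instances in a binary mask
#'
#' Full morphometry pipeline: label 8-connected instances, trace each outer
#' boundary, compute its convex hull and its maximum pixel distance (maximum
#' Feret diameter). With a calibration model the pixel measurements are
#' converted to physical units:
#' \itemize{
#'   \item `max_diameter_phys = slope * max_diameter_px + intercept` (mm),
#'   \item `area_phys = slope^2 * area_px` (mm^2; the additive intercept is a
#'     length offset and is not applied to areas),
#'   \item `est_volume_phys = (pi/6) * max_diameter_phys^3` (mm^3), an
#'     equivalent-sphere estimate — an explicit modelling assumption, flagged
#'     in the `volume_model` attribute of the result.
#' }
#' The tumour count of the image is `nrow()` of the result.
#'
#' @inheritParams label_instances
#' @param calibration Optional `calibration_model` from [fit_linear()]
#'   mapping pixel distance to physical distance (mm per px).
#' @param image_id Optional identifier copied into the output.
#' @return A tibble with one row per retained instance: `image_id`,
#'   `instance_id`, `area_px`, `max_diameter_px`, endpoint coordinates
#'   (`end1_row`, `end1_col`, `end2_row`, `end2_col`) and, when calibrated,
#'   `max_diameter_phys`, `area_phys`, `est_volume_phys`.
#' @examples
#' m <- matrix(FALSE, 32, 32)
#' m[8:24, 10:14] <- TRUE
#' measure_mask(m, min_area_px = 0)
#' @export
measure_mask <- function(mask, min_area_px = 5, calibration = NULL,
                         image_id = NA_character_) {
  mask <- as_mask(mask)
  instances <- label_instances(mask, min_area_px = min_area_px)

  rows <- purrr::map(instances$pixels, function(px) {
    contour <- extract_boundary(px, mask)
    hull <- convex_hull(contour)
    feret <- max_pixel_distance(hull)
    tibble(
      max_diameter_px = feret$distance,
      end1_row = feret$endpoints[1L, 1L], end1_col = feret$endpoints[1L, 2L],
      end2_row = feret$endpoints[2L, 1L], end2_col = feret$endpoints[2L, 2L]
    )
  })

  out <- dplyr::bind_cols(
    tibble(image_id = rep(image_id, nrow(instances))),
    instances[c("instance_id", "area_px")],
    if (nrow(instances)) dplyr::bind_rows(rows) else tibble(
      max_diameter_px = double(), end1_row = double(), end1_col = double(),
      end2_row = double(), end2_col = double()
    )
  )

  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_model"))
    out <- dplyr::mutate(
      out,
      max_diameter_phys = apply_calibration(calibration, .data$max_diameter_px),
      area_phys = calibration$slope^2 * .data$area_px,
      est_volume_phys = pi / 6 * .data$max_diameter_phys^3
    )
    attr(out, "volume_model") <- "estimated (sphere model)"
  }
  out
}

#' Measure a set of mask files
#'
#' @param paths Character vector of PNG/TIFF mask paths.
#' @inheritParams measure_mask
#' @inheritParams as_mask
#' @return Row-bound [measure_mask()] records, `image_id` set to the file
#'   name without extension.
#' @export
measure_masks <- function(paths, min_area_px = 5, calibration = NULL,
                          threshold = NULL) {
  purrr::map_dfr(paths, function(p) {
    measure_mask(read_mask(p, threshold = threshold),
                 min_area_px = min_area_px, calibration = calibration,
                 image_id = tools::file_path_sans_ext(basename(p)))
  })
}

#' Group-level therapy report
#'
#' Aggregates per-instance morphometry records into per-group (and optional
#' per-timepoint) summaries: tumour count, mean and maximum diameter, total
#' estimated volume — the quantities used to compare treatment arms from
#' endoscopic images.
#'
#' Endoscopy often photographs one tumour from several angles. With
#' `aggregate = "image"` (default) every image contributes its instances
#' separately; with `aggregate = "tumour"` records sharing a `tumour_id` in
#' `meta` are first collapsed to their maximum diameter across angles, so a
#' tumour is counted once.
#'
#' @param records Morphometry records from [measure_mask()]/[measure_masks()].
#' @param meta A data frame keyed by `image_id` with a `group` column and
#'   optional `timepoint` and `tumour_id` columns.
#' @param aggregate `"image"` or `"tumour"` (see Details).
#' @return A tibble per group (and timepoint): `n_tumours`,
#'   `mean_diameter`, `max_diameter`, `total_volume` (when calibrated
#'   columns are present, physical units; otherwise pixel units and
#'   `total_volume` is `NA`).
#' @export
group_report <- function(records, meta, aggregate = c("image", "tumour")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("image_id", "group") %in% names(meta)))
  df <- dplyr::inner_join(records, meta, by = "image_id")
  diam_col <- if ("max_diameter_phys" %in% names(df)) "max_diameter_phys" else "max_diameter_px"
  keys <- intersect(c("group", "timepoint"), names(df))

  if (aggregate == "tumour") {
    if (!"tumour_id" %in% names(df)) {
      abort("`aggregate = \"tumour\"` requires a `tumour_id` column in `meta`.")
    }
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "tumour_id")))) |>
      dplyr::slice_max(.data[[diam_col]], n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }

  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_tumours = dplyr::n(),
      mean_diameter = mean(.data[[diam_col]]),
      max_diameter = max(.data[[diam_col]]),
      total_volume = if ("est_volume_phys" %in% names(df)) {
        sum(.data$est_volume_phys)
      } else NA_real_,
      .groups = "drop"
    )
}
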