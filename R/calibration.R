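#' Fit a linear standard curve
#'
#' Ordinary least squares of `y` on `x` with a free intercept, used both for
#' the endoscopy size calibration (pixel distance vs dissected-tumour
#' distance in mm) and for assay standard curves (signal vs concentration).
#' A through-origin variant is available; the default keeps the intercept
#' free, the usual convention for laboratory standard curves.
#'
#' `r_squared` is `1 - SSE/SST` with SST about the mean response; a fit with
#' `SST = 0` and `SSE = 0` (constant, exactly reproduced response) reports
#' `r_squared = 1`.
#'
#' @param pairs Data frame whose first two columns (or columns named `x`
#'   and `y`) hold the predictor and response.
#' @param through_origin Force the intercept to zero.
#' @param x_units,y_units Unit labels carried into reports.
#' @return A `calibration_model`: slope, intercept, their standard errors,
#'   `r_squared`, `n`, unit labels and the fitting data.
#' @examples
#' fit_linear(data.frame(x = c(1, 2, 3), y = c(3, 5, 7)))
#' @export
fit_linear <- function(pairs, through_origin = FALSE,
                       x_units = "px", y_units = "mm") {
  xy <- extract_xy(pairs)
  x <- xy$x
  y <- xy$y
  if (length(x) < 2L) abort("insufficient pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("pairs must be finite")
  if (diff(range(x)) == 0) abort("degenerate design")

  n <- length(x)
  if (through_origin) {
    slope <- sum(x * y) / sum(x^2)
    intercept <- 0
  } else {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
  }
  resid <- y - (slope * x + intercept)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) as.numeric(sse <= .Machine$double.eps * sum(y^2) + 1e-300) else 1 - sse / sst

  df_resid <- n - if (through_origin) 1L else 2L
  sigma2 <- if (df_resid > 0) sse / df_resid else 0
  slope_se <- if (through_origin) sqrt(sigma2 / sum(x^2)) else {
    sqrt(sigma2 / sum((x - mean(x))^2))
  }
  intercept_se <- if (through_origin) 0 else {
    sqrt(sigma2 * sum(x^2) / (n * sum((x - mean(x))^2)))
  }

  structure(
    list(
      slope = slope,
      intercept = intercept,
      slope_se = slope_se,
      intercept_se = intercept_se,
      r_squared = r2,
      n = n,
      x_units = x_units,
      y_units = y_units,
      through_origin = through_origin,
      data = tibble(x = x, y = y)
    ),
    class = "calibration_model"
  )
}

extract_xy <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (!is.data.frame(pairs) || ncol(pairs) < 2L) {
    abort("`pairs` must be a data frame with at least two columns.")
  }
  if (all(c("x", "y") %in% names(pairs))) {
    list(x = as.numeric(pairs$x), y = as.numeric(pairs$y))
  } else {
    list(x = as.numeric(pairs[[1L]]), y = as.numeric(pairs[[2L]]))
  }
}

#' Apply a standard curve
#'
#' @param model A `calibration_model`.
#' @param x Numeric vector on the predictor scale (e.g. pixel distance).
#' @return `slope * x + intercept`.
#' @export
apply_calibration <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * x + model$intercept
}

#' Invert a standard curve
#'
#' Maps a response (e.g. fluorescence) back to the predictor scale
#' (e.g. concentration read off a standard curve fitted as signal ~ conc).
#'
#' @param model A `calibration_model`.
#' @param y Numeric vector on the response scale.
#' @return `(y - intercept) / slope`.
#' @export
invert_calibration <- function(model, y) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0) abort("non-invertible curve")
  (y - model$intercept) / model$slope
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> y = ",
      format(x$slope, digits = 6), " * x",
      if (x$intercept >= 0) " + " else " - ",
      format(abs(x$intercept), digits = 6),
      "   [", x$y_units, " per ", x$x_units, "]\n",
      "  n = ", x$n, ", R^2 = ", format(x$r_squared, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  apply_calibration(object, if (is.data.frame(newdata)) newdata$x else newdata)
}

#' @rdname fit_linear
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @rdname fit_linear
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n,
         x.units = x$x_units, y.units = x$y_units)
}

#' Read calibration pairs from a two-column CSV
#'
#' @param path CSV with a header row; columns `x,y` (or the first two
#'   columns are used).
#' @return A tibble with columns `x` and `y`.
#' @export
read_calibration_pairs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  xy <- extract_xy(df)
  tibble(x = xy$x, y = xy$y)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `calibration_model` (without the
#'   original fitting data).
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  fields <- model[c("slope", "intercept", "slope_se", "intercept_se",
                    "r_squared", "n", "x_units", "y_units", "through_origin")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(c(fields, list(data = NULL)), class = "calibration_model")
}
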