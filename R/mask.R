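#' Coerce a matrix to a binary lesion mask
#'
#' A mask is a logical matrix: rows index image rows (top to bottom), columns
#' index image columns (left to right), `TRUE` marks lesion (foreground)
#' pixels. Numeric matrices are interpreted as any-nonzero-is-foreground,
#' matching how segmenters export binary label images.
#'
#' @param x A logical or numeric matrix with at least one row and column.
#' @param threshold Optional numeric cut applied to a numeric/greyscale
#'   matrix: pixels strictly greater than `threshold` become foreground.
#'   When `NULL` (default) any nonzero value is foreground.
#' @return A logical matrix of the same dimensions.
#' @examples
#' as_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
as_mask <- function(x, threshold = NULL) {
  if (!is.matrix(x) || nrow(x) < 1 || ncol(x) < 1) {
    abort("`x` must be a matrix with at least one row and one column.")
  }
  if (is.logical(x)) {
    if (anyNA(x)) abort("mask contains missing values")
    return(x)
  }
  if (!is.numeric(x)) abort("`x` must be a logical or numeric matrix.")
  if (anyNA(x)) abort("mask contains missing values")
  if (is.null(threshold)) x != 0 else x > threshold
}

#' Read a binary mask from a PNG or TIFF file
#'
#' Multi-channel images are reduced to their first channel before
#' thresholding. Any nonzero pixel is foreground unless `threshold` is given
#' (required for greyscale masks whose foreground is not exactly 0/1 coded).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams as_mask
#' @return A logical matrix (see [as_mask()]).
#' @export
read_mask <- function(path, threshold = NULL) {
  if (!file.exists(path)) abort(paste0("mask file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported mask format: .", ext, " (use PNG or TIFF)"))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  as_mask(img, threshold = threshold)
}

#' Write a binary mask to a PNG or TIFF file
#'
#' Foreground pixels are written as 1, background as 0.
#'
#' @param mask A logical mask matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    abort(paste0("unsupported mask format: .", ext, " (use PNG or TIFF)"))
  )
  invisible(path)
}
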