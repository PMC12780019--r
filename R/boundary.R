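#' Trace the outer boundary of a tumour instance
#'
#' Moore-neighbourhood contour tracing with Jacob's stopping criterion.
#' Starting from the instance's topmost-leftmost pixel the trace walks the
#' outer contour clockwise in screen convention (rows grow downwards). The
#' trace is closed conceptually: the start pixel is not repeated at the end.
#'
#' For instances without interior holes the set of traced pixels equals the
#' set of foreground pixels that touch the background through a 4-neighbour
#' or lie on the image edge. Interior hole contours are not traced; they do
#' not affect convex hulls or diameters, which depend only on the outer
#' contour.
#'
#' @param pixels Two-column `(row, col)` matrix of the instance's pixels
#'   (one 8-connected component), e.g. a `pixels` entry from
#'   [label_instances()].
#' @param mask Optional logical mask the instance belongs to; only its
#'   dimensions are used. When `NULL` the instance's bounding box is used.
#' @return A two-column `(row, col)` matrix of boundary pixels in clockwise
#'   trace order. A single-pixel instance returns that pixel alone. Pixels on
#'   one-pixel-wide spurs can appear more than once (the contour passes them
#'   twice); the set of distinct pixels is the outer boundary.
#' @export
extract_boundary <- function(pixels, mask = NULL) {
  pixels <- validate_pixels(pixels)
  n <- nrow(pixels)
  if (n == 1L) return(pixels)

  if (is.null(mask)) {
    h <- max(pixels[, 1L])
    w <- max(pixels[, 2L])
  } else {
    h <- nrow(mask)
    w <- ncol(mask)
  }
  inside <- matrix(FALSE, h, w)
  inside[pixels] <- TRUE

  # Start pixel: topmost, then leftmost. Its west neighbour is background.
  start_i <- which.min((pixels[, 1L] - 1L) * w + pixels[, 2L])
  start <- pixels[start_i, ]

  # Moore neighbours in clockwise screen order, starting due west.
  dirs <- rbind(
    W = c(0L, -1L), NW = c(-1L, -1L), N = c(-1L, 0L), NE = c(-1L, 1L),
    E = c(0L, 1L), SE = c(1L, 1L), S = c(1L, 0L), SW = c(1L, -1L)
  )
  dir_index <- function(from, to) {
    d <- to - from
    which(dirs[, 1L] == d[[1L]] & dirs[, 2L] == d[[2L]])
  }
  is_fg <- function(p) {
    p[[1L]] >= 1L && p[[1L]] <= h && p[[2L]] >= 1L && p[[2L]] <= w &&
      inside[p[[1L]], p[[2L]]]
  }

  start_back <- c(start[[1L]], start[[2L]] - 1L)
  cur <- start
  back <- start_back
  trace <- matrix(start, ncol = 2L)
  max_steps <- 4L * n + 8L

  for (step in seq_len(max_steps)) {
    b <- dir_index(cur, back)
    nxt <- NULL
    new_back <- back
    prev <- back
    for (k in seq_len(8L)) {
      idx <- ((b - 1L + k) %% 8L) + 1L
      cand <- cur + dirs[idx, ]
      if (is_fg(cand)) {
        nxt <- cand
        new_back <- prev
        break
      }
      prev <- cand
    }
    if (is.null(nxt)) break # isolated pixel; cannot happen for n > 1
    if (nxt[[1L]] == start[[1L]] && nxt[[2L]] == start[[2L]] &&
        new_back[[1L]] == start_back[[1L]] && new_back[[2L]] == start_back[[2L]]) {
      break
    }
    trace <- rbind(trace, nxt)
    cur <- nxt
    back <- new_back
  }
  dimnames(trace) <- list(NULL, c("row", "col"))
  trace
}

#' All boundary pixels of a mask
#'
#' A foreground pixel is a boundary pixel when at least one of its
#' 4-neighbours is background or it lies on the image edge. Unlike
#' [extract_boundary()] this includes interior hole contours and returns
#' pixels in scan order, not trace order.
#'
#' @param mask A logical mask matrix.
#' @return Two-column `(row, col)` matrix of boundary pixels.
#' @export
boundary_pixels <- function(mask) {
  mask <- as_mask(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- padded[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    padded[1:h, 2:(w + 1L)] & padded[3:(h + 2L), 2:(w + 1L)] &
    padded[2:(h + 1L), 1:w] & padded[2:(h + 1L), 3:(w + 2L)]
  idx <- which(core & !interior)
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
}

validate_pixels <- function(pixels) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels[, 1:2])
  if (!is.matrix(pixels) || ncol(pixels) != 2L || nrow(pixels) < 1L) {
    abort("`pixels` must be a two-column (row, col) matrix with >= 1 row.")
  }
  storage.mode(pixels) <- "integer"
  dimnames(pixels) <- list(NULL, c("row", "col"))
  pixels
}
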