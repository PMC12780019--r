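#' Label connected tumour instances in a binary mask
#'
#' Foreground pixels are grouped into 8-connected components (the background
#' complement is implicitly 4-connected, the standard pairing for blob
#' labelling). Components smaller than `min_area_px` — typically segmentation
#' speckle — are dropped. Retained instances are labelled `1..k` in scan
#' order: the instance whose first pixel comes first in row-major reading
#' order (top row first, left to right) gets label 1.
#'
#' @param mask A logical mask matrix (see [as_mask()]).
#' @param min_area_px Minimum pixel area for an instance to be retained.
#'   The default 5 suppresses isolated-speckle artefacts from automated
#'   segmenters; use 0 to keep everything.
#' @return A tibble with one row per instance: `instance_id`, `area_px`,
#'   and a `pixels` list-column of two-column `(row, col)` integer matrices
#'   in scan order. Coordinates are 1-based pixel centres. The full labelled
#'   image is attached as attribute `"label_matrix"` (0 = background or
#'   filtered; retained instances carry their label).
#' @examples
#' m <- matrix(FALSE, 8, 8)
#' m[2:4, 2:4] <- TRUE
#' m[6:7, 6:7] <- TRUE
#' label_instances(m, min_area_px = 0)
#' @export
label_instances <- function(mask, min_area_px = 5) {
  mask <- as_mask(mask)
  if (min_area_px < 0) abort("`min_area_px` must be >= 0.")
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- which(mask)
  empty <- tibble(
    instance_id = integer(),
    area_px = integer(),
    pixels = list()
  )
  if (length(fg) == 0L) {
    attr(empty, "label_matrix") <- matrix(0L, h, w)
    return(empty)
  }

  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  id_of <- matrix(0L, h, w)
  id_of[fg] <- seq_along(fg)

  # Edges between each foreground pixel and its E, S, SE, SW neighbours:
  # enough to connect every 8-adjacent pair exactly once.
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  edge_list <- purrr::map(offsets, function(o) {
    r2 <- rows + o[[1L]]
    c2 <- cols + o[[2L]]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    to <- id_of[cbind(r2[ok], c2[ok])]
    keep <- to > 0L
    cbind(seq_along(fg)[ok][keep], to[keep])
  })
  edges <- do.call(rbind, edge_list)

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  membership <- igraph::components(g)$membership

  # Relabel components by scan order of their first pixel (row-major).
  scan_idx <- (rows - 1L) * w + cols
  first_scan <- tapply(scan_idx, membership, min)
  new_label <- rank(first_scan)
  labels_px <- as.integer(new_label[as.character(membership)])

  sizes <- tabulate(labels_px)
  keep_ids <- which(sizes >= min_area_px)
  if (length(keep_ids) == 0L) {
    attr(empty, "label_matrix") <- matrix(0L, h, w)
    return(empty)
  }

  relabel <- integer(length(sizes))
  relabel[keep_ids] <- seq_along(keep_ids)

  label_matrix <- matrix(0L, h, w)
  label_matrix[fg] <- relabel[labels_px]

  ord <- order(labels_px, scan_idx)
  rows_o <- rows[ord]
  cols_o <- cols[ord]
  labels_o <- labels_px[ord]

  pix <- purrr::map(keep_ids, function(k) {
    sel <- labels_o == k
    cbind(row = rows_o[sel], col = cols_o[sel])
  })

  out <- tibble(
    instance_id = seq_along(keep_ids),
    area_px = sizes[keep_ids],
    pixels = pix
  )
  attr(out, "label_matrix") <- label_matrix
  out
}
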