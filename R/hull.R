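#' Convex hull of pixel points (monotone chain)
#'
#' Andrew's monotone-chain construction. Vertices are the extreme points of
#' the input in counter-clockwise order in the `(col, row)` coordinate plane
#' (columns as x, rows as y); collinear non-extreme points are excluded, so
#' no three consecutive vertices are collinear. Duplicate input points are
#' tolerated and deduplicated.
#'
#' @param points Two-column `(row, col)` matrix or data frame of points;
#'   coordinates may be real-valued.
#' @return A `convex_polygon`: a two-column `(row, col)` numeric matrix of
#'   hull vertices. Degenerate inputs yield 1 (single point) or 2 (collinear
#'   set) vertices.
#' @examples
#' convex_hull(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0.5, 0.5)))
#' @export
convex_hull <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.null(points) || length(points) == 0L) abort("no points")
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) < 1L) {
    abort("`points` must be a two-column (row, col) matrix.")
  }
  if (!all(is.finite(points))) abort("points must be finite")

  pts <- unique(points[order(points[, 2L], points[, 1L]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(new_convex_polygon(pts))

  # x = col, y = row; strict left turns only (cross > 0 kept).
  cross <- function(o, a, b) {
    (a[2L] - o[2L]) * (b[1L] - o[1L]) - (a[1L] - o[1L]) * (b[2L] - o[2L])
  }
  build <- function(idx) {
    chain <- integer(0L)
    for (i in idx) {
      while (length(chain) >= 2L) {
        m <- length(chain)
        if (cross(pts[chain[m - 1L], ], pts[chain[m], ], pts[i, ]) <= 0) {
          chain <- chain[-m]
        } else break
      }
      chain <- c(chain, i)
    }
    chain
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull_idx <- c(lower[-length(lower)], upper[-length(upper)])
  new_convex_polygon(pts[hull_idx, , drop = FALSE])
}

new_convex_polygon <- function(vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 2L,
                     dimnames = list(NULL, c("row", "col")))
  structure(vertices, class = c("convex_polygon", "matrix", "array"))
}

#' @export
print.convex_polygon <- function(x, ...) {
  cat("<convex_polygon> ", nrow(x), " vertices (counter-clockwise)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Test whether points lie inside or on a convex polygon
#'
#' @param hull A `convex_polygon` from [convex_hull()].
#' @param points Two-column `(row, col)` matrix of query points.
#' @param tol Numeric slack on the half-plane tests, in squared-pixel units.
#' @return Logical vector, `TRUE` when the point is inside or on the hull.
#' @export
in_hull <- function(hull, points, tol = 1e-9) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  m <- nrow(hull)
  if (m == 1L) {
    return(abs(points[, 1L] - hull[1L, 1L]) <= tol &
             abs(points[, 2L] - hull[1L, 2L]) <= tol)
  }
  ok <- rep(TRUE, nrow(points))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (m == 2L && i == 2L) break
    # cross((hull_j - hull_i), (p - hull_i)) in (col=x, row=y) plane
    cr <- (hull[j, 2L] - hull[i, 2L]) * (points[, 1L] - hull[i, 1L]) -
      (hull[j, 1L] - hull[i, 1L]) * (points[, 2L] - hull[i, 2L])
    ok <- ok & if (m == 2L) abs(cr) <= tol else cr >= -tol
  }
  if (m == 2L) {
    # collinear hull: also require projection within the segment
    d <- hull[2L, ] - hull[1L, ]
    t <- ((points[, 1L] - hull[1L, 1L]) * d[1L] +
            (points[, 2L] - hull[1L, 2L]) * d[2L]) / sum(d^2)
    ok <- ok & t >= -tol & t <= 1 + tol
  }
  ok
}

#' Maximum pixel distance (maximum Feret diameter)
#'
#' The largest Euclidean distance between pixel centres of a region; by
#' convexity it is attained between convex-hull vertices. Computed by
#' rotating calipers over antipodal vertex pairs when the hull has at least
#' 3 vertices, by direct evaluation otherwise. Ties are broken by the
#' lexicographically smallest endpoint pair (rows before columns).
#'
#' @param x A `convex_polygon`, or a two-column `(row, col)` point matrix
#'   (its hull is computed first).
#' @return A list with `distance` (pixels) and `endpoints`, a 2x2
#'   `(row, col)` matrix. A single-vertex hull gives distance 0 with
#'   identical endpoints.
#' @examples
#' max_pixel_distance(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
#' @export
max_pixel_distance <- function(x) {
  hull <- if (inherits(x, "convex_polygon")) x else convex_hull(x)
  m <- nrow(hull)
  if (m == 1L) {
    return(list(distance = 0,
                endpoints = rbind(hull[1L, ], hull[1L, ])))
  }
  cand <- if (m == 2L) {
    matrix(c(1L, 2L), ncol = 2L)
  } else {
    antipodal_pairs(hull)
  }
  d2 <- (hull[cand[, 1L], 1L] - hull[cand[, 2L], 1L])^2 +
    (hull[cand[, 1L], 2L] - hull[cand[, 2L], 2L])^2
  best <- max(d2)
  ties <- cand[d2 == best, , drop = FALSE]
  pick <- pick_lex_pair(hull, ties)
  list(distance = sqrt(best),
       endpoints = rbind(hull[pick[1L], ], hull[pick[2L], ]))
}

# Antipodal vertex pairs of a CCW convex polygon (rotating calipers).
# Returns an index matrix; includes every diameter-achieving pair.
antipodal_pairs <- function(hull) {
  m <- nrow(hull)
  nxt <- function(i) if (i == m) 1L else i + 1L
  # twice the signed area of triangle (a, b, c) in the (col, row) plane
  tri2 <- function(a, b, c) {
    (hull[b, 2L] - hull[a, 2L]) * (hull[c, 1L] - hull[a, 1L]) -
      (hull[b, 1L] - hull[a, 1L]) * (hull[c, 2L] - hull[a, 2L])
  }
  pairs <- matrix(integer(0L), ncol = 2L)
  j <- 2L
  steps <- 0L
  for (i in seq_len(m)) {
    ni <- nxt(i)
    repeat {
      nj <- nxt(j)
      if (tri2(i, ni, nj) > tri2(i, ni, j)) {
        j <- nj
        steps <- steps + 1L
        if (steps > 4L * m) abort("rotating calipers failed to converge")
      } else break
    }
    pairs <- rbind(pairs, c(i, j), c(ni, j))
    # parallel edge: the next vertex is equally far from edge (i, ni)
    if (tri2(i, ni, nxt(j)) == tri2(i, ni, j)) {
      pairs <- rbind(pairs, c(i, nxt(j)), c(ni, nxt(j)))
    }
  }
  pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
}

# Among index pairs, pick the lexicographically smallest (row, col) ordered
# endpoint pair for reproducible tie-breaking.
pick_lex_pair <- function(hull, pairs) {
  keys <- apply(pairs, 1L, function(p) {
    a <- hull[p[1L], ]
    b <- hull[p[2L], ]
    if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L])) {
      tmp <- a; a <- b; b <- tmp
      p <- rev(p)
    }
    list(key = c(a, b), idx = p)
  })
  mat <- do.call(rbind, purrr::map(keys, "key"))
  ord <- do.call(order, as.data.frame(mat))
  keys[[ord[1L]]]$idx
}
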