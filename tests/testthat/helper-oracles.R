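# Independent reference implementations used only to check the package's
# primitives. Deliberately naive: correctness over speed.

# 8-connected components by stack-based flood fill.
oracle_flood_fill <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  lab <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || labels[r0, c0] != 0L) next
    lab <- lab + 1L
    stack <- list(c(r0, c0))
    labels[r0, c0] <- lab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr
        c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- lab
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  labels
}

# boundary set by exhaustive 4-neighbour scan
oracle_boundary_set <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    on_edge <- r == 1L || r == h || c == 1L || c == w
    bg4 <- (r > 1 && !mask[r - 1, c]) || (r < h && !mask[r + 1, c]) ||
      (c > 1 && !mask[r, c - 1]) || (c < w && !mask[r, c + 1])
    if (on_edge || bg4) out <- rbind(out, c(r, c))
  }
  out
}

# brute-force hull: a point is a hull vertex iff it is not strictly inside
# any triangle formed by three other points (valid for points in general
# position, which random continuous points are almost surely)
oracle_hull_vertices <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    tri <- utils::combn(others, 3L)
    px <- points[p, 2L]
    py <- points[p, 1L]
    for (t in seq_len(ncol(tri))) {
      a <- points[tri[1L, t], ]
      b <- points[tri[2L, t], ]
      c <- points[tri[3L, t], ]
      d1 <- (px - b[2L]) * (a[1L] - b[1L]) - (a[2L] - b[2L]) * (py - b[1L])
      d2 <- (px - c[2L]) * (b[1L] - c[1L]) - (b[2L] - c[2L]) * (py - c[1L])
      d3 <- (px - a[2L]) * (c[1L] - a[1L]) - (c[2L] - a[2L]) * (py - a[1L])
      neg <- (d1 < 0) || (d2 < 0) || (d3 < 0)
      pos <- (d1 > 0) || (d2 > 0) || (d3 > 0)
      if (!(neg && pos) && d1 != 0 && d2 != 0 && d3 != 0) {
        keep[p] <- FALSE
        break
      }
    }
  }
  points[keep, , drop = FALSE]
}

# all-pairs maximum distance with the same floating expression the package
# uses (squared sums, single final sqrt)
oracle_max_distance <- function(points) {
  d2 <- outer(points[, 1L], points[, 1L], "-")^2 +
    outer(points[, 2L], points[, 2L], "-")^2
  sqrt(max(d2))
}

# canonical key for comparing point sets regardless of order
point_set_key <- function(points) {
  points <- points[order(points[, 1L], points[, 2L]), , drop = FALSE]
  paste(points[, 1L], points[, 2L], sep = ",", collapse = ";")
}

# random blob-ish test mask: union of a few random discs plus salt noise
random_blob_mask <- function(h, w, n_discs = 3L, noise = 0.01, seed = 0) {
  withr::with_seed(seed, {
    mask <- matrix(stats::runif(h * w) < noise, h, w)
    for (i in seq_len(n_discs)) {
      cr <- stats::runif(1, h * 0.2, h * 0.8)
      cc <- stats::runif(1, w * 0.2, w * 0.8)
      rad <- stats::runif(1, 3, min(h, w) / 5)
      rr <- rep(seq_len(h), times = w)
      cc2 <- rep(seq_len(w), each = h)
      mask[(rr - cr)^2 + (cc2 - cc)^2 <= rad^2] <- TRUE
    }
    mask
  })
}
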