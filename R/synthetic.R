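#' Shape specifications for synthetic lesion masks
#'
#' Continuous-geometry shapes that [make_mask()] rasterizes, each with a
#' closed-form (or densely sampled) true maximum diameter and area:
#' \itemize{
#'   \item `shape_ellipse()`: semi-axes `a`, `b` in px and a rotation in
#'     degrees; true diameter `2 * max(a, b)`, true area `pi * a * b`.
#'   \item `shape_polygon()`: explicit convex or non-convex vertex list
#'     (`(row, col)` matrix); true diameter is the maximum vertex-pair
#'     distance, area by the shoelace formula.
#'   \item `shape_blob()`: a star-convex radial perturbation of a circle,
#'     `r(phi) = radius * (1 + jitter * s(phi))` with `s` a smooth periodic
#'     sum of random-phase harmonics (its own `seed` makes the shape a pure
#'     function of its arguments). Truth is computed by dense angular
#'     sampling of the boundary (720 directions), valid because the shape is
#'     star-convex.
#' }
#'
#' @param center `(row, col)` centre in pixels.
#' @param a,b Ellipse semi-axes, px (> 0).
#' @param angle Ellipse rotation, degrees counter-clockwise in the
#'   `(col, row)` plane.
#' @param vertices Two-column `(row, col)` matrix of polygon vertices in
#'   order (not self-intersecting).
#' @param radius Blob base radius, px (> 0).
#' @param jitter Relative radial perturbation amplitude in [0, 0.5).
#' @param n_harmonics Number of random harmonics in the blob boundary.
#' @param seed Seed for the blob's harmonic phases/amplitudes.
#' @return A `shape_spec` list understood by [make_mask()].
#' @name shape_spec
NULL

#' @rdname shape_spec
#' @export
shape_ellipse <- function(center, a, b, angle = 0) {
  stopifnot(length(center) == 2L, a > 0, b > 0)
  structure(list(kind = "ellipse", center = as.numeric(center),
                 a = a, b = b, angle = angle),
            class = "shape_spec")
}

#' @rdname shape_spec
#' @export
shape_polygon <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(kind = "polygon", vertices = vertices),
            class = "shape_spec")
}

#' @rdname shape_spec
#' @export
shape_blob <- function(center, radius, jitter = 0.2, n_harmonics = 4,
                       seed = 0) {
  stopifnot(length(center) == 2L, radius > 0, jitter >= 0, jitter < 0.5)
  coefs <- withr::with_seed(seed, {
    amp <- stats::runif(n_harmonics)
    amp <- amp / max(sum(amp), 1e-12)
    list(amp = amp, phase = stats::runif(n_harmonics, 0, 2 * pi))
  })
  structure(list(kind = "blob", center = as.numeric(center), radius = radius,
                 jitter = jitter, amp = coefs$amp, phase = coefs$phase),
            class = "shape_spec")
}

# radial function of a star-convex blob
blob_radius <- function(shape, phi) {
  s <- rep(0, length(phi))
  for (k in seq_along(shape$amp)) {
    s <- s + shape$amp[k] * cos((k + 1) * phi + shape$phase[k])
  }
  shape$radius * (1 + shape$jitter * s)
}

# dense boundary sample of any shape, (row, col) continuous coordinates
shape_boundary <- function(shape, n = 720L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  switch(shape$kind,
    ellipse = {
      th <- shape$angle * pi / 180
      x <- shape$a * cos(phi)
      y <- shape$b * sin(phi)
      cbind(row = shape$center[1L] + x * sin(th) + y * cos(th),
            col = shape$center[2L] + x * cos(th) - y * sin(th))
    },
    polygon = cbind(row = shape$vertices[, 1L], col = shape$vertices[, 2L]),
    blob = {
      r <- blob_radius(shape, phi)
      cbind(row = shape$center[1L] + r * sin(phi),
            col = shape$center[2L] + r * cos(phi))
    }
  )
}

shape_truth <- function(shape) {
  b <- shape_boundary(shape)
  diam <- switch(shape$kind,
    ellipse = 2 * max(shape$a, shape$b),
    polygon = max(stats::dist(shape$vertices)),
    blob = max(stats::dist(b))
  )
  area <- switch(shape$kind,
    ellipse = pi * shape$a * shape$b,
    polygon = shoelace_area(shape$vertices),
    blob = {
      phi <- seq(0, 2 * pi, length.out = 2881L)
      r <- blob_radius(shape, phi)
      # trapezoidal 0.5 * integral r(phi)^2 dphi
      sum((r[-1L]^2 + r[-length(r)]^2) / 2 * diff(phi)) / 2
    }
  )
  list(true_diameter_px = diam, true_area_px = area)
}

shoelace_area <- function(v) {
  x <- v[, 2L]
  y <- v[, 1L]
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# logical membership of pixel centres (integer grid) for one shape
rasterize_shape <- function(shape, height, width) {
  b <- shape_boundary(shape)
  r0 <- max(1L, floor(min(b[, 1L])) - 1L)
  r1 <- min(height, ceiling(max(b[, 1L])) + 1L)
  c0 <- max(1L, floor(min(b[, 2L])) - 1L)
  c1 <- min(width, ceiling(max(b[, 2L])) + 1L)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- switch(shape$kind,
    ellipse = {
      th <- shape$angle * pi / 180
      dr <- rr - shape$center[1L]
      dc <- cc - shape$center[2L]
      u <- dc * cos(th) + dr * sin(th)
      v <- -dc * sin(th) + dr * cos(th)
      (u / shape$a)^2 + (v / shape$b)^2 <= 1
    },
    polygon = point_in_polygon(rr, cc, shape$vertices),
    blob = {
      dr <- rr - shape$center[1L]
      dc <- cc - shape$center[2L]
      phi <- atan2(dr, dc)
      sqrt(dr^2 + dc^2) <= blob_radius(shape, phi)
    }
  )
  cbind(row = rr[inside], col = cc[inside])
}

# even-odd crossing test, vectorized over query points
point_in_polygon <- function(rr, cc, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(rr))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1L]; xi <- v[i, 2L]
    yj <- v[j, 1L]; xj <- v[j, 2L]
    crosses <- ((yi > rr) != (yj > rr)) &
      (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Generate a synthetic lesion mask with known ground truth
#'
#' Rasterizes disjoint shapes onto a blank image (a pixel is foreground iff
#' its centre lies inside the continuous shape — this makes the discretized
#' maximum diameter provably within ~1.5 px of the continuous truth for the
#' tested sizes), then optionally sprinkles isolated speckle pixels (to
#' emulate segmentation noise) and punches single-pixel holes into instance
#' interiors. Everything is a pure function of the arguments and `seed`.
#'
#' @param height,width Image size in pixels.
#' @param shapes List of [shape_spec] objects; must be pairwise separated by
#'   at least 2 px, otherwise an error `"shapes overlap"` is raised.
#' @param speckle_density Per-background-pixel probability of an isolated
#'   foreground speckle (speckles never touch shapes or each other).
#' @param hole_density Per-interior-pixel probability of flipping a strictly
#'   interior foreground pixel to background.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A list with `mask` (logical matrix) and `truth`, a tibble with
#'   one row per shape: `label`, `kind`, `true_diameter_px`, `true_area_px`.
#' @examples
#' sim <- make_mask(64, 64, list(shape_ellipse(c(32, 32), 20, 10)))
#' sim$truth
#' @export
make_mask <- function(height, width, shapes, speckle_density = 0,
                      hole_density = 0, seed = 0) {
  stopifnot(height >= 1L, width >= 1L, length(shapes) >= 1L)
  stopifnot(speckle_density >= 0, speckle_density <= 1,
            hole_density >= 0, hole_density <= 1)
  if (!all(purrr::map_lgl(shapes, inherits, "shape_spec"))) {
    abort("`shapes` must be a list of shape_spec objects.")
  }
  for (s in shapes) {
    b <- shape_boundary(s)
    if (min(b[, 1L]) < 1 || max(b[, 1L]) > height ||
        min(b[, 2L]) < 1 || max(b[, 2L]) > width) {
      abort("shape does not fit inside the image")
    }
  }

  pixel_sets <- purrr::map(shapes, rasterize_shape, height = height, width = width)

  # enforce >= 2 px separation: the 1-dilation of one shape must not touch
  # another shape's pixels
  if (length(pixel_sets) > 1L) {
    occ <- matrix(0L, height, width)
    for (i in seq_along(pixel_sets)) {
      px <- pixel_sets[[i]]
      for (dr in -1:1) for (dc in -1:1) {
        r <- px[, 1L] + dr
        c <- px[, 2L] + dc
        ok <- r >= 1L & r <= height & c >= 1L & c <= width
        hit <- occ[cbind(r[ok], c[ok])]
        if (any(hit != 0L & hit != i)) abort("shapes overlap")
      }
      occ[px] <- i
    }
  }

  mask <- matrix(FALSE, height, width)
  for (px in pixel_sets) mask[px] <- TRUE

  withr::with_seed(seed, {
    if (hole_density > 0) {
      bp <- boundary_pixels(mask)
      interior <- mask
      interior[bp] <- FALSE
      idx <- which(interior)
      flip <- idx[stats::runif(length(idx)) < hole_density]
      mask[flip] <- FALSE
    }
    if (speckle_density > 0) {
      # eligible: background pixels with no foreground within Chebyshev 2,
      # so speckles stay disjoint from the shapes even after their holes
      dil <- dilate_mask(dilate_mask(mask))
      eligible <- which(!dil)
      chosen <- eligible[stats::runif(length(eligible)) < speckle_density]
      # greedy thinning keeps speckles isolated single pixels
      keep <- logical(0L)
      taken <- matrix(FALSE, height, width)
      for (i in chosen) {
        r <- ((i - 1L) %% height) + 1L
        c <- ((i - 1L) %/% height) + 1L
        nb_r <- pmax(1L, r - 1L):pmin(height, r + 1L)
        nb_c <- pmax(1L, c - 1L):pmin(width, c + 1L)
        if (!any(taken[nb_r, nb_c])) {
          taken[r, c] <- TRUE
          mask[r, c] <- TRUE
        }
      }
    }
  })

  truth <- purrr::imap_dfr(shapes, function(s, i) {
    tr <- shape_truth(s)
    tibble(label = i, kind = s$kind,
           true_diameter_px = tr$true_diameter_px,
           true_area_px = tr$true_area_px)
  })
  list(mask = mask, truth = truth)
}

dilate_mask <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    src_r <- max(1L, 1L - dr):min(h, h - dr)
    src_c <- max(1L, 1L - dc):min(w, w - dc)
    out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] | mask[src_r, src_c]
  }
  out
}

#' Generate noisy linear calibration pairs
#'
#' Emulates the endoscopy size calibration: `n` tumours photographed, pixel
#' distance `x` drawn uniformly over `x_range`, true physical distance
#' `slope * x + intercept` observed with Gaussian noise. Defaults mirror the
#' study conditions: 38 calibration tumours, slope 0.12 mm/px, intercept
#' 0.3 mm, noise sd 0.05 mm.
#'
#' @param n Number of pairs (>= 2).
#' @param slope,intercept True line parameters (mm per px, mm).
#' @param sigma Gaussian noise standard deviation on `y` (>= 0).
#' @param x_range Range of pixel distances sampled.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y`; attributes `slope`, `intercept`.
#' @export
make_calibration_pairs <- function(n = 38, slope = 0.12, intercept = 0.3,
                                   sigma = 0.05, x_range = c(20, 200),
                                   seed = 0) {
  if (n < 2L) abort("insufficient pairs")
  stopifnot(sigma >= 0, length(x_range) == 2L, x_range[2L] > x_range[1L])
  out <- withr::with_seed(seed, {
    x <- stats::runif(n, x_range[1L], x_range[2L])
    y <- slope * x + intercept + stats::rnorm(n, 0, sigma)
    tibble(x = x, y = y)
  })
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Generate a Newtonian cooling curve
#'
#' `T(t) = T_surr + (T_max - T_surr) * exp(-t / tau_s)` sampled every `dt`
#' seconds over `duration`, with optional Gaussian measurement noise.
#' Defaults mirror the study's photothermal run (ambient 26.1 C, peak
#' 53.5 C).
#'
#' @param T_surr,T_max Ambient and peak temperature, C (`T_max > T_surr`).
#' @param tau_s Time constant, s (> 0).
#' @param dt Sampling interval, s.
#' @param duration Total duration, s (>= 3 * dt).
#' @param sigma Noise sd, C.
#' @param seed Integer seed.
#' @return A trace tibble (`time_s`, `temp_C`, `phase = "cooling"`).
#' @export
make_cooling_curve <- function(T_surr = 26.1, T_max = 53.5, tau_s = 120,
                               dt = 1, duration = 600, sigma = 0, seed = 0) {
  if (!(T_max > T_surr)) abort("invalid temperature bounds")
  if (tau_s <= 0) abort("`tau_s` must be > 0.")
  if (duration < 3 * dt) abort("`duration` must be >= 3 * dt.")
  time_s <- seq(0, duration, by = dt)
  temp <- T_surr + (T_max - T_surr) * exp(-time_s / tau_s)
  if (sigma > 0) {
    temp <- withr::with_seed(seed, temp + stats::rnorm(length(temp), 0, sigma))
  }
  tibble(time_s = time_s, temp_C = temp, phase = "cooling")
}

#' Generate a first-order decay curve
#'
#' `v(t) = baseline + v0 * exp(-t * ln 2 / half_life)` with multiplicative
#' Gaussian noise of relative sd `sigma_rel` — e.g. blood-probe fluorescence
#' sampled over a day with a 3.16 h half-life.
#'
#' @param v0 Initial amplitude above baseline.
#' @param half_life Half-life (time units of `times`).
#' @param baseline Asymptotic level.
#' @param times Sampling times.
#' @param sigma_rel Relative noise sd (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `time`, `value`; attribute `half_life`.
#' @export
make_decay_curve <- function(v0 = 100, half_life = 3.16, baseline = 0,
                             times = seq(0, 24, by = 0.5), sigma_rel = 0,
                             seed = 0) {
  stopifnot(v0 > 0, half_life > 0, sigma_rel >= 0, length(times) >= 3L)
  value <- v0 * exp(-times * log(2) / half_life)
  if (sigma_rel > 0) {
    value <- withr::with_seed(
      seed, value * (1 + stats::rnorm(length(times), 0, sigma_rel)))
  }
  out <- tibble(time = times, value = baseline + value)
  attr(out, "half_life") <- half_life
  out
}

#' Generate plate and fluorescence assay tables with known truth
#'
#' Builds the CSV-ready inputs the assay module reads, each with an
#' embedded known answer:
#' \itemize{
#'   \item `hemolysis`: a plate table whose sample wells sit at
#'     `hemolysis_truth_pct` between the PBS and water controls;
#'   \item `viability`: likewise for CCK-8 viability;
#'   \item `fluorescence_curve`: a WSP-1-style standard-curve table
#'     (`concentration`, `fluorescence`) on a known line;
#'   \item `h2s_groups`: the reported intratumoural group concentrations
#'     (see [h2s_tumour_groups()]).
#' }
#'
#' @param hemolysis_truth_pct,viability_truth_pct True rates for the sample
#'   wells, percent.
#' @param od_negative,od_positive Haemolysis controls (PBS, water).
#' @param od_blank,od_control Viability controls (blank, untreated).
#' @param fluor_slope,fluor_intercept Standard-curve line (AU per mM, AU).
#' @param concentrations Standard-curve concentration levels, mM.
#' @param sigma Gaussian noise sd added to generated ODs / fluorescence.
#' @param seed Integer seed.
#' @return Named list of tibbles plus a `truth` list echoing the inputs.
#' @export
make_assay_tables <- function(hemolysis_truth_pct = 50,
                              viability_truth_pct = 87.8,
                              od_negative = 0.05, od_positive = 1.0,
                              od_blank = 0.1, od_control = 1.1,
                              fluor_slope = 100, fluor_intercept = 50,
                              concentrations = c(0, 0.5, 1, 2, 3),
                              sigma = 0, seed = 0) {
  stopifnot(sigma >= 0)
  withr::with_seed(seed, {
    noise <- function(n) if (sigma > 0) stats::rnorm(n, 0, sigma) else rep(0, n)
    hem_sample <- od_negative +
      hemolysis_truth_pct / 100 * (od_positive - od_negative)
    hemolysis <- tibble(
      well = c("A1", "A2", "A3", "B1", "B2"),
      role = c("sample", "sample", "sample", "negative", "positive"),
      od = c(rep(hem_sample, 3L) + noise(3L), od_negative, od_positive)
    )
    via_sample <- od_blank +
      viability_truth_pct / 100 * (od_control - od_blank)
    viability <- tibble(
      well = c("C1", "C2", "C3", "D1", "D2"),
      role = c("sample", "sample", "sample", "negative", "positive"),
      od = c(rep(via_sample, 3L) + noise(3L), od_blank, od_control)
    )
    fluorescence_curve <- tibble(
      concentration = concentrations,
      fluorescence = fluor_intercept + fluor_slope * concentrations +
        noise(length(concentrations))
    )
    list(
      hemolysis = hemolysis,
      viability = viability,
      fluorescence_curve = fluorescence_curve,
      h2s_groups = h2s_tumour_groups(),
      truth = list(
        hemolysis_pct = hemolysis_truth_pct,
        viability_pct = viability_truth_pct,
        fluor_slope = fluor_slope,
        fluor_intercept = fluor_intercept
      )
    )
  })
}
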