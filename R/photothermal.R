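#' Driving-force temperature ratio of a trace
#'
#' Newtonian cooling towards ambient is linear in the dimensionless ratio
#' `theta = (T - T_surr) / (T_max - T_surr)`: 1 at the peak temperature, 0 at
#' ambient. Samples at or below ambient (`theta <= 0`) are flagged rather
#' than dropped, so the caller can see how much of the tail is unusable.
#'
#' @param trace Data frame with columns `time_s` and `temp_C` (an optional
#'   `phase` column is carried through).
#' @param T_surr,T_max Ambient and peak temperature, degrees C;
#'   `T_max > T_surr` required.
#' @return Tibble with `time_s`, `theta`, `flagged`.
#' @export
normalize_theta <- function(trace, T_surr, T_max) {
  trace <- validate_trace(trace)
  if (!(T_max > T_surr)) abort("invalid temperature bounds")
  theta <- (trace$temp_C - T_surr) / (T_max - T_surr)
  tibble(time_s = trace$time_s, theta = theta, flagged = theta <= 0)
}

validate_trace <- function(trace, min_n = 3L) {
  if (!is.data.frame(trace)) abort("`trace` must be a data frame.")
  need <- c("time_s", "temp_C")
  if (!all(need %in% names(trace))) {
    if (ncol(trace) >= 2L) {
      names(trace)[1:2] <- need
    } else abort("`trace` needs columns time_s and temp_C.")
  }
  if (nrow(trace) < min_n) {
    abort(paste0("trace needs at least ", min_n, " samples"))
  }
  if (any(diff(trace$time_s) <= 0)) abort("time must be strictly increasing")
  as_tibble(trace)
}

#' Fit the cooling time constant
#'
#' During passive cooling, elapsed time obeys `t = tau * (-ln theta)`, so the
#' time constant is the slope of cooling time regressed on `-ln theta`. Time
#' is re-zeroed at the start of the cooling trace (where `theta = 1`), and
#' the regression is through the origin by default, matching that boundary
#' condition; `through_origin = FALSE` frees the intercept when the start of
#' cooling is uncertain.
#'
#' Samples with `theta` outside `(theta_min, 1]` are excluded: near-ambient
#' points make `-ln theta` blow up and would dominate the fit. A warning is
#' issued when `theta` rises by more than 0.05 between consecutive retained
#' samples (non-monotone cooling beyond noise).
#'
#' @inheritParams normalize_theta
#' @param theta_min Lower usability cut for `theta` (default 0.05).
#' @param through_origin Fit `t ~ 0 + (-ln theta)` (default) or with a free
#'   intercept.
#' @return A `time_constant_fit`: `tau_s`, `r2`, `n_used`, and the working
#'   table (`time_s`, `theta`, `neg_log_theta`, `used`).
#' @export
fit_time_constant <- function(trace, T_surr, T_max, theta_min = 0.05,
                              through_origin = TRUE) {
  trace <- validate_trace(trace)
  if ("phase" %in% names(trace)) {
    trace <- dplyr::filter(trace, .data$phase == "cooling")
    if (nrow(trace) < 3L) abort("insufficient cooling data")
  }
  if (!(T_max > T_surr)) abort("invalid temperature bounds")

  t0 <- trace$time_s - trace$time_s[[1L]]
  theta <- (trace$temp_C - T_surr) / (T_max - T_surr)
  used <- theta > theta_min & theta <= 1

  if (sum(used) < 3L || sum(theta[used] < 1) < 2L) {
    abort("insufficient cooling data")
  }
  if (any(diff(theta[used]) > 0.05)) {
    warn("theta increases by more than 0.05 between consecutive samples; is this really a cooling trace?")
  }

  x <- -log(theta[used])
  y <- t0[used]
  fit <- if (through_origin) lm(y ~ 0 + x) else lm(y ~ x)
  tau <- unname(coef(fit)[["x"]])
  r2 <- r_squared_lm(fit, y, uncentered = through_origin)

  structure(
    list(
      tau_s = tau,
      r2 = r2,
      n_used = sum(used),
      through_origin = through_origin,
      data = tibble(time_s = t0, theta = theta,
                    neg_log_theta = -log(pmax(theta, .Machine$double.xmin)),
                    used = used)
    ),
    class = "time_constant_fit"
  )
}

#' @export
print.time_constant_fit <- function(x, ...) {
  cat("<time_constant_fit> tau = ", format(x$tau_s, digits = 6), " s, R^2 = ",
      format(x$r2, digits = 4), " (", x$n_used, " samples)\n", sep = "")
  invisible(x)
}

#' @rdname fit_time_constant
#' @param x A `time_constant_fit`.
#' @param ... Unused.
#' @export
glance.time_constant_fit <- function(x, ...) {
  tibble(tau_s = x$tau_s, r.squared = x$r2, nobs = x$n_used)
}

#' Photothermal conversion efficiency
#'
#' Energy-balance efficiency of converting absorbed near-infrared laser
#' power into heat:
#' \deqn{\eta = \frac{hS\,(T_{max} - T_{surr}) - Q_{dis}}{I\,(1 - 10^{-A_{808}})}}
#' where the lumped heat-transfer term is `hs = m * c / tau_s` (never
#' separated into coefficient and area), `Q_dis` is the baseline heat input
#' of solvent and container, `I` the incident laser power and `A_808` the
#' absorbance at the laser wavelength. Supply either `hs` directly
#' (mW per degree C) or the triple (`m` in g, `c` in J/(g*C), `tau_s` in s);
#' `m*c/tau_s` is in W per degree C and is converted to mW.
#'
#' @param T_max,T_surr Peak and ambient temperature, degrees C
#'   (`T_max >= T_surr`).
#' @param A_808 Absorbance at 808 nm (> 0).
#' @param I Incident laser power (> 0), in `I_units`.
#' @param m Sample mass, g.
#' @param c Specific heat capacity, J/(g*C).
#' @param tau_s Cooling time constant, s (see [fit_time_constant()]).
#' @param hs Lumped heat-transfer term, mW per degree C; overrides
#'   `m`, `c`, `tau_s` when given.
#' @param Q_dis Baseline heat input, mW (default 0: no solvent-blank run).
#' @param I_units `"mW"` (default) or `"W"`.
#' @param theta_fit_r2,n_points_used Optional provenance from the time
#'   constant fit, carried into the result.
#' @return An `efficiency_result`: `eta` (fraction), `tau_s`, `hs` (mW/C),
#'   `theta_fit_r2`, `n_points_used` and `warning_flag` (TRUE when `eta`
#'   falls outside [0, 1]; the value is still reported).
#' @examples
#' conversion_efficiency(T_max = 53.5, T_surr = 26.1, A_808 = 1.31, I = 600,
#'                       m = 0.3, c = 1.96, tau_s = 120)
#' @export
conversion_efficiency <- function(T_max, T_surr, A_808, I,
                                  m = NULL, c = NULL, tau_s = NULL, hs = NULL,
                                  Q_dis = 0, I_units = c("mW", "W"),
                                  theta_fit_r2 = NA_real_,
                                  n_points_used = NA_integer_) {
  I_units <- match.arg(I_units)
  if (I <= 0 || A_808 <= 0) abort("invalid optical parameters")
  if (T_max < T_surr) abort("invalid temperature bounds")
  if (Q_dis < 0) abort("`Q_dis` must be >= 0.")
  if (is.null(hs)) {
    if (is.null(m) || is.null(c) || is.null(tau_s)) {
      abort("supply `hs` or all of `m`, `c`, `tau_s`")
    }
    if (tau_s <= 0) abort("`tau_s` must be > 0.")
    hs <- m * c / tau_s * 1000 # W/C -> mW/C
  }
  I_mW <- if (I_units == "W") I * 1000 else I

  eta <- (hs * (T_max - T_surr) - Q_dis) / (I_mW * (1 - 10^(-A_808)))
  flag <- eta < 0 || eta > 1
  if (flag) warn(paste0("efficiency eta = ", format(eta, digits = 4),
                        " falls outside [0, 1]; check inputs"))

  structure(
    list(eta = eta, tau_s = tau_s %||% NA_real_, hs = hs, Q_dis = Q_dis,
         theta_fit_r2 = theta_fit_r2, n_points_used = n_points_used,
         warning_flag = flag),
    class = "efficiency_result"
  )
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat("<efficiency_result> eta = ", format(100 * x$eta, digits = 4), "%",
      if (x$warning_flag) "  [outside 0-100%]", "\n",
      "  hs = ", format(x$hs, digits = 4), " mW/C",
      if (is.finite(x$tau_s)) paste0(", tau = ", format(x$tau_s, digits = 4), " s"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname conversion_efficiency
#' @param x An `efficiency_result`.
#' @param ... Unused.
#' @export
glance.efficiency_result <- function(x, ...) {
  tibble(eta = x$eta, tau_s = x$tau_s, hs = x$hs, Q_dis = x$Q_dis,
         theta.fit.r2 = x$theta_fit_r2, n.points = x$n_points_used,
         warning = x$warning_flag)
}

#' End-to-end efficiency from a cooling trace
#'
#' Convenience wrapper: fits the time constant from the cooling trace, forms
#' `hs = m * c / tau`, and evaluates the efficiency formula. When a solvent
#' blank cooling run is supplied, `Q_dis` is estimated from it as
#' `hs_blank * (T_max_blank - T_surr)`.
#'
#' @inheritParams fit_time_constant
#' @inheritParams conversion_efficiency
#' @param blank Optional solvent-blank cooling trace (same columns), with
#'   attributes `T_max` implied by its own maximum temperature.
#' @param m_blank,c_blank Mass and heat capacity of the blank run (default:
#'   same as the sample).
#' @return An `efficiency_result` (see [conversion_efficiency()]).
#' @export
photothermal_efficiency <- function(trace, T_surr, T_max, A_808, I, m, c,
                                    Q_dis = NULL, blank = NULL,
                                    m_blank = m, c_blank = c,
                                    theta_min = 0.05, I_units = c("mW", "W")) {
  fit <- fit_time_constant(trace, T_surr = T_surr, T_max = T_max,
                           theta_min = theta_min)
  if (is.null(Q_dis)) {
    Q_dis <- if (is.null(blank)) 0 else {
      blank <- validate_trace(blank)
      T_max_blank <- max(blank$temp_C)
      bfit <- fit_time_constant(blank, T_surr = T_surr, T_max = T_max_blank,
                                theta_min = theta_min)
      hs_blank <- m_blank * c_blank / bfit$tau_s * 1000
      hs_blank * (T_max_blank - T_surr)
    }
  }
  conversion_efficiency(
    T_max = T_max, T_surr = T_surr, A_808 = A_808, I = I,
    m = m, c = c, tau_s = fit$tau_s, Q_dis = Q_dis, I_units = I_units,
    theta_fit_r2 = fit$r2, n_points_used = fit$n_used
  )
}

#' Fit a single-exponential decay (half-life)
#'
#' Log-linear least squares for first-order clearance,
#' `v(t) = baseline + v0 * exp(-t / tau)`: regress `ln(value - baseline)` on
#' time; `tau = -1/slope` and `half_life = tau * ln 2`. Used for blood
#' clearance of circulating probe. Samples at or below baseline are excluded
#' (their logarithm is undefined).
#'
#' @param samples Data frame whose first two columns (or columns `time`,
#'   `value`) are sampling time and measured signal.
#' @param baseline Signal level the decay approaches (default 0).
#' @return A `decay_fit`: `tau`, `half_life`, `r2`, `n_used` (time units
#'   follow the input).
#' @examples
#' fit_exponential_decay(data.frame(time = 0:5, value = 10 * exp(-(0:5) / 2)))
#' @export
fit_exponential_decay <- function(samples, baseline = 0) {
  if (is.matrix(samples)) samples <- as.data.frame(samples)
  if (!is.data.frame(samples) || ncol(samples) < 2L) {
    abort("`samples` must be a data frame with time and value columns.")
  }
  nm <- names(samples)
  time <- as.numeric(if ("time" %in% nm) samples$time else samples[[1L]])
  value <- as.numeric(if ("value" %in% nm) samples$value else samples[[2L]])

  keep <- is.finite(time) & is.finite(value) & (value > baseline)
  if (sum(keep) < 3L) abort("insufficient decay data")
  time <- time[keep]
  value <- value[keep]

  fit <- lm(log(value - baseline) ~ time)
  slope <- unname(coef(fit)[["time"]])
  if (slope >= 0) warn("no decay detected: fitted rate is non-negative")
  tau <- -1 / slope
  structure(
    list(tau = tau, half_life = tau * log(2),
         r2 = r_squared_lm(fit, log(value - baseline)), n_used = sum(keep),
         baseline = baseline,
         data = tibble(time = time, value = value)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> half-life = ", format(x$half_life, digits = 4),
      ", tau = ", format(x$tau, digits = 4),
      ", R^2 = ", format(x$r2, digits = 4),
      " (", x$n_used, " samples)\n", sep = "")
  invisible(x)
}

#' @rdname fit_exponential_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(tau = x$tau, half.life = x$half_life, r.squared = x$r2,
         nobs = x$n_used)
}

# coefficient of determination without summary.lm's perfect-fit warning;
# uncentered SST for through-origin fits (summary.lm's convention)
r_squared_lm <- function(fit, y, uncentered = FALSE) {
  sse <- sum(stats::residuals(fit)^2)
  sst <- if (uncentered) sum(y^2) else sum((y - mean(y))^2)
  if (sst == 0) return(as.numeric(sse <= 1e-300))
  1 - sse / sst
}

#' Temperature rise at a time point
#'
#' Linearly interpolated temperature at `at_time_s` minus the temperature at
#' the start of the trace — e.g. the temperature rise after 5 minutes of
#' irradiation.
#'
#' @inheritParams normalize_theta
#' @param at_time_s Query time, seconds; must lie within the trace span.
#' @return Temperature change in degrees C.
#' @export
delta_T <- function(trace, at_time_s) {
  trace <- validate_trace(trace, min_n = 2L)
  if (at_time_s < min(trace$time_s) || at_time_s > max(trace$time_s)) {
    abort("time outside trace")
  }
  approx(trace$time_s, trace$temp_C, xout = at_time_s)$y - trace$temp_C[[1L]]
}

#' Read a temperature trace from CSV
#'
#' Expects columns `time_s,temp_C[,phase]` (header row); extra columns are
#' ignored.
#'
#' @param path CSV path.
#' @return A trace tibble.
#' @export
read_trace <- function(path) {
  validate_trace(readr::read_csv(path, show_col_types = FALSE))
}
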