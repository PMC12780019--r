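#' Haemolysis rate from plate absorbances
#'
#' Normalized erythrocyte lysis signal,
#' `(OD_sample - OD_PBS) / (OD_water - OD_PBS) * 100`, where the PBS well is
#' the negative (0%) control and ultrapure water the positive (100%)
#' control. Values outside 0-100% (measurement noise) are reported with a
#' warning, not clipped. All arguments are vectorized.
#'
#' @param od_sample Sample absorbance.
#' @param od_negative Negative-control (PBS) absorbance.
#' @param od_positive Positive-control (water) absorbance.
#' @return Haemolysis rate in percent.
#' @examples
#' hemolysis_rate(0.525, 0.05, 1.0)
#' @export
hemolysis_rate <- function(od_sample, od_negative, od_positive) {
  check_finite(od_sample, od_negative, od_positive)
  if (any(od_positive == od_negative)) abort("degenerate controls")
  rate <- (od_sample - od_negative) / (od_positive - od_negative) * 100
  if (any(rate < 0 | rate > 100)) {
    warn("haemolysis rate outside [0, 100]%: check controls / noise")
  }
  rate
}

#' Cell viability from plate absorbances
#'
#' `(OD_experimental - OD_blank) / (OD_control - OD_blank) * 100`, the
#' standard CCK-8 readout: the blank well (medium only) is 0%, the untreated
#' control is 100%. Vectorized.
#'
#' @param od_sample Treated-well absorbance.
#' @param od_blank Blank (medium-only) absorbance.
#' @param od_control Untreated-control absorbance.
#' @return Viability in percent.
#' @examples
#' cell_viability(0.978, 0.1, 1.1)
#' @export
cell_viability <- function(od_sample, od_blank, od_control) {
  check_finite(od_sample, od_blank, od_control)
  if (any(od_control == od_blank)) abort("degenerate controls")
  (od_sample - od_blank) / (od_control - od_blank) * 100
}

#' Mass fraction of a component
#'
#' `component_mass / total_mass * 100`, reported to 4 significant figures
#' (the convention used for composition percentages such as cobalt or
#' peptide content of a freeze-dried nanoplatform). Set `digits = Inf` for
#' full precision.
#'
#' @param component_mass Component mass (same unit as `total_mass`, >= 0).
#' @param total_mass Total mass (> 0).
#' @param digits Significant figures for reporting (default 4).
#' @return Mass fraction in percent.
#' @examples
#' mass_fraction(0.8076, 4.75)
#' @export
mass_fraction <- function(component_mass, total_mass, digits = 4) {
  check_finite(component_mass, total_mass)
  if (any(total_mass <= 0)) abort("invalid total")
  if (any(component_mass < 0)) abort("`component_mass` must be >= 0.")
  out <- component_mass / total_mass * 100
  if (is.finite(digits)) signif(out, digits) else out
}

#' Reduction rate relative to a control
#'
#' `(control - treated) / control * 100`: the fraction of the control-group
#' concentration removed by a treatment. Used for intratumoural H2S
#' depletion and equally for metabolic elimination of cobalt. Vectorized.
#'
#' @param control Control-group concentration (> 0).
#' @param treated Treated-group concentration (>= 0).
#' @return Reduction in percent (0-100 whenever `0 <= treated <= control`).
#' @examples
#' reduction_rate(2.8, 1.27)
#' @export
reduction_rate <- function(control, treated) {
  check_finite(control, treated)
  if (any(control == 0)) abort("zero control")
  if (any(control < 0) || any(treated < 0)) {
    abort("concentrations must be >= 0")
  }
  (control - treated) / control * 100
}

#' Organ and tumour indices
#'
#' Gross burden metrics: organ (or tumour) weight divided by body weight,
#' times 100. Vectorized.
#'
#' @param organ_weight,tumour_weight Tissue weight, g (>= 0).
#' @param body_weight Body weight, g (> 0).
#' @return Index in percent.
#' @examples
#' organ_index(0.2, 20)
#' tumour_index(1.0, 20)
#' @export
organ_index <- function(organ_weight, body_weight) {
  check_finite(organ_weight, body_weight)
  if (any(body_weight <= 0)) abort("`body_weight` must be > 0.")
  if (any(organ_weight < 0)) abort("weights must be >= 0")
  organ_weight / body_weight * 100
}

#' @rdname organ_index
#' @export
tumour_index <- function(tumour_weight, body_weight) {
  organ_index(tumour_weight, body_weight)
}

#' Total apoptotic/necrotic fraction
#'
#' Sum of early-apoptosis, late-apoptosis and necrosis percentages from
#' flow-cytometry quadrants (commutative in its arguments). Each fraction
#' must lie in [0, 100]; a total above 100.5% (beyond rounding slack)
#' triggers a warning. Vectorized.
#'
#' @param early_pct,late_pct,necrosis_pct Quadrant percentages.
#' @return Total affected-cell percentage.
#' @examples
#' apoptosis_total(27.0, 14.5, 23)
#' @export
apoptosis_total <- function(early_pct, late_pct, necrosis_pct) {
  check_finite(early_pct, late_pct, necrosis_pct)
  fr <- c(early_pct, late_pct, necrosis_pct)
  if (any(fr < 0 | fr > 100)) abort("fractions must lie in [0, 100]")
  total <- early_pct + late_pct + necrosis_pct
  if (any(total > 100.5)) {
    warn("apoptosis fractions sum above 100.5%: check quadrant gating")
  }
  total
}

#' Quantify H2S from fluorescence signals via a standard curve
#'
#' Inverts a fluorescence-vs-concentration standard curve (e.g. the WSP-1
#' probe curve) for each group's signal. Negative inversions — signals below
#' the curve intercept — are floored at 0 with a warning, since a negative
#' concentration is unphysical.
#'
#' @param signals Data frame with columns `group` and `fluorescence` (or the
#'   first two columns are used).
#' @param curve A `calibration_model` fitted as fluorescence ~ concentration.
#' @return Tibble with `group`, `concentration`, `floored`.
#' @export
quantify_h2s <- function(signals, curve) {
  if (!is.data.frame(signals) || ncol(signals) < 2L) {
    abort("`signals` must be a data frame with group and fluorescence columns.")
  }
  nm <- names(signals)
  group <- if ("group" %in% nm) signals$group else signals[[1L]]
  fl <- as.numeric(if ("fluorescence" %in% nm) signals$fluorescence else signals[[2L]])
  conc <- invert_calibration(curve, fl)
  floored <- conc < 0
  if (any(floored)) {
    warn("negative concentration(s) floored at 0 (signal below curve intercept)")
    conc[floored] <- 0
  }
  tibble(group = group, concentration = conc, floored = floored)
}

#' Reduction rates of all groups against a control group
#'
#' @param groups Data frame with columns `group` and a concentration column
#'   (the first numeric column is used).
#' @param control Name of the control group (default `"PBS"`).
#' @return The input plus a `reduction_pct` column (the control row reads 0).
#' @examples
#' reduction_table(h2s_tumour_groups())
#' @export
reduction_table <- function(groups, control = "PBS") {
  stopifnot(is.data.frame(groups), "group" %in% names(groups))
  num_col <- names(groups)[purrr::map_lgl(groups, is.numeric)][1L]
  if (is.na(num_col)) abort("`groups` needs a numeric concentration column.")
  ctrl <- groups[[num_col]][groups$group == control]
  if (length(ctrl) != 1L) abort(paste0("control group not found: ", control))
  dplyr::mutate(as_tibble(groups),
                reduction_pct = reduction_rate(ctrl, .data[[num_col]]))
}

#' Reported intratumoural H2S concentrations by treatment group
#'
#' The study's WSP-1-quantified intratumoural H2S concentrations after each
#' treatment, in mM — bundled as a fixture for worked examples and for
#' recomputing the depletion statistics.
#'
#' @return Tibble with `group` and `concentration_mM`.
#' @export
h2s_tumour_groups <- function() {
  tibble(
    group = c("PBS", "NIR", "MCC", "MCC+NIR", "PfCC+NIR"),
    concentration_mM = c(2.8, 2.5, 1.27, 0.98, 0.676)
  )
}

check_finite <- function(...) {
  vals <- c(...)
  if (!all(is.finite(vals))) abort("inputs must be finite numbers")
  invisible(TRUE)
}

#' Rates from a plate table
#'
#' Computes haemolysis or viability rates from a long plate table with one
#' row per well: columns `well`, `role` (one of `sample`, `negative`,
#' `positive`) and `od`. Control wells of each role are averaged first.
#'
#' @param plate Plate data frame (`well`, `role`, `od`).
#' @param statistic `"hemolysis"` or `"viability"` (for viability the
#'   `negative` role is the blank and `positive` the untreated control).
#' @return Tibble of sample wells with a `rate_pct` column.
#' @export
plate_rates <- function(plate, statistic = c("hemolysis", "viability")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("well", "role", "od") %in% names(plate)))
  bad <- setdiff(unique(plate$role), c("sample", "negative", "positive"))
  if (length(bad)) abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  neg <- mean(plate$od[plate$role == "negative"])
  pos <- mean(plate$od[plate$role == "positive"])
  if (!is.finite(neg) || !is.finite(pos)) abort("plate needs negative and positive control wells")
  samp <- dplyr::filter(as_tibble(plate), .data$role == "sample")
  rate <- if (statistic == "hemolysis") {
    hemolysis_rate(samp$od, neg, pos)
  } else {
    cell_viability(samp$od, neg, pos)
  }
  dplyr::mutate(samp, rate_pct = rate)
}
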