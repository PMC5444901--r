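#' Fit a light-transmission decay model to slice measurements
#'
#' Fits the transmission fraction (transmitted / incident laser power)
#' against cortical-tissue thickness. Two model forms are available:
#' a single exponential `exp(-z / lambda)` and an exponential with
#' geometric cone spread `exp(-z / lambda) / (1 + z / z0)^2`. Both satisfy
#' transmission(0) = 1 and are monotone non-increasing.
#'
#' @param thickness_mm tissue thicknesses in mm (>= 4 points).
#' @param fraction measured transmission fractions in (0, 1].
#' @param model `"exponential"` or `"geom_exponential"`.
#' @return object of class `"updown_decay_model"`: `model`, `coef`,
#'   `residual_norm`, and `transmission(z)`.
#' @export
fit_transmission <- function(thickness_mm, fraction,
                             model = c("exponential", "geom_exponential")) {
  model <- match.arg(model)
  if (length(thickness_mm) < 4) stop("need at least 4 measurement points")
  if (any(fraction <= 0 | fraction > 1)) stop("fractions must be in (0, 1]")
  if (any(diff(fraction[order(thickness_mm)]) > 0.2)) {
    warning("transmission data grossly non-monotone; fit returned anyway")
  }
  lam0 <- -1 / stats::coef(stats::lm(log(fraction) ~ 0 + thickness_mm))[1]
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- max(thickness_mm)
  ctl <- stats::nls.control(maxiter = 500, minFactor = 1e-8, warnOnly = TRUE)
  if (model == "exponential") {
    fit <- stats::nls(fraction ~ exp(-thickness_mm / lambda),
                      start = list(lambda = lam0), control = ctl)
    cf <- stats::coef(fit)
    trans <- function(z) exp(-z / cf[["lambda"]])
  } else {
    fit <- stats::nls(
      fraction ~ exp(-thickness_mm / lambda) / (1 + thickness_mm / z0)^2,
      start = list(lambda = lam0 * 2, z0 = max(thickness_mm)),
      control = ctl
    )
    cf <- stats::coef(fit)
    trans <- function(z) exp(-z / cf[["lambda"]]) / (1 + z / cf[["z0"]])^2
  }
  structure(
    list(model = model, coef = as.list(cf),
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         transmission = trans),
    class = "updown_decay_model"
  )
}

#' Maximal depth of effective optogenetic modulation
#'
#' Solves `transmission(z) = min_power / surface_power` for the depth `z` at
#' which the light intensity falls to the minimal power needed to modulate
#' the targeted interneurons, by bisection to 1e-6 mm.
#'
#' @param decay an `"updown_decay_model"` (or any list with a
#'   `transmission` function).
#' @param surface_power_mW laser power at the tissue surface (I at z = 0).
#' @param min_power_mW minimal effective power (I_z).
#' @param z_max search upper bound in mm.
#' @return depth in mm (0 when the ratio is >= 1).
#' @export
max_depth <- function(decay, surface_power_mW, min_power_mW, z_max = 20) {
  ratio <- min_power_mW / surface_power_mW
  if (ratio >= 1) return(0)
  f <- function(z) decay$transmission(z) - ratio
  if (f(z_max) > 0) stop("transmission does not fall below the ratio by z_max")
  stats::uniroot(f, c(0, z_max), tol = 1e-6)$root
}

#' Volume of the illuminated cone frustum
#'
#' Truncated-cone volume of the tissue illuminated by an optical fiber:
#' base radius `radius_mm` (fiber radius), half-angle `asin(NA)`, height the
#' maximal modulation depth:
#' `V = pi * h / 3 * (r0^2 + r0 * r1 + r1^2)` with
#' `r1 = r0 + h * tan(asin(NA))`. With `NA = 0` this reduces exactly to a
#' cylinder.
#'
#' @param radius_mm fiber radius in mm (0.1 for a 200 um fiber).
#' @param na numerical aperture of the fiber (0.22).
#' @param depth_mm frustum height in mm (>= 0).
#' @return volume in mm^3.
#' @export
frustum_volume <- function(radius_mm = 0.1, na = 0.22, depth_mm) {
  stopifnot(depth_mm >= 0, na >= 0, na < 1, radius_mm > 0)
  r1 <- radius_mm + depth_mm * tan(asin(na))
  pi * depth_mm / 3 * (radius_mm^2 + radius_mm * r1 + r1^2)
}

#' Number of labelled cells in an illuminated volume
#'
#' Stereological count from planar density: `T = N * V / t` where `N` is the
#' planar cell density (cells per mm^2 of section), `V` the volume in mm^3
#' and `t` the section thickness in mm; multiplied by the double-labelled
#' (opsin-positive) fraction.
#'
#' @param density_mm2 labelled cells per mm^2 of section.
#' @param volume_mm3 volume in mm^3.
#' @param thickness_mm section thickness in mm (0.04 for 40 um sections).
#' @param double_label_fraction fraction of labelled cells that express the
#'   opsin, in \[0, 1\].
#' @return list with `exact` and `count` (rounded to nearest integer).
#' @export
cells_in_volume <- function(density_mm2, volume_mm3, thickness_mm = 0.04,
                            double_label_fraction = 1) {
  stopifnot(density_mm2 >= 0, thickness_mm > 0,
            double_label_fraction >= 0, double_label_fraction <= 1)
  exact <- density_mm2 * volume_mm3 / thickness_mm * double_label_fraction
  list(exact = exact, count = round(exact))
}

#' Endogenous spikes interfered with per state
#'
#' Expected number of action potentials the optogenetic manipulation
#' interferes with in one state: the number of opsin-positive cells in the
#' illuminated volume times the probability that a cell is active in a
#' state times the mean number of spikes per active state.
#'
#' @param n_cells number of opsin-positive cells.
#' @param p_active_state probability a cell is active in a given state.
#' @param spikes_per_active_state mean spikes per active state.
#' @return expected spikes per state.
#' @export
expected_interfered_spikes <- function(n_cells, p_active_state,
                                       spikes_per_active_state) {
  stopifnot(n_cells >= 0, p_active_state >= 0, spikes_per_active_state >= 0)
  n_cells * p_active_state * spikes_per_active_state
}
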