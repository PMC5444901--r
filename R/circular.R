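#' Circular statistics for spike phases
#'
#' Small self-contained set of circular routines used by the phase-locking
#' analyses. All interfaces use degrees in `[0, 360)`.
#'
#' @param angles numeric vector of angles in degrees.
#' @name circular_stats
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Mean resultant length and circular mean (degrees).
# @noRd
circ_resultant <- function(angles) {
  a <- deg2rad(angles)
  c_ <- mean(cos(a)); s_ <- mean(sin(a))
  list(r = sqrt(c_^2 + s_^2), mean = rad2deg(atan2(s_, c_)) %% 360)
}

#' @rdname circular_stats
#' @return `circ_mean()`: circular mean in degrees; `circ_var()`: circular
#'   variance `1 - R` where `R` is the mean resultant length.
#' @export
circ_mean <- function(angles) circ_resultant(angles)$mean

#' @rdname circular_stats
#' @export
circ_var <- function(angles) 1 - circ_resultant(angles)$r

# Signed circular difference a - b in (-180, 180].
# @noRd
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Rayleigh test of circular uniformity
#'
#' Tests departure from uniformity of an angular distribution from the mean
#' resultant length, using the standard finite-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` (Zar), where
#' `Rn = n * Rbar`.
#'
#' @param angles angles in degrees; at least 10 values.
#' @return a list with `r` (mean resultant length), `n`, `statistic`
#'   (`Z = n * Rbar^2`) and `p.value`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 10) stop("Rayleigh test requires at least 10 angles")
  rbar <- circ_resultant(angles)$r
  Rn <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(r = rbar, n = n, statistic = n * rbar^2, p.value = min(1, p))
}

# Circular quantile of signed deviations (type-1 / order-statistic).
# @noRd
.ord_quantile <- function(x, p) {
  x <- sort(x)
  x[pmin(length(x), pmax(1L, ceiling(p * length(x))))]
}

#' Circular median and interquartile range
#'
#' The circular median minimises the mean circular absolute deviation
#' (ties broken by the smallest angle in `[0, 360)`). The IQR is the
#' difference between the 75th and 25th order-statistic percentiles of the
#' signed deviations measured along the circle from the median.
#'
#' @param angles angles in degrees; at least 10 for [preferred_phase()].
#' @return `circ_median()`: the median angle; [preferred_phase()]: list with
#'   `median_deg` and `iqr_deg`.
#' @export
circ_median <- function(angles) {
  n <- length(angles)
  cand <- if (n <= 3000) sort(unique(angles %% 360)) else seq(0, 359.9, by = 0.1)
  best <- Inf; best_a <- cand[1]
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, length(cand), by = chunk)) {
    cc <- cand[s:min(length(cand), s + chunk - 1)]
    d <- abs(outer(angles %% 360, cc, circ_diff))
    m <- colMeans(d)
    i <- which.min(m)
    # strict improvement keeps the smallest candidate angle on ties
    if (m[i] < best - 1e-12) { best <- m[i]; best_a <- cc[i] }
  }
  best_a
}

#' @rdname circ_median
#' @export
preferred_phase <- function(angles) {
  if (length(angles) < 10) stop("need at least 10 spike phases")
  med <- circ_median(angles)
  dev <- circ_diff(angles, med)
  iqr <- .ord_quantile(dev, 0.75) - .ord_quantile(dev, 0.25)
  list(median_deg = med %% 360, iqr_deg = iqr)
}

#' Circular-linear correlation
#'
#' Correlation between an angle and a linear variable, computed as the
#' square root of the R-squared of regressing the value on
#' `(sin(theta), cos(theta))`; significance via the chi-squared
#' approximation `n * r^2 ~ chisq(2)`.
#'
#' @param angles angles in degrees.
#' @param values numeric vector, same length, non-constant.
#' @return list with `r` and `p.value`.
#' @export
circ_linear_corr <- function(angles, values) {
  if (length(angles) != length(values) || length(angles) < 5) {
    stop("need at least 5 paired observations")
  }
  if (stats::sd(values) == 0) stop("values are constant: correlation undefined")
  a <- deg2rad(angles)
  fit <- stats::lm(values ~ sin(a) + cos(a))
  r2 <- max(0, 1 - sum(stats::resid(fit)^2) /
              sum((values - mean(values))^2))
  n <- length(values)
  list(r = sqrt(r2), p.value = stats::pchisq(n * r2, df = 2, lower.tail = FALSE))
}

#' Draw von Mises distributed angles
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives the uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    m <- n - i + 1L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      k <- sum(ok)
      out[i:(i + k - 1)] <- (rad2deg(th + mu_r)) %% 360
      i <- i + k
    }
  }
  out
}

# von Mises density scaled to max 1 (used as a thinning profile).
# @noRd
vm_profile <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - mu_deg)) - 1))
}
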