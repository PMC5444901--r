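#' Anti-alias filter and decimate a raw trace to 1 kHz
#'
#' Low-pass filters below 500 Hz with a second-order elliptic filter (0.1 dB
#' peak-to-peak passband ripple, 40 dB stopband attenuation) and decimates by
#' `round(fs / target_fs)`. The filter is applied in a single forward pass;
#' its group delay at a 500 Hz corner is well below one sample of the
#' decimated signal.
#'
#' @param raw_lfp a [trace()] with `fs >= 2 * target_fs`.
#' @param target_fs output sampling rate, default 1000 Hz.
#' @return the filtered, decimated [trace()].
#' @export
lowpass_downsample <- function(raw_lfp, target_fs = 1000) {
  stopifnot(inherits(raw_lfp, "updown_trace"))
  if (raw_lfp$fs < 2 * target_fs) {
    stop("input sampling rate must be at least ", 2 * target_fs, " Hz")
  }
  k <- round(raw_lfp$fs / target_fs)
  flt <- signal::ellip(2, Rp = 0.1, Rs = 40, W = (target_fs / 2) / (raw_lfp$fs / 2))
  y <- signal::filter(flt, raw_lfp$samples)
  idx <- seq(1L, length(y), by = k)
  trace(as.numeric(y)[idx], fs = raw_lfp$fs / k, units = raw_lfp$units,
        t0 = raw_lfp$t0)
}

# FFT-domain zero-phase band isolation with raised-cosine transition edges.
# trans = transition half-width in Hz on each corner. Returns numeric vector.
# @noRd
fft_bandpass <- function(x, fs, f_lo, f_hi, trans = NULL) {
  n <- length(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided: mirror frequency axis
  if (is.null(trans)) {
    trans <- max(0.05, 0.1 * if (f_lo > 0) f_lo else f_hi)
  }
  gain <- rep(1, n)
  if (f_lo > 0) {
    lo0 <- max(f_lo - trans, 0)
    ramp <- (freq - lo0) / (f_lo - lo0)
    gain <- gain * ifelse(freq <= lo0, 0,
                          ifelse(freq >= f_lo, 1, 0.5 - 0.5 * cos(pi * ramp)))
    gain[freq == 0] <- 0
  }
  hi1 <- f_hi + trans
  ramp <- (hi1 - freq) / (hi1 - f_hi)
  gain <- gain * ifelse(freq >= hi1, 0,
                        ifelse(freq <= f_hi, 1, 0.5 - 0.5 * cos(pi * ramp)))
  mu <- mean(x)
  Re(stats::fft(stats::fft(x - mu) * gain, inverse = TRUE)) / n +
    if (f_lo <= 0) mu else 0
}

#' Zero-phase band-pass filtering
#'
#' Isolates a frequency band with a zero-phase FFT-domain filter
#' (raised-cosine transition edges), so the phase of the filtered signal is
#' not delayed relative to the input. `band[1] = 0` gives a low-pass.
#' Zero-phase isolation matters downstream: a causal filter would bias the
#' spike/phase time-shift analysis.
#'
#' @param x a [trace()].
#' @param band numeric length-2, `(f_lo, f_hi)` in Hz with
#'   `0 <= f_lo < f_hi < fs/2`.
#' @param trans transition half-width in Hz; default 10% of the corner
#'   frequency (at least 0.05 Hz).
#' @return the filtered [trace()].
#' @examples
#' tr <- trace(sin(2 * pi * 25 * seq(0, 2, by = 1e-3)), fs = 1000)
#' bp <- bandpass(tr, c(10, 40))
#' @export
bandpass <- function(x, band, trans = NULL) {
  stopifnot(inherits(x, "updown_trace"), length(band) == 2)
  f_lo <- band[1]; f_hi <- band[2]
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi < x$fs / 2)) {
    stop("band must satisfy 0 <= f_lo < f_hi < fs/2")
  }
  trace(fft_bandpass(x$samples, x$fs, f_lo, f_hi, trans),
        fs = x$fs, units = x$units, t0 = x$t0)
}

# Analytic signal via FFT (Hilbert transform).
# @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited trace
#'
#' Band-pass filters the trace and extracts the instantaneous phase, either
#' as the angle of the Hilbert-transform analytic signal or by linear
#' interpolation between peaks (0 deg), falling zero-crossings (90 deg),
#' troughs (180 deg) and rising zero-crossings (270 deg).
#'
#' Phase convention: 0 deg at the filtered-signal peak, 180 deg at the
#' trough. With the recording polarity set so that LFP troughs correspond to
#' up states, up states occupy phases around 180 deg.
#'
#' @param x a [trace()] longer than 3 periods of the lower band corner (or
#'   of the upper corner for a low-pass band).
#' @param band numeric `(f_lo, f_hi)` in Hz; default `c(0.1, 4)`, the slow
#'   oscillation band.
#' @param method `"hilbert"` (default) or `"interpolation"`.
#' @return an object of class `"updown_phase"`: fields `phase` (degrees in
#'   `[0, 360)`), `fs`, `t0`, `band`, `method`.
#' @export
instantaneous_phase <- function(x, band = c(0.1, 4),
                                method = c("hilbert", "interpolation")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "updown_trace"))
  f_ref <- if (band[1] > 0) band[1] else band[2]
  if (trace_duration(x) < 3 / f_ref) {
    stop("trace too short: need at least 3 periods of ", f_ref, " Hz")
  }
  xb <- bandpass(x, band)$samples
  ph <- if (method == "hilbert") {
    (Arg(analytic_signal(xb)) * 180 / pi) %% 360
  } else {
    interp_phase(xb, x$fs)
  }
  phase_trace(ph, fs = x$fs, t0 = x$t0, band = band, method = method)
}

#' Construct a phase trace
#'
#' @param phase per-sample angles in degrees (wrapped to `[0, 360)`).
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @param band the `(f_lo, f_hi)` band the phase refers to.
#' @param method how the phase was obtained.
#' @return an object of class `"updown_phase"`.
#' @export
phase_trace <- function(phase, fs, t0 = 0, band = c(NA, NA),
                        method = "synthetic") {
  structure(
    list(phase = as.numeric(phase) %% 360, fs = fs, t0 = t0, band = band,
         method = method),
    class = "updown_phase"
  )
}

#' @export
print.updown_phase <- function(x, ...) {
  cat(sprintf("<PhaseTrace> %d samples @ %g Hz, band [%s, %s] Hz, method %s\n",
              length(x$phase), x$fs, format(x$band[1]), format(x$band[2]),
              x$method))
  invisible(x)
}

# Peak/zero-crossing interpolation phase (0 = peak, 90 = falling zc,
# 180 = trough, 270 = rising zc), linear between anchor points.
# @noRd
interp_phase <- function(xb, fs) {
  n <- length(xb)
  d <- diff(xb)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  troughs <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  s <- sign(xb)
  falling <- which(s[-n] > 0 & s[-1] <= 0)
  rising <- which(s[-n] < 0 & s[-1] >= 0)
  anchors <- rbind(
    data.frame(i = peaks, a = 0),
    data.frame(i = falling, a = 90),
    data.frame(i = troughs, a = 180),
    data.frame(i = rising, a = 270)
  )
  anchors <- anchors[order(anchors$i), , drop = FALSE]
  # keep only anchors whose angle advances (drop spurious extrema)
  keep <- logical(nrow(anchors))
  last <- -Inf
  unw <- numeric(nrow(anchors))
  for (k in seq_len(nrow(anchors))) {
    a <- anchors$a[k]
    cand <- a + 360 * ceiling((last - a) / 360 + 1e-9)
    if (!is.finite(last)) cand <- a
    if (cand - last < 350 || !is.finite(last)) {
      keep[k] <- TRUE
      unw[k] <- cand
      last <- cand
    }
  }
  anchors <- anchors[keep, , drop = FALSE]
  unw <- unw[keep]
  if (nrow(anchors) < 2) stop("too few oscillation landmarks for interpolation phase")
  out <- stats::approx(anchors$i, unw, xout = seq_len(n), rule = 2)$y
  out %% 360
}

#' Phase speed (rate of change of the phase)
#'
#' Unwraps the phase and differentiates it by central differences (one-sided
#' at the edges). For a pure oscillation at `f` Hz the speed is `360 * f`
#' degrees per second.
#'
#' @param phase an `"updown_phase"` object.
#' @return a [trace()] in deg/s on the same time base.
#' @export
phase_speed <- function(phase) {
  stopifnot(inherits(phase, "updown_phase"))
  u <- unwrap_deg(phase$phase)
  n <- length(u)
  sp <- numeric(n)
  if (n >= 3) sp[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) * phase$fs / 2
  sp[1] <- (u[2] - u[1]) * phase$fs
  sp[n] <- (u[n] - u[n - 1]) * phase$fs
  trace(sp, fs = phase$fs, units = "deg/s", t0 = phase$t0)
}

# Unwrap angles in degrees.
# @noRd
unwrap_deg <- function(p) {
  d <- diff(p)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(p[1], d))
}
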