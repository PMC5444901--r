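#' MUA detection configuration
#'
#' @param hp_corner high-pass corner frequency in Hz (300).
#' @param threshold_factor detection threshold in units of the noise
#'   standard deviation (5).
#' @param dead_time refractory dead time between detected events, seconds.
#' @param noise_estimator `"robust"` (median absolute deviation / 0.6745) or
#'   `"plain"` (sample SD).
#' @param polarity `"negative"` (extracellular convention) or `"positive"`.
#' @return a list of class `"updown_mua_config"`.
#' @export
mua_config <- function(hp_corner = 300, threshold_factor = 5,
                       dead_time = 0.001,
                       noise_estimator = c("robust", "plain"),
                       polarity = c("negative", "positive")) {
  stopifnot(threshold_factor > 0, hp_corner > 0, dead_time >= 0)
  structure(
    list(hp_corner = hp_corner, threshold_factor = threshold_factor,
         dead_time = dead_time,
         noise_estimator = match.arg(noise_estimator),
         polarity = match.arg(polarity)),
    class = "updown_mua_config"
  )
}

#' Detect multi-unit activity by threshold crossing
#'
#' High-pass filters the raw extracellular signal above the corner frequency
#' (zero-phase 4th-order Butterworth) and detects threshold crossings at
#' `threshold_factor` times the noise standard deviation (negative-going by
#' default), enforcing a dead time between events.
#'
#' @param raw a [trace()] with `fs >= 10` kHz.
#' @param cfg a [mua_config()].
#' @return a [spike_train()] labelled `"MUA"`.
#' @export
detect_mua <- function(raw, cfg = mua_config()) {
  if (raw$fs < 10000) stop("MUA detection requires fs >= 10 kHz")
  bf <- signal::butter(4, cfg$hp_corner / (raw$fs / 2), type = "high")
  x <- signal::filtfilt(bf, raw$samples)
  sigma <- if (cfg$noise_estimator == "robust") {
    stats::mad(x)  # MAD / 0.6745
  } else {
    stats::sd(x)
  }
  thr <- cfg$threshold_factor * sigma
  if (cfg$polarity == "negative") {
    cross <- which(x[-1] < -thr & x[-length(x)] >= -thr) + 1L
  } else {
    cross <- which(x[-1] > thr & x[-length(x)] <= thr) + 1L
  }
  times <- raw$t0 + (cross - 1) / raw$fs
  if (length(times) > 1 && cfg$dead_time > 0) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= cfg$dead_time) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  spike_train(times, cell_label = "MUA")
}

#' Peri-stimulus time histogram
#'
#' Event-aligned spike counts in fixed bins over `[-pre, post]` around each
#' event, summed across events; rates are counts divided by
#' `n_events * bin`.
#'
#' @param spikes a [spike_train()].
#' @param event_times numeric vector of alignment times in seconds.
#' @param bin bin width in seconds; must divide both span limbs.
#' @param span `c(pre, post)`: seconds before/after each event.
#' @return object of class `"updown_psth"`: `edges`, `mids`, `counts`,
#'   `rate_hz`, `n_events`.
#' @export
psth <- function(spikes, event_times, bin = 0.1, span = c(1, 1)) {
  if (!length(event_times)) stop("no alignment events")
  k_pre <- span[1] / bin; k_post <- span[2] / bin
  if (abs(k_pre - round(k_pre)) > 1e-9 || abs(k_post - round(k_post)) > 1e-9) {
    stop("bin width must divide both parts of the span")
  }
  edges <- seq(-span[1], span[2], by = bin)
  counts <- integer(length(edges) - 1)
  for (ev in event_times) {
    rel <- spikes$times - ev
    rel <- rel[rel >= -span[1] & rel < span[2]]
    if (length(rel)) {
      b <- floor((rel + span[1]) / bin) + 1L
      counts <- counts + tabulate(b, nbins = length(counts))
    }
  }
  structure(
    list(edges = edges, mids = edges[-length(edges)] + bin / 2,
         counts = counts, rate_hz = counts / (length(event_times) * bin),
         n_events = length(event_times), bin = bin),
    class = "updown_psth"
  )
}

# Hamming window.
# @noRd
hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided modified periodogram of a windowed segment, zero-padded to nfft.
# Scaled so that sum(psd) * fs / nfft = mean(x^2 * w^2) / mean(w^2)
# (power conservation for the windowed signal).
# @noRd
modified_periodogram <- function(x, fs, win, nfft) {
  xw <- x * win
  X <- stats::fft(c(xw, numeric(nfft - length(xw))))
  n_keep <- floor(nfft / 2) + 1
  p <- Mod(X[1:n_keep])^2 / (fs * sum(win^2))
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[n_keep] <- 1
  list(freq = (0:(n_keep - 1)) * fs / nfft, psd = p * scale2)
}

#' Short-time spectrogram of the LFP
#'
#' One-sided modified periodograms of Hamming-windowed segments (100 ms
#' windows shifted every 1 ms by default, FFT length 500), retaining
#' frequencies up to `fmax`.
#'
#' @param lfp a [trace()] at 1 kHz (after [lowpass_downsample()]).
#' @param window_s window length in seconds.
#' @param step_s window step in seconds.
#' @param nfft FFT length in points.
#' @param fmax highest retained frequency in Hz.
#' @return object of class `"updown_spectrogram"`: `times` (window
#'   centres), `freq`, `power` (freq x time matrix).
#' @export
spectrogram_lfp <- function(lfp, window_s = 0.1, step_s = 0.001, nfft = 500,
                            fmax = 100) {
  n_win <- round(window_s * lfp$fs)
  if (length(lfp$samples) < n_win) stop("trace shorter than one window")
  step <- max(1L, round(step_s * lfp$fs))
  win <- hamming_win(n_win)
  starts <- seq(1L, length(lfp$samples) - n_win + 1L, by = step)
  first <- modified_periodogram(lfp$samples[1:n_win], lfp$fs, win, nfft)
  keep <- first$freq <= fmax
  power <- matrix(0, sum(keep), length(starts))
  for (j in seq_along(starts)) {
    seg <- lfp$samples[starts[j]:(starts[j] + n_win - 1L)]
    power[, j] <- modified_periodogram(seg, lfp$fs, win, nfft)$psd[keep]
  }
  structure(
    list(times = lfp$t0 + (starts - 1 + (n_win - 1) / 2) / lfp$fs,
         freq = first$freq[keep], power = power),
    class = "updown_spectrogram"
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodograms of Hamming-windowed segments with 50%
#' overlap.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = floor(length(x) / 2), overlap = 0.5) {
  seg_len <- min(seg_len, length(x))
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  win <- hamming_win(seg_len)
  acc <- NULL
  for (s in starts) {
    p <- modified_periodogram(x[s:(s + seg_len - 1L)], fs, win, seg_len)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  list(freq = p$freq, psd = acc / length(starts))
}

#' Relative band power of an analysis window
#'
#' Welch PSD of the analysis window (segment length half the window, 50%
#' overlap), integrated over the requested band and normalised by the total
#' signal power of the pre-stimulus window. A blanking interval at the start
#' of each window is excluded to suppress stimulation artefacts. Because the
#' pre window normalises the integral, the result is invariant to scaling
#' the whole recording.
#'
#' @param lfp a [trace()].
#' @param window `c(t0, t1)` analysis window in seconds (>= 0.2 s).
#' @param band `c(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param pre_window `c(t0, t1)` pre-stimulus reference window.
#' @param blanking blanked interval at the start of each window, seconds.
#' @return list with `relative_power`, `band_power`, `total_pre_power`.
#' @export
band_power <- function(lfp, window, band, pre_window = window,
                       blanking = 0.01) {
  if (diff(window) < 0.2) stop("analysis window must be at least 0.2 s")
  if (band[1] < 0 || band[2] > lfp$fs / 2) stop("band outside 0..fs/2")
  cut <- function(w) {
    i0 <- time_to_index(lfp, w[1] + blanking)
    i1 <- time_to_index(lfp, w[2]) - 1L
    lfp$samples[max(1L, i0):min(length(lfp$samples), i1)]
  }
  x <- cut(window)
  xp <- cut(pre_window)
  pw <- welch_psd(x, lfp$fs, seg_len = floor(length(x) / 2))
  pp <- welch_psd(xp, lfp$fs, seg_len = floor(length(xp) / 2))
  df <- pw$freq[2] - pw$freq[1]
  in_band <- pw$freq >= band[1] & pw$freq <= band[2]
  bp <- sum(pw$psd[in_band]) * df
  total_pre <- sum(pp$psd) * (pp$freq[2] - pp$freq[1])
  list(relative_power = bp / total_pre, band_power = bp,
       total_pre_power = total_pre)
}

#' Trial window configuration
#'
#' @param pre_dur pre-stimulus window, seconds (0.1 anesthetized, 0.05
#'   awake for membrane-voltage analyses; 1.0 for spike rates).
#' @param light_dur light window, seconds (0.5 for photoinhibition).
#' @param post_dur post-stimulus window, seconds.
#' @param blanking artefact blanking at window starts, seconds (0.01).
#' @return a list of class `"updown_trial_windows"`.
#' @export
trial_windows <- function(pre_dur = 0.1, light_dur = 0.5, post_dur = 0.1,
                          blanking = 0.01) {
  stopifnot(pre_dur > 0, post_dur > 0, light_dur >= 0, blanking >= 0)
  structure(
    list(pre_dur = pre_dur, light_dur = light_dur, post_dur = post_dur,
         blanking = blanking),
    class = "updown_trial_windows"
  )
}

#' Classify a stimulation trial as delivered in an up or down state
#'
#' A trial counts as *up* if the membrane potential was stably depolarised
#' more than 10 mV above the resting potential throughout the pre-stimulus
#' window, *down* if it stayed stably within 3 mV of rest, and is discarded
#' otherwise. "Stably" means the criterion holds for at least
#' `stable_frac` of the pre-window samples.
#'
#' @param vm a [trace()] of membrane potential, mV.
#' @param rest_mV resting potential (down-state mode of the recording).
#' @param stim_time stimulus onset, seconds.
#' @param windows a [trial_windows()].
#' @param stable_frac fraction of samples that must satisfy the criterion.
#' @param up_depol,down_band the >10 mV and +-3 mV criteria.
#' @return `"up"`, `"down"` or `"discarded"`.
#' @export
classify_trial <- function(vm, rest_mV, stim_time, windows = trial_windows(),
                           stable_frac = 0.9, up_depol = 10, down_band = 3) {
  i1 <- time_to_index(vm, stim_time) - 1L
  i0 <- time_to_index(vm, stim_time - windows$pre_dur)
  if (i0 < 1 || i1 > length(vm$samples) || i1 < i0) {
    stop("pre-stimulus window unavailable in the trace")
  }
  v <- vm$samples[i0:i1]
  if (mean(v - rest_mV > up_depol) >= stable_frac) return("up")
  if (mean(abs(v - rest_mV) <= down_band) >= stable_frac) return("down")
  "discarded"
}

#' Membrane-voltage change around a stimulus
#'
#' Mean membrane potential in the pre, (optional) light and post windows and
#' the change `post - pre` (and `light - pre` when a light window is
#' configured). The first `blanking` seconds of the light and post windows
#' are excluded.
#'
#' @param vm a [trace()] in mV.
#' @param stim_time stimulus onset in seconds.
#' @param windows a [trial_windows()].
#' @return list with `pre_mean`, `light_mean` (NA when `light_dur = 0`),
#'   `post_mean`, `delta_post`, `delta_light`.
#' @export
delta_vm <- function(vm, stim_time, windows = trial_windows()) {
  seg <- function(a, b) {
    i0 <- time_to_index(vm, a); i1 <- time_to_index(vm, b) - 1L
    if (i0 < 1 || i1 > length(vm$samples) || i1 < i0) {
      stop("trial window outside the trace")
    }
    mean(vm$samples[i0:i1])
  }
  pre <- seg(stim_time - windows$pre_dur, stim_time)
  light <- if (windows$light_dur > 0) {
    seg(stim_time + windows$blanking, stim_time + windows$light_dur)
  } else {
    NA_real_
  }
  post_start <- stim_time + windows$light_dur
  post <- seg(post_start + windows$blanking, post_start + windows$post_dur)
  list(pre_mean = pre, light_mean = light, post_mean = post,
       delta_post = post - pre,
       delta_light = if (is.na(light)) NA_real_ else light - pre)
}

#' Latency of a state transition after a stimulus
#'
#' Onset is the first time after the stimulus at which the membrane
#' potential crosses a threshold of two standard deviations of the
#' pre-window baseline away from the baseline mean (above for `"up"`
#' transitions, below for `"down"`). Returns `NA` when no crossing occurs
#' within the search window.
#'
#' @param vm a [trace()] in mV.
#' @param stim_time stimulus onset, seconds.
#' @param windows a [trial_windows()] (the baseline is the pre window; the
#'   search window is the light window, or `search_dur` when given).
#' @param direction `"up"` or `"down"`.
#' @param search_dur optional search duration in seconds.
#' @param n_sd threshold in baseline standard deviations (2).
#' @return list with `latency` (seconds or NA), `threshold`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
transition_onset <- function(vm, stim_time, windows = trial_windows(),
                             direction = c("up", "down"), search_dur = NULL,
                             n_sd = 2) {
  direction <- match.arg(direction)
  i1 <- time_to_index(vm, stim_time) - 1L
  i0 <- time_to_index(vm, stim_time - windows$pre_dur)
  if (i0 < 1 || i1 < i0) stop("pre-stimulus window unavailable")
  base <- vm$samples[i0:i1]
  mu <- mean(base); sdv <- stats::sd(base)
  if (sdv == 0) {
    # noiseless baseline: any departure from the baseline mean counts
    sdv <- .Machine$double.eps
  }
  thr <- mu + if (direction == "up") n_sd * sdv else -n_sd * sdv
  dur <- if (is.null(search_dur)) windows$light_dur else search_dur
  j0 <- time_to_index(vm, stim_time)
  j1 <- min(length(vm$samples), time_to_index(vm, stim_time + dur))
  seg <- vm$samples[j0:j1]
  hit <- if (direction == "up") which(seg > thr) else which(seg < thr)
  latency <- if (length(hit)) (hit[1] - 1) / vm$fs else NA_real_
  list(latency = latency, threshold = thr, baseline_mean = mu,
       baseline_sd = stats::sd(base))
}

#' Slope of a membrane-potential transition
#'
#' Ordinary least-squares slope of the membrane potential against time over
#' the transition interval, in mV/s.
#'
#' @param vm a [trace()] in mV.
#' @param interval `c(t0, t1)` in seconds, spanning >= `min_samples`
#'   samples.
#' @param min_samples minimum number of samples (10).
#' @return the slope in mV/s.
#' @export
transition_slope <- function(vm, interval, min_samples = 10) {
  i0 <- time_to_index(vm, interval[1])
  i1 <- time_to_index(vm, interval[2])
  if (i1 - i0 + 1 < min_samples) {
    stop("transition interval must span at least ", min_samples, " samples")
  }
  tt <- (i0:i1 - 1) / vm$fs
  unname(stats::coef(stats::lm(vm$samples[i0:i1] ~ tt))[2])
}

#' Dual-channel transition lag
#'
#' Per-trial lag between the transition onsets of two simultaneously
#' recorded cells (`onset2 - onset1`); trials with a missing onset on either
#' channel are skipped and counted.
#'
#' @param onsets_ch1,onsets_ch2 numeric vectors of per-trial onsets in
#'   seconds (NA for trials without a detected onset).
#' @param hist_bin histogram bin width in seconds (e.g. 0.00025 or 0.01).
#' @return list with `lags`, `mean`, `sem`, `n`, `n_skipped`, `hist`
#'   (breaks/counts).
#' @export
channel_lag <- function(onsets_ch1, onsets_ch2, hist_bin = 0.01) {
  if (length(onsets_ch1) != length(onsets_ch2)) {
    stop("channel onset vectors must be paired (equal length)")
  }
  ok <- !is.na(onsets_ch1) & !is.na(onsets_ch2)
  lags <- onsets_ch2[ok] - onsets_ch1[ok]
  h <- if (length(lags)) {
    rng <- range(lags)
    breaks <- seq(floor(rng[1] / hist_bin) * hist_bin,
                  ceiling(rng[2] / hist_bin) * hist_bin + hist_bin,
                  by = hist_bin)
    counts <- graphics::hist(lags, breaks = breaks, plot = FALSE)$counts
    list(breaks = breaks, counts = counts)
  } else {
    NULL
  }
  list(lags = lags, mean = if (length(lags)) mean(lags) else NA_real_,
       sem = if (length(lags) > 1) stats::sd(lags) / sqrt(length(lags)) else NA_real_,
       n = length(lags), n_skipped = sum(!ok), hist = h)
}
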