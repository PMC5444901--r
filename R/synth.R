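#' Generate an alternating up/down state sequence
#'
#' Durations are drawn from gamma distributions (shape `duration_shape`,
#' means `mean_up_dur` / `mean_down_dur`), redrawn until they exceed
#' `min_dur` so no state is shorter than the minimum state duration used by
#' the detector (100 ms). The sequence starts with a down state and
#' alternates; the final interval is clipped to `total_dur`.
#'
#' @param total_dur total recording duration in seconds; must be at least
#'   `10 * (mean_up_dur + mean_down_dur)`.
#' @param mean_up_dur,mean_down_dur mean state durations in seconds.
#' @param duration_shape gamma shape parameter (larger = more regular).
#' @param min_dur minimum state duration in seconds (>= 0.1 by default).
#' @param t0 start time in seconds.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a [segmentation()] of alternating `up`/`down` intervals.
#' @export
gen_state_sequence <- function(total_dur, mean_up_dur = 0.5,
                               mean_down_dur = 0.4, duration_shape = 4,
                               min_dur = 0.1, t0 = 0, seed = NULL) {
  if (min_dur >= mean_up_dur || min_dur >= mean_down_dur) {
    stop("min_dur must be smaller than the mean durations")
  }
  if (total_dur < 10 * (mean_up_dur + mean_down_dur)) {
    stop("total_dur too short: need at least 10 mean up+down cycles")
  }
  with_seed(seed, {
    draw <- function(mean_dur, n) {
      d <- stats::rgamma(n, shape = duration_shape,
                         scale = mean_dur / duration_shape)
      while (any(bad <- d < min_dur)) {
        d[bad] <- stats::rgamma(sum(bad), shape = duration_shape,
                                scale = mean_dur / duration_shape)
      }
      d
    }
    n_guess <- ceiling(2.5 * total_dur / (mean_up_dur + mean_down_dur)) + 10
    durs <- as.vector(rbind(draw(mean_down_dur, n_guess),
                            draw(mean_up_dur, n_guess)))
    labs <- rep(c("down", "up"), n_guess)
    ends <- t0 + cumsum(durs)
    k <- which(ends >= t0 + total_dur)[1]
    if (is.na(k)) stop("internal error: not enough drawn states")
    durs <- durs[1:k]; labs <- labs[1:k]; ends <- ends[1:k]
    ends[k] <- t0 + total_dur
    onsets <- c(t0, ends[-k])
    if (ends[k] - onsets[k] < min_dur && k > 1) {
      ends <- ends[-k]; onsets <- onsets[-k]; labs <- labs[-k]
      ends[length(ends)] <- t0 + total_dur
    }
    segmentation(data.frame(onset = onsets, offset = ends, label = labs))
  })
}

# Default phase anchors, degrees: down onset/offset, up onset/offset.
# Up states occupy (112, 264) (LFP trough region), down states (322, 45)
# (LFP peak region).
default_anchors <- function() {
  c(down_on = 322, down_off = 45, up_on = 112, up_off = 264)
}

# Piecewise-linear ground-truth phase through the anchor values.
# Each interval owns two knots (onset anchor at onset + w/2, offset anchor at
# offset - w/2 with w = min(0.1 s, half the interval)); the 45->112 and
# 264->322 gaps are crossed linearly across the shared boundary so the
# unwrapped phase is continuous and strictly increasing.
# Returns list(phase_unwrapped, fs, t0) sampled at fs.
# @noRd
baseline_phase <- function(states, fs, anchors = default_anchors()) {
  on_a <- ifelse(states$label == "up", anchors[["up_on"]], anchors[["down_on"]])
  off_a <- ifelse(states$label == "up", anchors[["up_off"]], anchors[["down_off"]])
  w <- pmin(0.1, (states$offset - states$onset) / 2)
  kt <- as.vector(rbind(states$onset + w / 2, states$offset - w / 2))
  ka <- as.vector(rbind(on_a, off_a))
  # unwrap the knot angles into a strictly increasing sequence
  unw <- numeric(length(ka))
  unw[1] <- ka[1]
  for (i in 2:length(ka)) {
    step <- (ka[i] - unw[i - 1]) %% 360
    if (step == 0) step <- 360
    unw[i] <- unw[i - 1] + step
  }
  t0 <- states$onset[1]
  t_end <- states$offset[nrow(states)]
  n <- round((t_end - t0) * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  ph <- stats::approx(kt, unw, xout = tt, rule = 2)$y
  # linear extrapolation at the edges (approx rule = 2 is flat)
  s1 <- (unw[2] - unw[1]) / (kt[2] - kt[1])
  s2 <- (unw[length(unw)] - unw[length(unw) - 1]) /
    (kt[length(kt)] - kt[length(kt) - 1])
  lo <- tt < kt[1]; hi <- tt > kt[length(kt)]
  ph[lo] <- unw[1] + s1 * (tt[lo] - kt[1])
  ph[hi] <- unw[length(unw)] + s2 * (tt[hi] - kt[length(kt)])
  list(phase = ph, fs = fs, t0 = t0)
}

# State-gated band-limited noise plus white noise, added to the cosine of a
# (possibly perturbed) unwrapped phase.
# @noRd
compose_lfp <- function(phase_unwrapped, labels, fs, delta_amp, hf_band,
                        hf_amp_up, hf_amp_down, noise_sd) {
  n <- length(phase_unwrapped)
  lfp <- delta_amp * cos(deg2rad(phase_unwrapped))
  if (hf_amp_up > 0 || hf_amp_down > 0) {
    hf <- fft_bandpass(stats::rnorm(n), fs, hf_band[1], hf_band[2])
    hf <- hf / stats::sd(hf)
    amp <- ifelse(labels == "up", hf_amp_up, hf_amp_down)
    lfp <- lfp + hf * amp
  }
  if (noise_sd > 0) lfp <- lfp + stats::rnorm(n, sd = noise_sd)
  lfp
}

#' Generate a synthetic LFP with phase-anchored slow oscillation
#'
#' The ground-truth slow-oscillation phase advances monotonically, hitting
#' the anchor values at state boundaries (down states span 322..45 deg, the
#' LFP peak region; up states span 112..264 deg, the trough region; the
#' 45..112 and 264..322 gaps are crossed linearly at the boundaries). The
#' LFP is `delta_amp * cos(phase)` plus band-limited (10-40 Hz by default)
#' noise whose amplitude is higher inside up states, plus white noise.
#'
#' @param states a [segmentation()] of alternating up/down intervals.
#' @param fs sampling rate in Hz.
#' @param delta_amp slow-oscillation amplitude (a.u.).
#' @param anchors named phase anchors in degrees
#'   (`down_on`, `down_off`, `up_on`, `up_off`).
#' @param hf_band high-frequency band `(f_lo, f_hi)` in Hz.
#' @param hf_amp_up,hf_amp_down RMS of the band-limited component inside up
#'   and down states (`hf_amp_up > hf_amp_down >= 0`).
#' @param noise_sd white-noise standard deviation (a.u.).
#' @param seed integer seed.
#' @return list with `lfp` (a [trace()]) and `phase` (the ground-truth
#'   `"updown_phase"`).
#' @export
gen_lfp <- function(states, fs = 1000, delta_amp = 1,
                    anchors = default_anchors(), hf_band = c(10, 40),
                    hf_amp_up = 0.2, hf_amp_down = 0.05, noise_sd = 0.1,
                    seed = NULL) {
  stopifnot(hf_amp_up >= hf_amp_down, hf_amp_down >= 0)
  bp <- baseline_phase(states, fs, anchors)
  labels <- states_to_labels(states, list(samples = bp$phase, fs = fs, t0 = bp$t0))
  lfp <- with_seed(seed, {
    compose_lfp(bp$phase, labels, fs, delta_amp, hf_band, hf_amp_up,
                hf_amp_down, noise_sd)
  })
  list(
    lfp = trace(lfp, fs = fs, units = "a.u.", t0 = bp$t0),
    phase = phase_trace(bp$phase, fs = fs, t0 = bp$t0, method = "synthetic")
  )
}

#' Generate a synthetic membrane potential
#'
#' Two-level trace (depolarized in up states) with linear transitions of
#' `ramp` seconds plus Gaussian noise. The level separation should exceed
#' 10 mV, the criterion used for stable depolarization.
#'
#' @param states a [segmentation()].
#' @param levels `(down_mV, up_mV)`; `up - down` must exceed 10.
#' @param noise_sd noise standard deviation in mV.
#' @param ramp transition duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a [trace()] in mV.
#' @export
gen_vm <- function(states, levels = c(-70, -55), noise_sd = 1, ramp = 0.02,
                   fs = 1000, seed = NULL) {
  if (levels[2] - levels[1] <= 10) {
    stop("up level must exceed the down level by more than 10 mV")
  }
  t0 <- states$onset[1]
  n <- round((states$offset[nrow(states)] - t0) * fs)
  labels <- states_to_labels(states, list(samples = numeric(n), fs = fs, t0 = t0))
  ind <- as.numeric(labels == "up")
  k <- max(1L, round(ramp * fs))
  ind <- as.numeric(stats::filter(ind, rep(1 / k, k), sides = 2))
  if (anyNA(ind)) {  # edge samples lost to the centred moving average
    first_ok <- which(!is.na(ind))[1]
    last_ok <- max(which(!is.na(ind)))
    ind[seq_len(first_ok - 1)] <- ind[first_ok]
    if (last_ok < n) ind[(last_ok + 1):n] <- ind[last_ok]
  }
  vm <- levels[1] + (levels[2] - levels[1]) * ind
  if (noise_sd > 0) vm <- with_seed(seed, vm + stats::rnorm(n, sd = noise_sd))
  trace(vm, fs = fs, units = "mV", t0 = t0)
}

#' Generate spikes entrained to the slow-oscillation phase
#'
#' Inhomogeneous Poisson spikes with intensity
#' `rate_state(t) * exp(kappa * (cos(phase(t) - mu) - 1))`: the state-gated
#' peak rate is modulated by a max-normalised von Mises profile of the
#' ground-truth phase. `rate_down > 0` produces sparse down-state spikes;
#' `vm_kappa = 0` removes the phase preference.
#'
#' @param states a [segmentation()].
#' @param true_phase an `"updown_phase"` on the same time base.
#' @param rate_up,rate_down peak firing rates (Hz) inside up/down states.
#' @param vm_mu preferred phase in degrees.
#' @param vm_kappa von Mises concentration (>= 0).
#' @param cell_label label for the returned spike train.
#' @param seed integer seed.
#' @return a [spike_train()].
#' @export
gen_spikes_entrained <- function(states, true_phase, rate_up = 10,
                                 rate_down = 0.2, vm_mu = 167, vm_kappa = 2,
                                 cell_label = "PV", seed = NULL) {
  stopifnot(rate_up >= 0, rate_down >= 0, vm_kappa >= 0)
  labels <- states_to_labels(states, list(samples = true_phase$phase,
                                          fs = true_phase$fs,
                                          t0 = true_phase$t0))
  rate <- ifelse(labels == "up", rate_up,
                 ifelse(labels == "down", rate_down, 0))
  lambda <- rate * vm_profile(true_phase$phase, vm_mu, vm_kappa)
  with_seed(seed, {
    p <- 1 - exp(-lambda / true_phase$fs)
    hit <- stats::runif(length(p)) < p
    times <- true_phase$t0 + (which(hit) - 0.5) / true_phase$fs
    spike_train(times, cell_label = cell_label)
  })
}

#' Generate spikes that causally accelerate the slow-oscillation phase
#'
#' Implements the causal scenario in which interneuron firing advances the
#' phase of the slow oscillation (precipitating the up-to-down transition)
#' rather than merely being entrained by it. The recording is simulated
#' forward in time: the phase advances at the baseline anchor speed of the
#' supplied state sequence; spikes are drawn as a Poisson process gated by
#' the *current perturbed phase* (rate `rate_up` while the phase is in the
#' up range 112-264 deg, `rate_down` otherwise); and each up-phase spike
#' schedules a Gaussian speed bump in the near future, so the spike changes
#' the subsequent phase dynamics and not vice versa. The LFP is rebuilt from
#' the perturbed phase, and the returned state segmentation is re-derived
#' from it (boundaries at the anchor-gap midpoints 78.5 and 293 deg), since
#' the perturbation decouples the phase from the originally drawn states.
#'
#' Two kernels are available:
#' \describe{
#'   \item{`"reset"` (default)}{the bump amplitude is chosen per spike as
#'     `causal_strength` times the phase distance from the predicted
#'     trajectory to the up-state offset anchor (264 deg): a partial phase
#'     reset that drives the network toward the end of the up state. The
#'     reset *completes* `causal_lag` seconds after the spike (the bump is
#'     centred at `causal_lag - 2 * causal_width` and truncated at two
#'     widths), so the caused phase configuration is in place at latency
#'     `causal_lag` -- the lag the time-shifted locking analysis recovers.
#'     Spikes whose predicted phase has already left the up range add
#'     nothing.}
#'   \item{`"advance"`}{a fixed Gaussian bump of peak amplitude
#'     `causal_gain` deg/s centred `causal_lag` after the spike; the total
#'     extra phase per spike is `causal_gain * causal_width * sqrt(2*pi)`.
#'     With `causal_gain = 0` the integration is exactly the baseline.}
#' }
#'
#' @inheritParams gen_lfp
#' @param rate_up,rate_down Poisson rates (Hz) while the perturbed phase is
#'   inside/outside the up range.
#' @param causal_lag latency from spike to completed phase effect, seconds.
#' @param causal_width Gaussian temporal width of the bump, seconds
#'   (`causal_lag >= 4 * causal_width` so the bump is strictly causal).
#' @param causal_gain peak bump amplitude in deg/s (`"advance"` kernel).
#' @param causal_strength fractional reset toward the up-offset anchor
#'   (`"reset"` kernel), in `[0, 1]`.
#' @param kernel `"reset"` or `"advance"`.
#' @param cell_label label for the returned spike train.
#' @return list with `spikes` ([spike_train()]), `lfp` ([trace()]), `phase`
#'   (perturbed ground-truth `"updown_phase"`), `states` (segmentation
#'   re-derived from the perturbed phase).
#' @export
gen_spikes_causal <- function(states, fs = 1000, rate_up = 4,
                              rate_down = 0.2, causal_lag = 0.1,
                              causal_width = 0.015, causal_gain = 1500,
                              causal_strength = 0.9,
                              kernel = c("reset", "advance"),
                              delta_amp = 1, anchors = default_anchors(),
                              hf_band = c(10, 40), hf_amp_up = 0.2,
                              hf_amp_down = 0.05, noise_sd = 0.1,
                              cell_label = "PV", seed = NULL) {
  kernel <- match.arg(kernel)
  if (causal_lag < 4 * causal_width) {
    stop("causal_lag must be at least 4 * causal_width (strict causality)")
  }
  bp <- baseline_phase(states, fs, anchors)
  n <- length(bp$phase)
  base_speed <- c(diff(bp$phase), utils::tail(diff(bp$phase), 1)) * fs
  up_rng <- sort(c(anchors[["up_on"]], anchors[["up_off"]]))
  # truncated Gaussian kernel; for "reset" the support ends at causal_lag
  centre_lag <- if (kernel == "reset") causal_lag - 2 * causal_width else causal_lag
  koff <- seq(-round(2 * causal_width * fs), round(2 * causal_width * fs))
  kern <- stats::dnorm(koff / fs, sd = causal_width)
  kern <- kern / sum(kern / fs)  # unit integral after truncation
  lag_n <- round(causal_lag * fs)
  centre_n <- round(centre_lag * fs)
  with_seed(seed, {
    u <- stats::runif(n)
    p_up <- 1 - exp(-rate_up / fs)
    p_down <- 1 - exp(-rate_down / fs)
    speed <- base_speed
    phi <- numeric(n)
    phi[1] <- bp$phase[1]
    spike_i <- integer(0)
    for (i in 2:n) {
      phi[i] <- phi[i - 1] + (speed[i - 1] + speed[i]) / (2 * fs)
      pm <- phi[i] %% 360
      in_up <- pm > up_rng[1] && pm < up_rng[2]
      if (u[i] >= (if (in_up) p_up else p_down)) next
      spike_i <- c(spike_i, i)
      amp <- if (kernel == "advance") {
        causal_gain * causal_width * sqrt(2 * pi)
      } else {
        if (!in_up) next
        j1 <- min(n, i + lag_n)
        pred <- (phi[i] + sum(speed[(i + 1):j1]) / fs) %% 360
        if (pred <= up_rng[1] || pred >= up_rng[2]) next
        causal_strength * ((anchors[["up_off"]] - pred) %% 360)
      }
      if (amp <= 0) next
      ks <- i + centre_n + koff
      ok <- ks >= 1 & ks <= n
      speed[ks[ok]] <- speed[ks[ok]] + amp * kern[ok]
    }
    spike_t <- bp$t0 + (spike_i - 0.5) / fs
    pm <- phi %% 360
    labels <- ifelse(pm >= 78.5 & pm < 293, "up", "down")
    derived <- labels_to_states(labels, fs, bp$t0)
    lfp <- compose_lfp(phi, labels, fs, delta_amp, hf_band, hf_amp_up,
                       hf_amp_down, noise_sd)
    list(
      spikes = spike_train(spike_t, cell_label = cell_label),
      lfp = trace(lfp, fs = fs, units = "a.u.", t0 = bp$t0),
      phase = phase_trace(phi, fs = fs, t0 = bp$t0, method = "synthetic"),
      states = derived
    )
  })
}

#' Simulate a complete synthetic recording
#'
#' Bundles the state sequence, membrane potential, LFP, ground-truth phase
#' and an interneuron spike train into one object, with all randomness
#' derived from a single seed. `mode = "entrained"` draws phase-entrained
#' spikes on the anchored LFP; `mode = "causal"` uses
#' [gen_spikes_causal()] so the spikes perturb the phase.
#'
#' @param total_dur recording duration in seconds.
#' @param seed master integer seed.
#' @param mode `"entrained"` or `"causal"`.
#' @param state_params,lfp_params,vm_params,spike_params named lists of
#'   overrides passed to the respective generators.
#' @return an object of class `"updown_groundtruth"`: list with `states`,
#'   `vm`, `lfp`, `phase`, `spikes`, `params`.
#' @export
simulate_recording <- function(total_dur = 600, seed = 1,
                               mode = c("entrained", "causal"),
                               state_params = list(), lfp_params = list(),
                               vm_params = list(), spike_params = list()) {
  mode <- match.arg(mode)
  states <- do.call(gen_state_sequence, c(
    list(total_dur = total_dur, seed = seed), state_params
  ))
  vm <- do.call(gen_vm, c(list(states = states, seed = seed + 1L), vm_params))
  if (mode == "entrained") {
    gl <- do.call(gen_lfp, c(list(states = states, seed = seed + 2L), lfp_params))
    spikes <- do.call(gen_spikes_entrained, c(
      list(states = states, true_phase = gl$phase, seed = seed + 3L),
      spike_params
    ))
    lfp <- gl$lfp; phase <- gl$phase
  } else {
    gc_ <- do.call(gen_spikes_causal, c(
      list(states = states, seed = seed + 2L), lfp_params, spike_params
    ))
    spikes <- gc_$spikes; lfp <- gc_$lfp; phase <- gc_$phase
    states <- gc_$states  # perturbed phase re-derives the state boundaries
  }
  structure(
    list(states = states, vm = vm, lfp = lfp, phase = phase, spikes = spikes,
         params = list(total_dur = total_dur, seed = seed, mode = mode,
                       state_params = state_params, lfp_params = lfp_params,
                       vm_params = vm_params, spike_params = spike_params)),
    class = "updown_groundtruth"
  )
}

#' @export
print.updown_groundtruth <- function(x, ...) {
  cat(sprintf("<GroundTruth> %g s, mode '%s', %d states, %d spikes\n",
              x$params$total_dur, x$params$mode, nrow(x$states),
              length(x$spikes$times)))
  invisible(x)
}
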