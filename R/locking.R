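#' Rescale a phase trace by its cumulative distribution
#'
#' Replaces each phase value by `360 * F(phase)` where `F` is the empirical
#' CDF over all samples (rank-based, ties averaged), making the overall
#' phase distribution uniform. This corrects for non-uniform phase occupancy
#' caused by asymmetries of the LFP wave shape, so that phase locking of
#' spikes is not confounded by the marginal phase distribution.
#'
#' @param phase an `"updown_phase"` object (>= 1e4 samples recommended).
#' @return an `"updown_phase"` with method suffix `"+rescaled"`.
#' @export
rescale_phase <- function(phase) {
  stopifnot(inherits(phase, "updown_phase"))
  n <- length(phase$phase)
  r <- rank(phase$phase, ties.method = "average")
  phase_trace(360 * (r - 0.5) / n, fs = phase$fs, t0 = phase$t0,
              band = phase$band, method = paste0(phase$method, "+rescaled"))
}

#' Phase of firing at an LFP time shift
#'
#' Collects, for each spike at time `t`, the phase of the LFP trace shifted
#' by `tau` relative to the spike train, i.e. the phase sampled at `t - tau`
#' (nearest sample). Negative shifts therefore probe the phase *after* the
#' spike, which is where a causal effect of the spike on the phase dynamics
#' shows up. Spikes whose shifted time falls outside the trace are dropped
#' and counted.
#'
#' @param spikes a [spike_train()].
#' @param phase an `"updown_phase"` (typically rescaled; see
#'   [rescale_phase()]).
#' @param tau LFP time shift in seconds.
#' @return object of class `"updown_pof"`: `angles` (degrees), `n_spikes`,
#'   `n_dropped`, `tau`.
#' @export
phase_of_firing <- function(spikes, phase, tau = 0) {
  stopifnot(inherits(spikes, "updown_spikes"), inherits(phase, "updown_phase"))
  idx <- round((spikes$times - tau - phase$t0) * phase$fs) + 1L
  ok <- idx >= 1L & idx <= length(phase$phase)
  if (!any(ok)) stop("all spikes fall outside the shifted trace")
  structure(
    list(angles = phase$phase[idx[ok]], n_spikes = sum(ok),
         n_dropped = sum(!ok), tau = tau),
    class = "updown_pof"
  )
}

#' Locking strength (one minus the circular variance)
#'
#' The strength of spike-LFP phase locking is the mean resultant length of
#' the phase-of-firing angles, i.e. one minus the circular variance: 1 for
#' spikes all at one phase, 0 for a balanced distribution.
#'
#' @param pof an `"updown_pof"` from [phase_of_firing()], or a numeric
#'   vector of angles in degrees.
#' @return scalar in \[0, 1\].
#' @export
locking_strength <- function(pof) {
  angles <- if (inherits(pof, "updown_pof")) pof$angles else pof
  if (!length(angles)) stop("no spikes: locking strength undefined")
  circ_resultant(angles)$r
}

#' Rayleigh test of a phase-of-firing distribution
#'
#' @param pof an `"updown_pof"` or numeric angles (degrees), n >= 10.
#' @return the p-value for departure from circular uniformity.
#' @seealso [rayleigh_test()] for the full statistic.
#' @export
rayleigh_p <- function(pof) {
  angles <- if (inherits(pof, "updown_pof")) pof$angles else pof
  rayleigh_test(angles)$p.value
}

#' Time-shifted locking profile with causal-window statistics
#'
#' Computes locking strength and Rayleigh significance of the phase of
#' firing at every LFP time shift tau on a grid spanning -0.5 to 0.5 s
#' (10 ms steps by default), after rescaling the phase by its cumulative
#' distribution. Rayleigh p-values are Bonferroni-corrected by the grid
#' size. Derived quantities:
#' \describe{
#'   \item{`tau_max`}{the shift maximising locking strength.}
#'   \item{`tau_end`}{the most negative shift such that at every shift in
#'     `[tau_end, 0)` locking is significant (corrected p < alpha) *and*
#'     stronger than the maximal strength over tau >= 0 (which cannot
#'     reflect causation of spikes on the phase). `NA` when no such shift
#'     exists; clamped at -0.5 s when the run reaches the grid edge.}
#' }
#' Cells with fewer than `min_spikes` (100) spikes are excluded: the
#' returned object has `excluded = TRUE` and a reason, not an error.
#'
#' @param spikes a [spike_train()].
#' @param phase an `"updown_phase"` (raw; rescaling is applied internally
#'   unless `rescale = FALSE`).
#' @param grid_step tau grid step in seconds.
#' @param tau_range range of shifts in seconds.
#' @param alpha significance level before Bonferroni correction (0.01).
#' @param min_spikes minimum spike count for inclusion.
#' @param rescale apply [rescale_phase()] first.
#' @return object of class `"updown_locking_profile"`: `tau_grid`,
#'   `strength`, `p_values` (corrected), `tau_max`, `tau_end`, `alpha`,
#'   `n_spikes`, `excluded`.
#' @export
shifted_locking_profile <- function(spikes, phase, grid_step = 0.01,
                                    tau_range = c(-0.5, 0.5), alpha = 0.01,
                                    min_spikes = 100, rescale = TRUE) {
  n_sp <- length(spikes$times)
  if (n_sp < min_spikes) {
    return(structure(
      list(excluded = TRUE,
           reason = sprintf("cell has %d spikes (< %d required)", n_sp,
                            min_spikes),
           n_spikes = n_sp),
      class = "updown_locking_profile"
    ))
  }
  if (rescale) phase <- rescale_phase(phase)
  taus <- seq(tau_range[1], tau_range[2], by = grid_step)
  m <- length(taus)
  strength <- p_raw <- numeric(m)
  for (i in seq_len(m)) {
    pof <- phase_of_firing(spikes, phase, taus[i])
    strength[i] <- locking_strength(pof)
    p_raw[i] <- rayleigh_p(pof)
  }
  p_corr <- pmin(1, p_raw * m)
  derived <- profile_causal_window(taus, strength, p_corr, alpha)
  structure(
    list(tau_grid = taus, strength = strength, p_values = p_corr,
         tau_max = derived$tau_max, tau_end = derived$tau_end, alpha = alpha,
         n_spikes = n_sp, excluded = FALSE),
    class = "updown_locking_profile"
  )
}

# tau_max / tau_end from a locking profile: tau_max maximises strength;
# tau_end is the most negative tau such that every tau in [tau_end, 0) is
# significant (corrected p < alpha) and exceeds the max strength over
# tau >= 0; NA if the shift just below zero already fails (clamping at the
# grid edge falls out naturally).
# @noRd
profile_causal_window <- function(taus, strength, p_corr, alpha) {
  tau_max <- taus[which.max(strength)]
  max_pos <- max(strength[taus >= 0])
  neg <- which(taus < 0)
  neg <- neg[order(taus[neg], decreasing = TRUE)]  # from -step downwards
  qual <- p_corr[neg] < alpha & strength[neg] > max_pos
  run <- cumprod(qual) > 0
  tau_end <- if (any(run)) taus[neg[max(which(run))]] else NA_real_
  list(tau_max = tau_max, tau_end = tau_end)
}

#' @export
print.updown_locking_profile <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("<LockingProfile> excluded:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<LockingProfile> %d spikes; tau_max = %g s; tau_end = %s; peak strength %.3f\n",
      x$n_spikes, x$tau_max,
      if (is.na(x$tau_end)) "undefined" else sprintf("%g s", x$tau_end),
      max(x$strength)
    ))
  }
  invisible(x)
}

#' Per-state firing statistics
#'
#' Spike counts per state class, percentage of up (down) states in which the
#' cell was active (fired at least one spike), mean number of spikes per
#' active state, and the overall firing rate. Spikes are assigned to
#' intervals by the half-open convention.
#'
#' @param spikes a [spike_train()].
#' @param states a [segmentation()].
#' @return object of class `"updown_state_firing"`.
#' @export
state_firing_stats <- function(spikes, states) {
  idx <- spikes_to_intervals(spikes, states)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(states))
  per_class <- function(lab) {
    sel <- states$label == lab
    k <- counts[sel]
    list(
      n_states = sum(sel),
      n_spikes = sum(k),
      pct_active = if (sum(sel)) 100 * mean(k >= 1) else NA_real_,
      spikes_per_active = if (any(k >= 1)) mean(k[k >= 1]) else NA_real_
    )
  }
  span <- states$offset[nrow(states)] - states$onset[1]
  structure(
    list(up = per_class("up"), down = per_class("down"),
         indeterminate = per_class("indeterminate"),
         rate_hz = length(spikes$times) / span,
         cell_label = spikes$cell_label),
    class = "updown_state_firing"
  )
}

#' @export
print.updown_state_firing <- function(x, ...) {
  cat(sprintf("<StateFiringStats> '%s': %.2f Hz overall\n", x$cell_label,
              x$rate_hz))
  for (lab in c("up", "down")) {
    s <- x[[lab]]
    cat(sprintf(
      "  %s: %d spikes in %d states; %.1f%% active; %.2f spikes/active state\n",
      lab, s$n_spikes, s$n_states, s$pct_active,
      ifelse(is.na(s$spikes_per_active), 0, s$spikes_per_active)
    ))
  }
  invisible(x)
}

# Occurrence windows for a state context: the labelled intervals themselves,
# or 100 ms windows straddling the boundary for transition contexts.
# @noRd
context_windows <- function(states, context, transition_half = 0.1) {
  if (context %in% c("up", "down")) {
    sel <- states$label == context
    data.frame(onset = states$onset[sel], offset = states$offset[sel])
  } else {
    from <- if (context == "down-to-up") "down" else "up"
    to <- if (context == "down-to-up") "up" else "down"
    k <- which(states$label[-nrow(states)] == from &
                 states$label[-1] == to)
    b <- states$offset[k]
    data.frame(onset = b - transition_half, offset = b + transition_half)
  }
}

#' Phase-of-firing strength and reliability histograms
#'
#' Two complementary per-phase-bin quantifications across the occurrences of
#' a state: *strength* is the mean number of spikes per phase bin per
#' occurrence; *reliability* is the fraction of occurrences with at least
#' one spike in the bin. They coincide when the cell never fires more than
#' one spike per bin per occurrence; their similarity is summarised by the
#' Pearson correlation across bins.
#'
#' @param spikes a [spike_train()].
#' @param states a [segmentation()].
#' @param phase an `"updown_phase"`.
#' @param context `"up"`, `"down"`, `"down-to-up"` or `"up-to-down"`
#'   (transition contexts use 100 ms windows straddling the boundary).
#' @param n_bins number of phase bins.
#' @param min_occurrences minimum number of state occurrences.
#' @return object of class `"updown_histpair"`: `edges`, `strength`,
#'   `reliability`, `pearson_r`, `n_occurrences`.
#' @export
strength_reliability_histograms <- function(spikes, states, phase,
                                            context = "up", n_bins = 36,
                                            min_occurrences = 5) {
  win <- context_windows(states, context)
  if (nrow(win) < min_occurrences) {
    stop("fewer than ", min_occurrences, " occurrences of context '",
         context, "'")
  }
  edges <- seq(0, 360, length.out = n_bins + 1)
  counts <- matrix(0, nrow(win), n_bins)
  for (i in seq_len(nrow(win))) {
    sel <- spikes$times >= win$onset[i] & spikes$times < win$offset[i]
    if (!any(sel)) next
    idx <- round((spikes$times[sel] - phase$t0) * phase$fs) + 1L
    idx <- idx[idx >= 1 & idx <= length(phase$phase)]
    b <- pmin(n_bins, findInterval(phase$phase[idx], edges,
                                   rightmost.closed = TRUE))
    counts[i, ] <- tabulate(b, nbins = n_bins)
  }
  strength <- colMeans(counts)
  reliability <- colMeans(counts >= 1)
  r <- if (stats::sd(strength) > 0 && stats::sd(reliability) > 0) {
    stats::cor(strength, reliability)
  } else {
    NA_real_
  }
  structure(
    list(edges = edges, strength = strength, reliability = reliability,
         pearson_r = r, n_occurrences = nrow(win), context = context),
    class = "updown_histpair"
  )
}

#' Null test for genuine down-state firing
#'
#' Tests the null hypothesis that all of a cell's putative down-state spikes
#' were fired in time bins wrongly classified as down. Each 20 ms
#' detected-down bin containing at least one spike contributes one factor --
#' the empirical misclassification probability given the bin's S_comb value
#' (from [misclassification_table()]) -- and the p-value is the product of
#' the factors (bins are assumed independent given the rarity of down-state
#' spikes). `per_spike = TRUE` multiplies one factor per spike instead, so
#' bins with several spikes contribute repeatedly.
#'
#' @param spikes a [spike_train()].
#' @param detected the detected [segmentation()].
#' @param sc the S_comb [trace()].
#' @param table an `"updown_misclass_table"`.
#' @param per_spike product over spikes instead of over occupied bins.
#' @return list with `p` (the null probability), `n_bins`, `n_spikes`
#'   (down-state spikes considered).
#' @export
down_state_spike_test <- function(spikes, detected, sc, table,
                                  per_spike = FALSE) {
  stopifnot(inherits(table, "updown_misclass_table"))
  det_lab <- states_to_labels(detected, sc)
  bin_n <- round(table$bin_ms / 1000 * sc$fs)
  n_bins <- floor(length(sc$samples) / bin_n)
  idx <- rep(seq_len(n_bins), each = bin_n)
  take <- seq_len(n_bins * bin_n)
  det_down <- tapply(det_lab[take] == "down", idx, mean) > 0.5
  sc_bin <- tapply(sc$samples[take], idx, mean)
  sp_bin <- floor((spikes$times - sc$t0) * sc$fs / bin_n) + 1L
  sp_bin <- sp_bin[sp_bin >= 1 & sp_bin <= n_bins]
  sp_bin <- sp_bin[det_down[sp_bin]]
  if (!length(sp_bin)) stop("no spikes in detected-down bins")
  occupied <- if (per_spike) sp_bin else sort(unique(sp_bin))
  n_value_bins <- length(table$edges) - 1
  lookup <- function(v) {
    b <- pmin(n_value_bins, pmax(1L, findInterval(v, table$edges,
                                                  rightmost.closed = TRUE)))
    if (is.na(table$p_false_down[b])) {
      filled <- which(!is.na(table$p_false_down))
      nb <- filled[which.min(abs(filled - b))]
      warning("S_comb value bin unoccupied in calibration; using nearest bin")
      b <- nb
    }
    table$p_false_down[b]
  }
  facs <- vapply(sc_bin[occupied], lookup, numeric(1))
  list(p = prod(facs), n_bins = length(unique(sp_bin)),
       n_spikes = length(sp_bin), factors = facs)
}
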