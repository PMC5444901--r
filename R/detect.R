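#' Detection configuration
#'
#' Parameters of the LFP up/down state detector. The defaults are the
#' calibrated values used throughout: low-frequency phase bands 0-1 and
#' 1-3 Hz, envelope band 10-40 Hz, 5 ms running-RMS frame, 50 ms smoothing
#' frame, 100 ms minimum state duration, 50 ms minimum inter-state interval,
#' Hilbert phase, 36 phase bins of 10 degrees with pseudo-count 1.
#'
#' @param low_bands list of two `(f_lo, f_hi)` phase bands in Hz.
#' @param hf_band envelope band in Hz.
#' @param rms_frame running-RMS frame in seconds.
#' @param smooth_frame smoothing frame in seconds.
#' @param min_state_dur minimum state duration in seconds.
#' @param min_gap minimum inter-state interval in seconds.
#' @param phase_method `"hilbert"` or `"interpolation"`.
#' @param n_phase_bins number of phase histogram bins.
#' @param pseudo_count Laplace smoothing pseudo-count for the histograms.
#' @return a list of class `"updown_detection_config"`.
#' @export
detection_config <- function(low_bands = list(c(0, 1), c(1, 3)),
                             hf_band = c(10, 40), rms_frame = 0.005,
                             smooth_frame = 0.05, min_state_dur = 0.1,
                             min_gap = 0.05, phase_method = "hilbert",
                             n_phase_bins = 36, pseudo_count = 1) {
  stopifnot(rms_frame > 0, smooth_frame > 0, min_state_dur > 0, min_gap > 0,
            n_phase_bins > 0, pseudo_count >= 0)
  structure(
    list(low_bands = low_bands, hf_band = hf_band, rms_frame = rms_frame,
         smooth_frame = smooth_frame, min_state_dur = min_state_dur,
         min_gap = min_gap, phase_method = phase_method,
         n_phase_bins = n_phase_bins, pseudo_count = pseudo_count),
    class = "updown_detection_config"
  )
}

# Centred moving average with edge replication.
# @noRd
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  if (anyNA(y)) {
    ok <- which(!is.na(y))
    y[seq_len(ok[1] - 1)] <- y[ok[1]]
    if (max(ok) < length(y)) y[(max(ok) + 1):length(y)] <- y[max(ok)]
  }
  y
}

# Merge sub-min_gap gaps between same-label runs, then relabel sub-min_dur
# labelled runs as indeterminate. Single pass, up processed before down.
# @noRd
apply_morphology <- function(labels, fs, min_state_dur, min_gap) {
  min_gap_n <- round(min_gap * fs)
  min_dur_n <- round(min_state_dur * fs)
  for (lab in c("up", "down")) {
    r <- rle(labels == lab)
    if (length(r$lengths) >= 3) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (!r$values[i] && i > 1 && i < length(r$values) &&
            r$lengths[i] < min_gap_n) {
          labels[starts[i]:ends[i]] <- lab
        }
      }
    }
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] %in% c("up", "down") && r$lengths[i] < min_dur_n) {
      labels[starts[i]:ends[i]] <- "indeterminate"
    }
  }
  labels
}

#' Detect up/down states from the membrane potential
#'
#' Ground-truth state detection for calibration and ROC validation. The Vm
#' sample distribution is fitted with a two-Gaussian mixture; samples above
#' `mu_up - 2 sigma_up` are up, samples below `mu_down + 2 sigma_down` are
#' down, the rest indeterminate; sub-50 ms gaps are then merged and
#' sub-100 ms states dropped, as for the LFP detector.
#'
#' @param vm a [trace()] of membrane potential in mV; must be bimodal with
#'   modes separated by more than `min_separation` mV.
#' @param cfg a [detection_config()].
#' @param min_separation minimum mode separation in mV.
#' @param seed seed for the mixture fit restarts.
#' @return a [segmentation()].
#' @export
detect_states_vm <- function(vm, cfg = detection_config(),
                             min_separation = 5, seed = 1) {
  stopifnot(inherits(vm, "updown_trace"))
  fit <- fit_gmm(vm$samples, k = 2, seed = seed)
  if (diff(fit$mean) <= min_separation) {
    stop("Vm distribution is not bimodal: modes separated by <= ",
         min_separation, " mV")
  }
  up_thr <- fit$mean[2] - 2 * fit$sd[2]
  down_thr <- fit$mean[1] + 2 * fit$sd[1]
  if (up_thr < down_thr) stop("Vm thresholds crossed; distribution too broad")
  labels <- ifelse(vm$samples > up_thr, "up",
                   ifelse(vm$samples < down_thr, "down", "indeterminate"))
  labels <- apply_morphology(labels, vm$fs, cfg$min_state_dur, cfg$min_gap)
  labels_to_states(labels, vm$fs, vm$t0)
}

#' Calibrate phase-likelihood tables from ground truth
#'
#' For each configured low-frequency band, bins the instantaneous LFP phase
#' of up-labelled and down-labelled samples into `n_phase_bins` histograms
#' (Laplace-smoothed, normalised to sum to one). The tables encode the
#' differential likelihood of observing each phase in an up versus a down
#' state and drive the phase decision variable.
#'
#' @param lfp a [trace()] at 1 kHz.
#' @param truth a ground-truth [segmentation()] with at least `min_states`
#'   up and down intervals each.
#' @param cfg a [detection_config()].
#' @param min_states minimum number of up and of down intervals.
#' @return object of class `"updown_likelihood_tables"`: per band, `p_up`
#'   and `p_down` histograms over phase bins, plus the bin edges.
#' @export
fit_phase_likelihoods <- function(lfp, truth, cfg = detection_config(),
                                  min_states = 10) {
  n_up <- sum(truth$label == "up"); n_down <- sum(truth$label == "down")
  if (n_up < min_states || n_down < min_states) {
    stop("need at least ", min_states, " up and down intervals for calibration")
  }
  labels <- states_to_labels(truth, lfp)
  edges <- seq(0, 360, length.out = cfg$n_phase_bins + 1)
  tabs <- lapply(cfg$low_bands, function(band) {
    ph <- instantaneous_phase(lfp, band, method = cfg$phase_method)$phase
    bin <- pmin(cfg$n_phase_bins, findInterval(ph, edges, rightmost.closed = TRUE))
    h <- function(sel) {
      counts <- tabulate(bin[sel], nbins = cfg$n_phase_bins) + cfg$pseudo_count
      counts / sum(counts)
    }
    list(band = band, p_up = h(labels == "up"), p_down = h(labels == "down"))
  })
  structure(list(tables = tabs, edges = edges, n_bins = cfg$n_phase_bins),
            class = "updown_likelihood_tables")
}

#' Phase decision variable S_delta
#'
#' Per-sample evidence for the up state from the low-frequency phase: the
#' log-likelihood ratios `log(P(phase_b | up) / P(phase_b | down))` of the
#' calibrated bands are summed and squashed through a logistic, giving a
#' value in (0, 1) that is 0.5 when the bands are uninformative.
#'
#' @param lfp a [trace()].
#' @param tables tables from [fit_phase_likelihoods()].
#' @param cfg a [detection_config()].
#' @return a [trace()] of values in (0, 1).
#' @export
s_delta <- function(lfp, tables, cfg = detection_config()) {
  stopifnot(inherits(tables, "updown_likelihood_tables"))
  llr <- numeric(length(lfp$samples))
  for (tab in tables$tables) {
    ph <- instantaneous_phase(lfp, tab$band, method = cfg$phase_method)$phase
    bin <- pmin(tables$n_bins,
                findInterval(ph, tables$edges, rightmost.closed = TRUE))
    llr <- llr + log(tab$p_up[bin] / tab$p_down[bin])
  }
  trace(stats::plogis(llr), fs = lfp$fs, units = "prob", t0 = lfp$t0)
}

#' Envelope decision variable S_beta_gamma
#'
#' Band-passes the LFP to 10-40 Hz, computes the running RMS in a 5 ms
#' frame, smooths it with a 50 ms moving average and min-max normalises the
#' result to \[0, 1\]. A constant input yields all zeros with a warning.
#'
#' @param lfp a [trace()] of at least 1 s.
#' @param cfg a [detection_config()].
#' @return a [trace()] of values in \[0, 1\].
#' @export
s_beta_gamma <- function(lfp, cfg = detection_config()) {
  if (trace_duration(lfp) < 1) stop("recording must be at least 1 s long")
  xb <- bandpass(lfp, cfg$hf_band)$samples
  rms <- sqrt(moving_average(xb^2, round(cfg$rms_frame * lfp$fs)))
  sm <- moving_average(rms, round(cfg$smooth_frame * lfp$fs))
  rng <- range(sm)
  if (diff(rng) == 0) {
    warning("constant signal: S_beta_gamma set to all zeros")
    vals <- rep(0, length(sm))
  } else {
    vals <- (sm - rng[1]) / diff(rng)
  }
  trace(vals, fs = lfp$fs, units = "norm", t0 = lfp$t0)
}

#' Combined decision variable S_comb
#'
#' Element-wise mean of the phase ([s_delta()]) and envelope
#' ([s_beta_gamma()]) decision variables.
#'
#' @param sd_trace,sbg_trace [trace()]s of equal length on the same time base.
#' @return a [trace()] of values in \[0, 1\].
#' @export
s_comb <- function(sd_trace, sbg_trace) {
  if (length(sd_trace$samples) != length(sbg_trace$samples)) {
    stop("decision traces must have equal length")
  }
  trace((sd_trace$samples + sbg_trace$samples) / 2, fs = sd_trace$fs,
        units = "prob", t0 = sd_trace$t0)
}

# EM fit of a k-component univariate Gaussian mixture, k-means init,
# restarts ranked by log-likelihood; components sorted by mean.
# @noRd
fit_gmm <- function(x, k, seed = 1, n_restarts = 10, tol = 1e-6,
                    max_iter = 500) {
  if (stats::sd(x) == 0) stop("degenerate input: all values identical")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1, {
      km <- tryCatch(stats::kmeans(x, centers = k, nstart = 1),
                     error = function(e) NULL)
      if (is.null(km)) return(NULL)
      mu <- as.numeric(km$centers)
      sdv <- vapply(seq_len(k), function(j) {
        s <- stats::sd(x[km$cluster == j])
        if (!is.finite(s) || s < 1e-8) s <- stats::sd(x) / k
        s
      }, numeric(1))
      w <- as.numeric(table(factor(km$cluster, seq_len(k)))) / length(x)
      ll_old <- -Inf; n_iter <- 0L; degenerate <- FALSE
      for (it in seq_len(max_iter)) {
        dens <- vapply(seq_len(k), function(j) {
          w[j] * stats::dnorm(x, mu[j], sdv[j])
        }, numeric(length(x)))
        tot <- rowSums(dens)
        tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
        ll <- sum(log(tot))
        resp <- dens / tot
        nk <- colSums(resp)
        if (any(nk < 2)) { degenerate <- TRUE; break }
        w <- nk / length(x)
        mu <- colSums(resp * x) / nk
        sdv <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
        if (any(sdv < 1e-6)) { degenerate <- TRUE; break }
        n_iter <- it
        if (abs(ll - ll_old) < tol) break
        ll_old <- ll
      }
      if (degenerate) NULL else list(w = w, mu = mu, sd = sdv, loglik = ll,
                                     n_iter = n_iter)
    })
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts degenerate; consider fallback thresholds")
  }
  o <- order(best$mu)
  list(weight = best$w[o], mean = best$mu[o], sd = best$sd[o],
       loglik = best$loglik, n_iter = best$n_iter)
}

#' Three-Gaussian mixture fit of the combined decision variable
#'
#' Fits S_comb values with a mixture of three Gaussians by expectation
#' maximisation (k-means initialisation, 10 restarts ranked by
#' log-likelihood, tolerance 1e-6, at most 500 iterations). Components are
#' labelled by their sorted means: down (lowest), indeterminate, up
#' (highest). Restarts that collapse (a component standard deviation below
#' 1e-6) are discarded; if all collapse an error advises fallback
#' thresholds.
#'
#' @param x numeric vector of S_comb values (>= 1000 samples).
#' @param seed integer seed; the fit is deterministic given `seed` and
#'   `n_restarts`.
#' @param n_restarts number of EM restarts.
#' @param max_fit_samples recordings longer than this are thinned evenly
#'   (deterministically) before fitting; the mixture shape is unaffected.
#' @return object of class `"updown_gmm3"`: `weight`, `mean`, `sd` (ordered
#'   down/indeterminate/up), `loglik`, `n_iter`.
#' @export
fit_gmm3 <- function(x, seed = 1, n_restarts = 10, max_fit_samples = 1e5) {
  if (length(x) < 1000) stop("need at least 1000 samples to fit the mixture")
  if (length(x) > max_fit_samples) {
    x <- x[seq(1L, length(x), length.out = max_fit_samples)]
  }
  fit <- fit_gmm(x, k = 3, seed = seed, n_restarts = n_restarts)
  structure(c(fit, list(roles = c("down", "indeterminate", "up"))),
            class = "updown_gmm3")
}

#' @export
print.updown_gmm3 <- function(x, ...) {
  cat("<GmmFit> 3 components (down / indeterminate / up)\n")
  print(data.frame(role = x$roles, weight = round(x$weight, 4),
                   mean = round(x$mean, 4), sd = round(x$sd, 4)))
  cat(sprintf("log-likelihood %.2f after %d iterations\n", x$loglik, x$n_iter))
  invisible(x)
}

#' Threshold the combined decision variable into states
#'
#' Samples with `S_comb > mu_up - 2 sigma_up` are labelled up and samples
#' with `S_comb < mu_down + 2 sigma_down` down (the down criterion is the
#' mirror of the up one: down states live at the lowest S_comb values);
#' everything else is indeterminate. Gaps shorter than the minimum
#' inter-state interval (50 ms) between same-label states are then merged,
#' and labelled states shorter than the minimum duration (100 ms) are
#' relabelled indeterminate, in that order, once.
#'
#' @param sc a [trace()] of S_comb values.
#' @param gmm a [fit_gmm3()] fit.
#' @param cfg a [detection_config()].
#' @return a [segmentation()].
#' @export
threshold_states <- function(sc, gmm, cfg = detection_config()) {
  stopifnot(inherits(gmm, "updown_gmm3"))
  up_thr <- gmm$mean[3] - 2 * gmm$sd[3]
  down_thr <- gmm$mean[1] + 2 * gmm$sd[1]
  if (up_thr < down_thr) {
    stop("thresholds crossed: mu_up - 2*sd_up < mu_down + 2*sd_down")
  }
  x <- sc$samples
  labels <- ifelse(x > up_thr & x < down_thr, "indeterminate",
                   ifelse(x > up_thr, "up",
                          ifelse(x < down_thr, "down", "indeterminate")))
  labels <- apply_morphology(labels, sc$fs, cfg$min_state_dur, cfg$min_gap)
  labels_to_states(labels, sc$fs, sc$t0)
}

#' ROC validation of a decision variable against ground truth
#'
#' Sweeps a threshold over the decision variable and computes per-sample
#' true/false positive rates for up detection (decision above threshold on
#' truly-up versus truly-down samples) and for down detection (decision
#' below threshold), with AUC by the trapezoid rule. Samples the ground
#' truth labels indeterminate are ignored.
#'
#' @param decision a [trace()] (e.g. S_comb or S_delta).
#' @param truth a ground-truth [segmentation()] containing both up and down
#'   states.
#' @param n_thresholds size of the threshold grid.
#' @return object of class `"updown_roc"`: `thresholds`, `tpr_up`, `fpr_up`,
#'   `tpr_down`, `fpr_down`, `auc_up`, `auc_down`.
#' @export
roc_evaluate <- function(decision, truth, n_thresholds = 201) {
  labels <- states_to_labels(truth, decision)
  x_up <- decision$samples[labels == "up"]
  x_down <- decision$samples[labels == "down"]
  if (!length(x_up) || !length(x_down)) {
    stop("ground truth must contain both up and down samples")
  }
  thr <- c(-Inf, seq(min(decision$samples), max(decision$samples),
                     length.out = n_thresholds), Inf)
  tpr_up <- vapply(thr, function(th) mean(x_up > th), numeric(1))
  fpr_up <- vapply(thr, function(th) mean(x_down > th), numeric(1))
  tpr_down <- vapply(thr, function(th) mean(x_down < th), numeric(1))
  fpr_down <- vapply(thr, function(th) mean(x_up < th), numeric(1))
  auc <- function(fpr, tpr) {
    o <- order(fpr, tpr)
    sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  }
  structure(
    list(thresholds = thr, tpr_up = tpr_up, fpr_up = fpr_up,
         tpr_down = tpr_down, fpr_down = fpr_down,
         auc_up = auc(fpr_up, tpr_up), auc_down = auc(fpr_down, tpr_down)),
    class = "updown_roc"
  )
}

#' @export
print.updown_roc <- function(x, ...) {
  cat(sprintf("<RocResult> AUC up = %.4f, AUC down = %.4f\n",
              x$auc_up, x$auc_down))
  invisible(x)
}

#' Empirical down-state misclassification table
#'
#' From a calibration recording with ground truth, estimates the probability
#' that a 20 ms time bin is wrongly classified as a down state, as a
#' function of the bin's mean S_comb value. A time bin counts as
#' detected-down (or truly-down) when more than half of its samples carry
#' that label. Probabilities are Laplace-smoothed `(k+1)/(n+2)`; no
#' monotonicity is enforced.
#'
#' @param sc the S_comb [trace()] of the calibration recording.
#' @param detected the detected [segmentation()].
#' @param truth the ground-truth [segmentation()].
#' @param bin_ms time bin in milliseconds.
#' @param n_value_bins number of S_comb-value bins over \[0, 1\].
#' @return object of class `"updown_misclass_table"`: data frame with value
#'   bin edges, `p_false_down`, `n_bins` per value bin.
#' @export
misclassification_table <- function(sc, detected, truth, bin_ms = 20,
                                    n_value_bins = 20) {
  det_lab <- states_to_labels(detected, sc)
  tru_lab <- states_to_labels(truth, sc)
  bin_n <- round(bin_ms / 1000 * sc$fs)
  n_bins <- floor(length(sc$samples) / bin_n)
  if (n_bins < 1) stop("recording shorter than one time bin")
  idx <- rep(seq_len(n_bins), each = bin_n)
  take <- seq_len(n_bins * bin_n)
  frac_down <- function(lab) {
    tapply(lab[take] == "down", idx, mean)
  }
  det_down <- frac_down(det_lab) > 0.5
  tru_down <- frac_down(tru_lab) > 0.5
  if (!any(det_down)) stop("no detected-down time bins in the calibration data")
  sc_bin <- tapply(sc$samples[take], idx, mean)
  edges <- seq(0, 1, length.out = n_value_bins + 1)
  vb <- pmin(n_value_bins, pmax(1L, findInterval(sc_bin, edges,
                                                 rightmost.closed = TRUE)))
  p <- rep(NA_real_, n_value_bins)
  n <- integer(n_value_bins)
  for (b in seq_len(n_value_bins)) {
    sel <- det_down & vb == b
    n[b] <- sum(sel)
    if (n[b] > 0) p[b] <- (sum(!tru_down[sel]) + 1) / (n[b] + 2)
  }
  structure(
    list(edges = edges, p_false_down = p, n_bins = n, bin_ms = bin_ms),
    class = "updown_misclass_table"
  )
}

#' Run the full LFP state-detection pipeline
#'
#' Convenience wrapper: calibrates the phase likelihoods on ground truth,
#' computes S_delta, S_beta_gamma and S_comb, fits the three-Gaussian
#' mixture and thresholds into a segmentation.
#'
#' @param lfp a [trace()] at 1 kHz.
#' @param truth ground-truth [segmentation()] (e.g. from
#'   [detect_states_vm()] or a generator).
#' @param cfg a [detection_config()].
#' @param seed seed for the mixture fit.
#' @return list with `states`, `s_delta`, `s_beta_gamma`, `s_comb`, `gmm`,
#'   `tables`.
#' @export
detect_states_lfp <- function(lfp, truth, cfg = detection_config(), seed = 1) {
  tables <- fit_phase_likelihoods(lfp, truth, cfg)
  sd_tr <- s_delta(lfp, tables, cfg)
  sbg_tr <- s_beta_gamma(lfp, cfg)
  sc <- s_comb(sd_tr, sbg_tr)
  gmm <- fit_gmm3(sc$samples, seed = seed)
  states <- threshold_states(sc, gmm, cfg)
  list(states = states, s_delta = sd_tr, s_beta_gamma = sbg_tr, s_comb = sc,
       gmm = gmm, tables = tables)
}
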