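# Independent brute-force oracles used to validate the vectorised
# implementations. These deliberately use naive per-sample loops and must
# never call the functions they check.

# Threshold -> merge sub-min_gap gaps -> drop sub-min_dur runs, one pass,
# up before down, as a plain loop over samples.
oracle_morphology <- function(labels, fs, min_dur = 0.1, min_gap = 0.05) {
  runs <- function(lab) {
    out <- list()
    i <- 1
    while (i <= length(lab)) {
      j <- i
      while (j < length(lab) && lab[j + 1] == lab[i]) j <- j + 1
      out[[length(out) + 1]] <- list(start = i, end = j, value = lab[i])
      i <- j + 1
    }
    out
  }
  for (target in c("up", "down")) {
    rr <- runs(labels)
    for (k in seq_along(rr)) {
      r <- rr[[k]]
      if (r$value != target && k > 1 && k < length(rr) &&
          rr[[k - 1]]$value == target && rr[[k + 1]]$value == target &&
          (r$end - r$start + 1) < round(min_gap * fs)) {
        labels[r$start:r$end] <- target
      }
    }
  }
  rr <- runs(labels)
  for (r in rr) {
    if (r$value %in% c("up", "down") &&
        (r$end - r$start + 1) < round(min_dur * fs)) {
      labels[r$start:r$end] <- "indeterminate"
    }
  }
  labels
}

oracle_threshold_labels <- function(x, up_thr, down_thr) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    out[i] <- if (x[i] > up_thr) "up" else if (x[i] < down_thr) "down" else "indeterminate"
  }
  out
}

# Naive PSTH recount.
oracle_psth_counts <- function(spike_times, event_times, bin, span) {
  edges <- seq(-span[1], span[2], by = bin)
  counts <- integer(length(edges) - 1)
  for (ev in event_times) {
    for (s in spike_times) {
      rel <- s - ev
      for (b in seq_len(length(edges) - 1)) {
        if (rel >= edges[b] && rel < edges[b + 1]) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# Naive per-interval spike counting (half-open intervals).
oracle_state_counts <- function(spike_times, states) {
  counts <- integer(nrow(states))
  for (s in spike_times) {
    for (i in seq_len(nrow(states))) {
      if (s >= states$onset[i] && s < states$offset[i]) {
        counts[i] <- counts[i] + 1
      }
    }
  }
  counts
}

# Naive stretch scan: all spikes of `label` states with the selection and
# containment rules applied literally.
oracle_stretches <- function(spike_times, states, speed, X = 0.4,
                             excl = 0.2, T_avg = 0.2, half = 0.2) {
  fs <- speed$fs
  T_n <- round(T_avg * fs); half_n <- round(half * fs)
  res <- list()
  for (s in spike_times) {
    for (i in seq_len(nrow(states))) {
      if (s < states$onset[i] || s >= states$offset[i]) next
      if (states$label[i] != "up") next
      d <- states$offset[i] - s
      if (d < excl || d > X) next
      if (s - half < states$onset[i] || s + half > states$offset[i]) next
      ci <- round((s - speed$t0) * fs) + 1
      if (ci - half_n < 1 || ci + half_n > length(speed$samples)) next
      res[[length(res) + 1]] <- c(
        center = s,
        pre = mean(speed$samples[(ci - T_n):(ci - 1)]),
        post = mean(speed$samples[(ci + 1):(ci + T_n)])
      )
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

# Mardia's circular-linear correlation via pairwise Pearson correlations,
# an algebraically independent route to the same quantity.
oracle_circ_linear_r <- function(angles_deg, values) {
  a <- angles_deg * pi / 180
  rxc <- stats::cor(values, cos(a))
  rxs <- stats::cor(values, sin(a))
  rcs <- stats::cor(cos(a), sin(a))
  sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
}

# Kolmogorov-Smirnov statistic against the uniform distribution on [0, 360).
ks_uniform_360 <- function(x) {
  n <- length(x)
  u <- sort(x) / 360
  max(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n))
}
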