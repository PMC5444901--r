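#' Stretch-selection configuration
#'
#' Parameters of the spike-triggered phase-speed analysis. Defaults follow
#' the reference analysis: spikes selected between `X = 0.4` s and 0.2 s
#' before the end of a state, averaging window `T = 0.2` s on each side of
#' the spike, full-stretch half-window 0.2 s, control stretches matched in
#' distance-to-state-end and within 50 deg/s in whole-window mean speed.
#'
#' @param X selection-window start before state end, seconds (0.3-0.4).
#' @param exclusion_end end of the selection window before state end (0.2 s).
#' @param T_avg pre/post averaging window, seconds (0.05-0.2).
#' @param half_window half-width of the full stretch, seconds (0.2).
#' @param control_tolerance maximum whole-window mean-speed difference for a
#'   control stretch, deg/s.
#' @param seed seed for control sampling.
#' @return a list of class `"updown_stretch_config"`.
#' @export
stretch_config <- function(X = 0.4, exclusion_end = 0.2, T_avg = 0.2,
                           half_window = 0.2, control_tolerance = 50,
                           seed = 1) {
  stopifnot(T_avg > 0, T_avg <= half_window, X > exclusion_end)
  structure(
    list(X = X, exclusion_end = exclusion_end, T_avg = T_avg,
         half_window = half_window, control_tolerance = control_tolerance,
         seed = seed),
    class = "updown_stretch_config"
  )
}

# Means of a speed trace around a centre sample: pre = [-T, 0), post = (0, T],
# whole = [-half, half]. The spike sample itself belongs to neither pre nor
# post. Returns NULL if the window leaves the trace.
# @noRd
stretch_means <- function(speed, ci, T_n, half_n) {
  n <- length(speed$samples)
  if (ci - half_n < 1 || ci + half_n > n) return(NULL)
  x <- speed$samples
  list(
    pre = mean(x[(ci - T_n):(ci - 1)]),
    post = mean(x[(ci + 1):(ci + T_n)]),
    whole = mean(x[(ci - half_n):(ci + half_n)])
  )
}

#' Collect spike-triggered phase-speed stretches near state ends
#'
#' For each spike of the requested state label that falls between
#' `X` and `exclusion_end` seconds before the end of its state, and whose
#' full `±half_window` stretch lies entirely inside that state, records the
#' pre-spike, post-spike and whole-window mean phase speed.
#'
#' @param spikes a [spike_train()].
#' @param states a [segmentation()].
#' @param speed a [trace()] of phase speed in deg/s (see [phase_speed()]).
#' @param cfg a [stretch_config()].
#' @param label state label, `"up"` or `"down"`.
#' @return data frame of class `"updown_stretches"`: one row per stretch
#'   with `center_time`, `state_label`, `distance_to_end`, `pre_mean`,
#'   `post_mean`, `whole_mean`, `is_control`.
#' @export
collect_spike_stretches <- function(spikes, states, speed,
                                    cfg = stretch_config(), label = "up") {
  idx <- spikes_to_intervals(spikes, states)
  T_n <- round(cfg$T_avg * speed$fs)
  half_n <- round(cfg$half_window * speed$fs)
  rows <- list()
  for (k in seq_along(spikes$times)) {
    i <- idx[k]
    if (is.na(i) || states$label[i] != label) next
    t <- spikes$times[k]
    dist_end <- states$offset[i] - t
    if (dist_end < cfg$exclusion_end || dist_end > cfg$X) next
    if (t - cfg$half_window < states$onset[i] ||
        t + cfg$half_window > states$offset[i]) next
    ci <- time_to_index(speed, t)
    m <- stretch_means(speed, ci, T_n, half_n)
    if (is.null(m)) next
    rows[[length(rows) + 1]] <- data.frame(
      center_time = t, state_label = label, state_index = i,
      distance_to_end = dist_end, pre_mean = m$pre, post_mean = m$post,
      whole_mean = m$whole, is_control = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    center_time = numeric(0), state_label = character(0),
    state_index = integer(0), distance_to_end = numeric(0),
    pre_mean = numeric(0), post_mean = numeric(0), whole_mean = numeric(0),
    is_control = logical(0)
  )
  class(out) <- c("updown_stretches", "data.frame")
  out
}

#' Paired pre/post phase-speed test
#'
#' One-tailed paired t-test of the post-spike versus pre-spike mean phase
#' speed across stretches. `direction = "greater"` tests post > pre (the
#' up-state prediction of causal inhibitory firing: phase accelerates toward
#' the state end after a spike); `"less"` tests post < pre. If every
#' post-pre difference is exactly zero the boundary convention `p = 0.5` is
#' returned.
#'
#' @param stretches an `"updown_stretches"` data frame (>= 2 rows).
#' @param direction `"greater"` or `"less"`.
#' @return list with `n`, `mean_pre`, `mean_post`, `mean_change`,
#'   `statistic`, `p.value`, `direction`.
#' @export
pre_post_test <- function(stretches, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (nrow(stretches) < 2) stop("need at least 2 stretches for the test")
  d <- stretches$post_mean - stretches$pre_mean
  if (all(d == 0)) {
    return(list(n = nrow(stretches), mean_pre = mean(stretches$pre_mean),
                mean_post = mean(stretches$post_mean), mean_change = 0,
                statistic = 0, p.value = 0.5, direction = direction))
  }
  tt <- stats::t.test(stretches$post_mean, stretches$pre_mean, paired = TRUE,
                      alternative = direction)
  list(n = nrow(stretches), mean_pre = mean(stretches$pre_mean),
       mean_post = mean(stretches$post_mean), mean_change = mean(d),
       statistic = unname(tt$statistic), p.value = tt$p.value,
       direction = direction)
}

#' Sample spike-free control stretches matched to data stretches
#'
#' For every data stretch, draws (seeded) one control centre such that the
#' cell fires no spike within the full control window, the control's
#' distance to its state end equals the data stretch's distance (within one
#' sample), and the whole-window mean speeds differ by less than the
#' configured tolerance. Controls are sampled without replacement across
#' data stretches; unmatched stretches are dropped and counted in the match
#' rate.
#'
#' @param spikes the same cell's [spike_train()].
#' @param states a [segmentation()].
#' @param speed a [trace()] of phase speed.
#' @param data_stretches stretches from [collect_spike_stretches()].
#' @param cfg a [stretch_config()] (its `seed` drives the sampling).
#' @return list with `controls` (an `"updown_stretches"` data frame with
#'   `is_control = TRUE`), `match_rate`, `n_unmatched`.
#' @export
sample_control_stretches <- function(spikes, states, speed, data_stretches,
                                     cfg = stretch_config()) {
  T_n <- round(cfg$T_avg * speed$fs)
  half_n <- round(cfg$half_window * speed$fs)
  one_sample <- 1 / speed$fs
  used <- numeric(0)
  rows <- list()
  n_unmatched <- 0L
  with_seed(cfg$seed, {
    for (k in seq_len(nrow(data_stretches))) {
      ds <- data_stretches[k, ]
      cand <- list()
      for (i in which(states$label == ds$state_label)) {
        ct <- states$offset[i] - ds$distance_to_end
        if (ct - cfg$half_window < states$onset[i] ||
            ct + cfg$half_window > states$offset[i]) next
        if (any(abs(spikes$times - ct) <= cfg$half_window)) next
        if (any(abs(used - ct) < one_sample / 2)) next
        ci <- time_to_index(speed, ct)
        m <- stretch_means(speed, ci, T_n, half_n)
        if (is.null(m)) next
        if (abs(m$whole - ds$whole_mean) >= cfg$control_tolerance) next
        cand[[length(cand) + 1]] <- data.frame(
          center_time = ct, state_label = ds$state_label, state_index = i,
          distance_to_end = ds$distance_to_end, pre_mean = m$pre,
          post_mean = m$post, whole_mean = m$whole, is_control = TRUE,
          data_center_time = ds$center_time
        )
      }
      if (!length(cand)) {
        n_unmatched <- n_unmatched + 1L
        next
      }
      pick <- cand[[sample.int(length(cand), 1)]]
      used <- c(used, pick$center_time)
      rows[[length(rows) + 1]] <- pick
    }
  })
  controls <- if (length(rows)) do.call(rbind, rows) else
    data_stretches[0, , drop = FALSE]
  class(controls) <- c("updown_stretches", "data.frame")
  n_data <- nrow(data_stretches)
  if (n_data > 0 && n_unmatched == n_data) {
    warning("no control stretches could be matched")
  }
  list(controls = controls,
       match_rate = if (n_data) 1 - n_unmatched / n_data else NA_real_,
       n_unmatched = n_unmatched)
}

#' Per-cell phase-speed change and its correlates
#'
#' Computes each cell's mean post-minus-pre phase-speed change (cells with
#' fewer than `min_stretches` stretches are excluded), and across eligible
#' cells the Pearson correlation of the change with the circular variance of
#' the phase-of-firing distribution and the circular-linear correlation with
#' the preferred phase. Correlations require at least 3 eligible cells and
#' non-constant changes.
#'
#' @param stretch_list named list of `"updown_stretches"` data frames, one
#'   per cell.
#' @param circ_variance optional named numeric: circular variance of each
#'   cell's phase of firing.
#' @param preferred_deg optional named numeric: preferred phase (degrees).
#' @param min_stretches minimum stretches per cell (10).
#' @return list with `per_cell` data frame (`cell`, `n`, `mean_change`,
#'   `excluded`), `cor_circ_variance` (list r/p or NULL), `cor_preferred`
#'   (list r/p or NULL).
#' @export
per_cell_speed_change <- function(stretch_list, circ_variance = NULL,
                                  preferred_deg = NULL, min_stretches = 10) {
  cells <- names(stretch_list)
  if (is.null(cells)) cells <- paste0("cell", seq_along(stretch_list))
  per <- data.frame(
    cell = cells,
    n = vapply(stretch_list, nrow, integer(1)),
    mean_change = vapply(stretch_list, function(s) {
      if (nrow(s)) mean(s$post_mean - s$pre_mean) else NA_real_
    }, numeric(1))
  )
  per$excluded <- per$n < min_stretches
  elig <- !per$excluded
  res <- list(per_cell = per, cor_circ_variance = NULL, cor_preferred = NULL)
  if (sum(elig) < 3) return(res)
  ch <- per$mean_change[elig]
  if (stats::sd(ch) == 0) {
    res$cor_circ_variance <- list(r = NA_real_, p.value = NA_real_,
                                  note = "changes are constant across cells")
    return(res)
  }
  if (!is.null(circ_variance)) {
    cv <- circ_variance[per$cell[elig]]
    ct <- stats::cor.test(ch, cv)
    res$cor_circ_variance <- list(r = unname(ct$estimate),
                                  p.value = ct$p.value)
  }
  if (!is.null(preferred_deg)) {
    pp <- preferred_deg[per$cell[elig]]
    res$cor_preferred <- tryCatch(circ_linear_corr(pp, ch),
                                  error = function(e) NULL)
  }
  res
}
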