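test_that("CDF rescaling uniformises the phase distribution", {
  # already uniform: rescaling is the identity up to one grid step
  n <- 36000
  ph <- phase_trace(seq(0, 360 - 1e-6, length.out = n), fs = 1000)
  rs <- rescale_phase(ph)
  expect_lt(max(abs(rs$phase - ph$phase)), 360 / n + 0.02)

  # concentrated phases get spread over the full circle
  set.seed(1)
  conc <- phase_trace(runif(20000, 0, 180), fs = 1000)
  rs2 <- rescale_phase(conc)
  expect_gt(max(rs2$phase), 350)
  expect_lt(ks_uniform_360(rs2$phase), 0.01)

  # strongly non-uniform phases from a skewed density
  skew <- phase_trace((rvonmises(1e5, 90, 1.5)), fs = 1000)
  expect_lt(ks_uniform_360(rescale_phase(skew)$phase), 0.01)
})

test_that("phase of firing samples the shifted LFP phase at spike times", {
  # noise-free synthetic spikes at a fixed 167 deg preference
  n <- 120 * 1000
  ph <- phase_trace((seq_len(n) - 1) * 360 / 1000, fs = 1000)  # 1 Hz
  spike_samples <- which(abs(((ph$phase - 167 + 180) %% 360) - 180) < 0.2)
  sp <- spike_train((spike_samples - 1) / 1000)
  pof <- phase_of_firing(sp, ph, 0)
  expect_true(all(abs(((pof$angles - 167 + 180) %% 360) - 180) < 0.5))

  # shifting the LFP by tau samples the phase at t - tau: on a forward 1 Hz
  # oscillation tau = +0.1 s rotates the angles by -36 deg
  pof_shift <- phase_of_firing(sp, ph, 0.1)
  d <- ((pof_shift$angles - pof$angles[seq_along(pof_shift$angles)] + 180) %%
          360) - 180
  expect_lt(max(abs(d + 36)), 0.5)

  # negative tau probes the post-spike phase
  pof_neg <- phase_of_firing(sp, ph, -0.1)
  d2 <- ((pof_neg$angles - 167 + 180) %% 360) - 180
  expect_lt(max(abs(d2 - 36)), 0.5)

  # boundary contract: out-of-range shifted spikes dropped and counted
  sp_end <- spike_train(c(1, 119.9999))
  pof_end <- phase_of_firing(sp_end, ph, -0.5)
  expect_equal(pof_end$n_dropped, 1)
  expect_equal(pof_end$n_spikes, 1)
  expect_error(phase_of_firing(spike_train(119.9999), ph, -0.5), "outside")
})

test_that("locking strength equals the mean resultant length", {
  expect_equal(locking_strength(rep(42, 10)), 1)
  expect_equal(locking_strength(c(0, 90, 180, 270)), 0, tolerance = 1e-12)
  set.seed(2)
  ang <- runif(500, 0, 360)
  direct <- sqrt(mean(cos(ang * pi / 180))^2 + mean(sin(ang * pi / 180))^2)
  expect_equal(locking_strength(ang), direct, tolerance = 1e-12)
  # von Mises kappa = 1: population resultant is I1(1)/I0(1)
  bessel <- besselI(1, 1) / besselI(1, 0)
  set.seed(3)
  expect_lt(abs(locking_strength(rvonmises(1e5, 10, 1)) - bessel), 0.01)
})

test_that("Rayleigh test is calibrated against a Monte-Carlo null", {
  set.seed(4)
  expect_lt(rayleigh_p(rep(90, 100)), 1e-10)
  # n = 50, moderate concentration: analytic p within Monte-Carlo error of
  # the simulated null distribution of the resultant
  ang <- rvonmises(50, 0, 0.5)
  robs <- locking_strength(ang)
  null_r <- replicate(20000, locking_strength(runif(50, 0, 360)))
  p_mc <- mean(null_r >= robs)
  p_an <- rayleigh_p(ang)
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(p_an - p_mc), 4 * se + 0.005)
  expect_error(rayleigh_p(runif(5, 0, 360)), "at least 10")
})

test_that("circular median and IQR handle wrap-around and ties", {
  pp <- preferred_phase(c(rep(170, 4), rep(180, 3), rep(190, 3)))
  expect_equal(pp$median_deg, 180)
  expect_equal(circ_median(c(170, 180, 190)), 180)
  expect_equal(circ_median(c(350, 0, 10)), 0)
  pp2 <- preferred_phase(c(rep(350, 3), rep(0, 4), rep(10, 3)))
  expect_equal(pp2$median_deg, 0)
  expect_equal(pp2$iqr_deg, 20)
  set.seed(5)
  pp3 <- preferred_phase(rvonmises(1e4, 170, 2))
  expect_lt(abs(pp3$median_deg - 170), 3)
  expect_error(preferred_phase(c(1, 2, 3)), "at least 10")
})

test_that("causal-window derivation: clamp rule and undefined tau_end", {
  taus <- seq(-0.5, 0.5, by = 0.01)
  # strength exceeds the tau >= 0 maximum all the way down to -0.5 s
  strength <- ifelse(taus < 0, 0.8, 0.4)
  p <- rep(1e-6, length(taus))
  cw <- updownphase:::profile_causal_window(taus, strength, p, 0.01)
  expect_equal(cw$tau_end, -0.5)
  expect_equal(cw$tau_max, -0.5)

  # significance gap at -0.2 s interrupts the run
  p2 <- p; p2[which.min(abs(taus + 0.2))] <- 0.5
  cw2 <- updownphase:::profile_causal_window(taus, strength, p2, 0.01)
  expect_equal(cw2$tau_end, -0.19)

  # no negative shift beats the non-causal maximum: tau_end undefined
  flat <- rep(0.5, length(taus)); flat[taus == 0] <- 0.6
  cw3 <- updownphase:::profile_causal_window(taus, flat, p, 0.01)
  expect_true(is.na(cw3$tau_end))
})

test_that("locking profile excludes sparse cells instead of failing", {
  ph <- phase_trace((seq_len(60000) - 1) * 360 / 1000, fs = 1000)
  few <- spike_train(seq(1, 50, by = 1))
  prof <- shifted_locking_profile(few, ph)
  expect_true(prof$excluded)
  expect_match(prof$reason, "50 spikes")
  many <- spike_train(seq(0.5, 59, by = 0.4))
  prof2 <- shifted_locking_profile(many, ph)
  expect_false(prof2$excluded)
  expect_equal(length(prof2$strength), 101)
  expect_true(all(prof2$strength >= 0 & prof2$strength <= 1))
})

test_that("per-state firing statistics match a brute-force recount", {
  st <- gen_state_sequence(60, seed = 6)
  set.seed(7)
  sp <- spike_train(sort(runif(300, 0, 60)))
  stats_ <- state_firing_stats(sp, st)
  counts <- oracle_state_counts(sp$times, st)
  for (lab in c("up", "down")) {
    k <- counts[st$label == lab]
    expect_equal(stats_[[lab]]$n_spikes, sum(k))
    expect_equal(stats_[[lab]]$pct_active, 100 * mean(k >= 1))
    expect_equal(stats_[[lab]]$spikes_per_active, mean(k[k >= 1]))
  }
  expect_equal(stats_$rate_hz, 300 / 60)

  # spikes only in up states
  up_only <- spike_train((st$onset + st$offset)[st$label == "up"] / 2)
  s2 <- state_firing_stats(up_only, st)
  expect_equal(s2$down$pct_active, 0)

  # one spike in half of the up states
  ups <- which(st$label == "up")
  half <- ups[seq(1, length(ups), by = 2)]
  sp3 <- spike_train((st$onset + st$offset)[half] / 2)
  s3 <- state_firing_stats(sp3, st)
  expect_equal(s3$up$pct_active, 100 * length(half) / length(ups))
  expect_equal(s3$up$spikes_per_active, 1)
})

test_that("strength and reliability histograms coincide for single spikes", {
  st <- segmentation(data.frame(
    onset = seq(0, 18, by = 2), offset = seq(1, 19, by = 2),
    label = "up"
  ))
  full <- segmentation(data.frame(
    onset = c(rbind(seq(0, 18, by = 2), seq(1, 19, by = 2))),
    offset = c(rbind(seq(1, 19, by = 2), seq(2, 20, by = 2))),
    label = rep(c("up", "down"), 10)
  ))
  ph <- phase_trace(rep(185, 20000), fs = 1000)  # all spikes in one bin
  one_per <- spike_train(st$onset + 0.5)
  h <- strength_reliability_histograms(one_per, full, ph, "up")
  bin185 <- findInterval(185, h$edges)
  expect_equal(h$strength[bin185], 1)
  expect_equal(h$reliability[bin185], 1)
  expect_true(all(h$strength[-bin185] == 0))
  expect_equal(h$pearson_r, 1)

  two_per <- spike_train(sort(c(st$onset + 0.4, st$onset + 0.6)))
  h2 <- strength_reliability_histograms(two_per, full, ph, "up")
  expect_equal(h2$strength[bin185], 2)
  expect_equal(h2$reliability[bin185], 1)

  # Poisson spiking: Pearson r against a direct recount
  set.seed(8)
  pois <- spike_train(sort(runif(400, 0, 20)))
  ph2 <- phase_trace((seq_len(20000) - 1) * 360 / 1000, fs = 1000)
  h3 <- strength_reliability_histograms(pois, full, ph2, "up")
  counts <- matrix(0, sum(full$label == "up"), 36)
  occ <- which(full$label == "up")
  for (ii in seq_along(occ)) {
    i <- occ[ii]
    sel <- pois$times >= full$onset[i] & pois$times < full$offset[i]
    ang <- ph2$phase[round(pois$times[sel] * 1000) + 1]
    b <- pmin(36, floor(ang / 10) + 1)
    for (bb in b) counts[ii, bb] <- counts[ii, bb] + 1
  }
  expect_equal(h3$strength, colMeans(counts), tolerance = 1e-12)
  expect_equal(h3$reliability, colMeans(counts >= 1), tolerance = 1e-12)
  expect_equal(h3$pearson_r, stats::cor(colMeans(counts), colMeans(counts >= 1)),
               tolerance = 1e-12)

  expect_error(strength_reliability_histograms(pois, full[1:3, ], ph2, "up"),
               "occurrences")
})

test_that("circular-linear correlation matches its regression definition", {
  set.seed(9)
  ang <- runif(200, 0, 360)
  perfect <- circ_linear_corr(ang, sin(ang * pi / 180))
  expect_equal(perfect$r, 1, tolerance = 1e-9)

  vals <- rnorm(200) + 0.5 * cos(ang * pi / 180) - 0.3 * sin(ang * pi / 180)
  got <- circ_linear_corr(ang, vals)
  expect_equal(got$r, oracle_circ_linear_r(ang, vals), tolerance = 1e-10)

  # independence: r stays small
  null_r <- replicate(20, circ_linear_corr(runif(1e4, 0, 360), rnorm(1e4))$r)
  expect_gt(mean(null_r < 0.05), 0.9)

  expect_error(circ_linear_corr(ang, rep(1, 200)), "constant")
})

test_that("down-state spike test multiplies per-bin misclassification factors", {
  fs <- 1000
  tab <- structure(
    list(edges = seq(0, 1, by = 0.05),
         p_false_down = c(rep(0.05, 10), rep(1, 10)),
         n_bins = rep(10L, 20), bin_ms = 20),
    class = "updown_misclass_table"
  )
  sc_low <- trace(rep(0.1, 2000), fs = fs)   # value bin with p = 0.05
  down_seg <- segmentation(data.frame(onset = 0, offset = 2, label = "down"))
  one <- down_state_spike_test(spike_train(0.55), down_seg, sc_low, tab)
  expect_equal(one$p, 0.05)

  sc_high <- trace(rep(0.9, 2000), fs = fs)  # value bin with p = 1
  all_one <- down_state_spike_test(spike_train(c(0.1, 0.5, 1.5)), down_seg,
                                   sc_high, tab)
  expect_equal(all_one$p, 1)

  # product is non-increasing as spike-containing bins are added
  p_seq <- vapply(1:5, function(k) {
    down_state_spike_test(spike_train(seq(0.1, by = 0.3, length.out = k)),
                          down_seg, sc_low, tab)$p
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 0))

  # per-spike option double-counts bins with several spikes
  two_same_bin <- spike_train(c(0.101, 0.105))
  pb <- down_state_spike_test(two_same_bin, down_seg, sc_low, tab)
  ps <- down_state_spike_test(two_same_bin, down_seg, sc_low, tab,
                              per_spike = TRUE)
  expect_equal(pb$p, 0.05)
  expect_equal(ps$p, 0.05^2)
})
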