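test_that("Vm state detection matches the generator truth and enforces morphology", {
  st <- gen_state_sequence(120, seed = 1)
  vm <- gen_vm(st, levels = c(-70, -55), noise_sd = 1, seed = 2)
  seg <- detect_states_vm(vm)
  agree <- mean(states_to_labels(seg, vm) == states_to_labels(st, vm))
  expect_gt(agree, 0.95)

  expect_error(detect_states_vm(trace(rnorm(5000, -60, 1), fs = 1000)),
               "bimodal")
})

test_that("threshold/morphology stage honours the 100 ms and 50 ms rules", {
  fs <- 1000
  gmm <- structure(
    list(weight = c(1, 1, 1) / 3, mean = c(0.15, 0.5, 0.85),
         sd = c(0.03, 0.05, 0.03), loglik = 0, n_iter = 1,
         roles = c("down", "indeterminate", "up")),
    class = "updown_gmm3"
  )
  # 80 ms excursion above the up threshold -> indeterminate
  x <- c(rep(0.15, 500), rep(0.9, 80), rep(0.15, 500))
  seg <- threshold_states(trace(x, fs = fs), gmm)
  expect_false(any(seg$label == "up"))

  # two up intervals separated by a 40 ms sub-threshold gap -> merged
  x2 <- c(rep(0.9, 300), rep(0.5, 40), rep(0.9, 300), rep(0.15, 300))
  seg2 <- threshold_states(trace(x2, fs = fs), gmm)
  ups <- seg2[seg2$label == "up", ]
  expect_equal(nrow(ups), 1)
  expect_equal(ups$offset - ups$onset, 0.640)

  # square wave maps onto its segments
  x3 <- rep(rep(c(0.9, 0.1), 3), each = 1000)
  seg3 <- threshold_states(trace(x3, fs = fs), gmm)
  expect_equal(seg3$label, rep(c("up", "down"), 3))
  expect_equal(seg3$offset - seg3$onset, rep(1, 6))

  bad <- gmm; bad$mean <- c(0.45, 0.5, 0.55); bad$sd <- c(0.2, 0.05, 0.2)
  expect_error(threshold_states(trace(x3, fs = fs), bad), "crossed")
})

test_that("threshold/morphology equals the brute-force oracle on random traces", {
  set.seed(99)
  gmm <- structure(
    list(weight = c(1, 1, 1) / 3, mean = c(0.2, 0.5, 0.8),
         sd = c(0.05, 0.05, 0.05), loglik = 0, n_iter = 1,
         roles = c("down", "indeterminate", "up")),
    class = "updown_gmm3"
  )
  up_thr <- 0.8 - 2 * 0.05
  down_thr <- 0.2 + 2 * 0.05
  for (rep in 1:30) {
    # random piecewise-constant trace with state-scale runs
    n_seg <- sample(5:20, 1)
    lens <- sample(c(20:60, 150:400), n_seg, replace = TRUE)
    vals <- sample(c(0.1, 0.3, 0.5, 0.7, 0.9), n_seg, replace = TRUE)
    x <- rep(vals, lens)
    seg <- threshold_states(trace(x, fs = 1000), gmm)
    got <- states_to_labels(seg, trace(x, fs = 1000))
    want <- oracle_morphology(oracle_threshold_labels(x, up_thr, down_thr),
                              1000)
    expect_identical(got, want)
  }
})

test_that("phase likelihood tables are normalised and informative on synthetic LFP", {
  st <- gen_state_sequence(200, seed = 5)
  gl <- gen_lfp(st, seed = 6)
  tabs <- fit_phase_likelihoods(gl$lfp, st)
  for (tab in tabs$tables) {
    expect_equal(sum(tab$p_up), 1)
    expect_equal(sum(tab$p_down), 1)
    expect_true(all(tab$p_up > 0) && all(tab$p_down > 0))
  }
  # ground-truth phase: up states spend > 80% of their time in the 112-264
  # range (the estimated-phase tables below are smeared by the band filter)
  lab <- states_to_labels(st, gl$lfp)
  p_true <- gl$phase$phase[lab == "up"] %% 360
  expect_gt(mean(p_true > 112 & p_true < 264), 0.8)
  # estimated-phase tables still concentrate up mass in the up range and
  # separate the classes by a large factor there
  mids <- tabs$edges[-1] - 5
  in_up <- mids > 112 & mids < 264
  for (tab in tabs$tables) {
    expect_gt(sum(tab$p_up[in_up]), 0.6)
    expect_gt(sum(tab$p_up[in_up]) / sum(tab$p_down[in_up]), 5)
  }

  expect_error(
    fit_phase_likelihoods(gl$lfp, st[st$label == "up", ][1:5, ]),
    "at least"
  )
})

test_that("uninformative phases give flat likelihoods and s_delta near 0.5", {
  set.seed(7)
  st <- gen_state_sequence(120, seed = 7)
  noise <- trace(rnorm(120000), fs = 1000)
  tabs <- fit_phase_likelihoods(noise, st)
  for (tab in tabs$tables) {
    kl <- sum(tab$p_up * log(tab$p_up / tab$p_down))
    expect_lt(kl, 0.05)
  }
  sdt <- s_delta(noise, tabs)
  expect_lt(abs(mean(sdt$samples) - 0.5), 0.05)
})

test_that("s_delta follows the logistic log-likelihood-ratio arithmetic", {
  # hand-built tables: ratio 9 in both bands for phases in one bin
  n_bins <- 36
  edges <- seq(0, 360, length.out = n_bins + 1)
  p_up <- rep(1, n_bins); p_down <- rep(1, n_bins)
  p_up[1] <- 9
  tabs <- structure(
    list(tables = list(list(band = c(0, 1), p_up = p_up / sum(p_up),
                            p_down = p_down / sum(p_down)),
                       list(band = c(1, 3), p_up = p_up / sum(p_up),
                            p_down = p_down / sum(p_down))),
         edges = edges, n_bins = n_bins),
    class = "updown_likelihood_tables"
  )
  # two tones, one per band, peak-aligned every 2 s: at those instants both
  # band phases sit in bin 1 and the log-likelihood ratios add
  t <- seq(0, 60, by = 1e-3)
  tr <- trace(cos(2 * pi * 0.5 * t) + cos(2 * pi * 2 * t), fs = 1000)
  sdt <- s_delta(tr, tabs)
  ratio_up <- (9 / sum(p_up)) / (1 / sum(p_down))
  expected_max <- stats::plogis(2 * log(ratio_up))
  expect_lt(abs(max(sdt$samples[5000:55000]) - expected_max), 1e-6)
  # uninformative bins give exactly the complementary logistic value
  expected_flat <- stats::plogis(2 * log((1 / sum(p_up)) / (1 / sum(p_down))))
  expect_lt(abs(stats::median(sdt$samples) - expected_flat), 1e-6)

  # on synthetic data s_delta separates the states
  st <- gen_state_sequence(200, seed = 8)
  gl <- gen_lfp(st, seed = 9)
  tabs2 <- fit_phase_likelihoods(gl$lfp, st)
  sd2 <- s_delta(gl$lfp, tabs2)
  lab <- states_to_labels(st, gl$lfp)
  expect_gt(mean(sd2$samples[lab == "up"]), mean(sd2$samples[lab == "down"]))
})

test_that("s_beta_gamma implements RMS, smoothing and min-max normalisation", {
  expect_warning(
    z <- s_beta_gamma(trace(rep(0, 2000), fs = 1000)),
    "constant"
  )
  expect_true(all(z$samples == 0))

  # 25 Hz tone gated on/off in 500 ms blocks
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  gate <- rep(rep(c(1, 0), 10), each = 500)
  tr <- trace(sin(2 * pi * 25 * t) * gate, fs = 1000)
  sbg <- s_beta_gamma(tr)
  on_idx <- which(gate == 1)
  off_idx <- which(gate == 0)
  keep <- function(idx) idx[(idx %% 500) %in% 150:350]
  expect_gt(mean(sbg$samples[keep(on_idx)]), 0.8)
  expect_lt(mean(sbg$samples[keep(off_idx)]), 0.2)
  expect_equal(min(sbg$samples), 0)
  expect_equal(max(sbg$samples), 1)

  # scale invariance for noise-free input
  sbg2 <- s_beta_gamma(trace(tr$samples * 7.3, fs = 1000))
  expect_equal(sbg$samples, sbg2$samples, tolerance = 1e-12)

  expect_error(s_beta_gamma(trace(rnorm(500), fs = 1000)), "1 s")
})

test_that("s_comb is the elementwise mean with bounds preserved", {
  a <- trace(c(0.2, 0.4, 1), fs = 1000)
  b <- trace(c(0.8, 0.4, 0), fs = 1000)
  expect_equal(s_comb(a, b)$samples, c(0.5, 0.4, 0.5))
  expect_equal(s_comb(a, a)$samples, a$samples)
  expect_error(s_comb(a, trace(c(1, 2), fs = 1000)), "equal length")
})

test_that("three-Gaussian EM recovers mixture parameters and is deterministic", {
  set.seed(11)
  x <- c(rnorm(15000, 0.15, 0.05), rnorm(20000, 0.5, 0.08),
         rnorm(15000, 0.85, 0.05))
  fit <- fit_gmm3(x, seed = 3)
  expect_lt(max(abs(fit$mean - c(0.15, 0.5, 0.85))), 0.02)
  fit2 <- fit_gmm3(x, seed = 3)
  expect_identical(fit$mean, fit2$mean)

  # cross-check against an independent EM implementation
  suppressMessages(library(mclust))
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(mc$parameters$mean) - fit$mean)), 0.01)

  expect_error(fit_gmm3(rep(0.5, 2000)), "degenerate")
  expect_error(fit_gmm3(x[1:500]), "at least 1000")
})

test_that("ROC analysis is calibrated on perfect and uninformative detectors", {
  st <- gen_state_sequence(120, seed = 13)
  ref <- trace(numeric(120000), fs = 1000)
  lab <- states_to_labels(st, ref)
  perfect <- trace(as.numeric(lab == "up"), fs = 1000)
  roc <- roc_evaluate(perfect, st)
  expect_equal(roc$auc_up, 1)
  expect_equal(roc$auc_down, 1)

  set.seed(14)
  noise <- trace(runif(120000), fs = 1000)
  roc2 <- roc_evaluate(noise, st)
  expect_lt(abs(roc2$auc_up - 0.5), 0.02)

  only_up <- segmentation(data.frame(onset = 0, offset = 120, label = "up"))
  expect_error(roc_evaluate(noise, only_up), "both")
})

test_that("misclassification table matches analytic expectations", {
  st <- gen_state_sequence(300, seed = 15)
  ref <- trace(numeric(300000), fs = 1000)
  lab <- states_to_labels(st, ref)
  sc <- trace(ifelse(lab == "up", 0.8, 0.2), fs = 1000)

  # detector identical to truth: error probability at the Laplace floor
  tab <- misclassification_table(sc, st, st)
  occ <- !is.na(tab$p_false_down)
  expect_true(all(tab$p_false_down[occ] < 0.05))

  # detector that calls down at random: among detected-down bins the truly-up
  # fraction equals the marginal up occupancy
  set.seed(16)
  rand_lab <- sample(c("down", "up"), 300000, replace = TRUE)
  rand_seg <- labels_to_states(rand_lab, 1000, 0)
  sc_flat <- trace(rep(0.45, 300000), fs = 1000)
  tab2 <- misclassification_table(sc_flat, rand_seg, st)
  p_occ <- tab2$p_false_down[!is.na(tab2$p_false_down)]
  n_occ <- tab2$n_bins[!is.na(tab2$p_false_down)]
  est <- sum(p_occ * n_occ) / sum(n_occ)
  truly_up_frac <- mean(lab == "up")
  expect_lt(abs(est - truly_up_frac), 0.05)
  expect_true(all(p_occ >= 0 & p_occ <= 1))
})
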