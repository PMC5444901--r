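#' Run the full analysis pipeline from a configuration
#'
#' Wires the pipeline stages together with seeded reproducibility: simulate
#' (optional) -> detect -> lock -> speed, writing CSV outputs and a JSON
#' report into `out_dir`. Each stochastic stage receives a seed derived
#' deterministically from the master seed, so running the same
#' configuration twice produces byte-identical outputs.
#'
#' The configuration is a named list (or path to a JSON file) with
#' components:
#' \describe{
#'   \item{`seed`}{master integer seed (required).}
#'   \item{`simulate`}{optional list passed to [simulate_recording()]
#'     (`total_dur`, `mode`, parameter overrides).}
#'   \item{`inputs`}{alternatively, paths: `lfp` (CSV trace), `spikes`
#'     (spike-time file), `truth` (segmentation CSV).}
#'   \item{`detect`}{optional overrides for [detection_config()].}
#'   \item{`lock`}{optional: `grid_step`, `alpha`, `min_spikes`.}
#'   \item{`speed`}{optional overrides for [stretch_config()] plus
#'     `label` and `direction`.}
#' }
#'
#' @param config named list or path to a JSON configuration file.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the report list, also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config_path <- NULL
  }
  if (is.null(config$seed)) stop("config must provide a master 'seed'")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("updownphase")),
    seed = seed,
    config = config
  )
  if (!is.null(config_path)) {
    report$config_md5 <- unname(tools::md5sum(config_path))
  }

  # -- inputs: simulate or load --------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    gt <- do.call(simulate_recording, sim_args)
    lfp <- gt$lfp; spikes <- gt$spikes; truth <- gt$states
    write_trace(lfp, file.path(out_dir, "lfp.csv"))
    write_trace(gt$vm, file.path(out_dir, "vm.csv"))
    write_spike_train(spikes, file.path(out_dir, "spikes.txt"))
    write_segmentation(truth, file.path(out_dir, "states_true.csv"))
    report$simulate <- list(n_states = nrow(truth),
                            n_spikes = length(spikes$times),
                            duration_s = trace_duration(lfp))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$lfp) || !file.exists(inp$lfp)) {
      stop("[inputs] LFP trace file missing: ", inp$lfp)
    }
    lfp <- read_trace(inp$lfp)
    spikes <- if (!is.null(inp$spikes)) {
      if (!file.exists(inp$spikes)) stop("[lock] spike file missing: ", inp$spikes)
      read_spike_train(inp$spikes)
    } else {
      NULL
    }
    truth <- if (!is.null(inp$truth)) read_segmentation(inp$truth) else NULL
  } else {
    stop("config must provide either 'simulate' or 'inputs'")
  }

  # -- detect ---------------------------------------------------------------
  cfg <- do.call(detection_config, as.list(config$detect))
  if (is.null(truth)) stop("[detect] ground-truth segmentation required")
  det <- detect_states_lfp(lfp, truth, cfg, seed = seed + 101L)
  write_segmentation(det$states, file.path(out_dir, "states_detected.csv"))
  roc_c <- roc_evaluate(det$s_comb, truth)
  roc_d <- roc_evaluate(det$s_delta, truth)
  det_lab <- states_to_labels(det$states, lfp)
  tru_lab <- states_to_labels(truth, lfp)
  report$detect <- list(
    n_states = nrow(det$states),
    up_threshold = det$gmm$mean[3] - 2 * det$gmm$sd[3],
    down_threshold = det$gmm$mean[1] + 2 * det$gmm$sd[1],
    auc_s_comb = roc_c$auc_up, auc_s_delta = roc_d$auc_up,
    fpr_up = mean(det_lab[tru_lab == "down"] == "up"),
    fpr_down = mean(det_lab[tru_lab == "up"] == "down"),
    agreement = mean((det_lab == tru_lab)[det_lab != "indeterminate"])
  )

  # -- lock -----------------------------------------------------------------
  if (!is.null(spikes)) {
    lk <- config$lock
    phase <- instantaneous_phase(lfp, c(0.1, 4), method = cfg$phase_method)
    prof <- shifted_locking_profile(
      spikes, phase,
      grid_step = if (is.null(lk$grid_step)) 0.01 else lk$grid_step,
      alpha = if (is.null(lk$alpha)) 0.01 else lk$alpha,
      min_spikes = if (is.null(lk$min_spikes)) 100 else lk$min_spikes
    )
    if (!isTRUE(prof$excluded)) {
      pof0 <- phase_of_firing(spikes, rescale_phase(phase), 0)
      pp <- preferred_phase(pof0$angles)
      report$lock <- list(
        n_spikes = prof$n_spikes, tau_max = prof$tau_max,
        tau_end = prof$tau_end, strength_tau0 = locking_strength(pof0),
        rayleigh_p_tau0 = rayleigh_p(pof0),
        preferred_deg = pp$median_deg, iqr_deg = pp$iqr_deg
      )
      utils::write.csv(
        data.frame(tau = prof$tau_grid, strength = prof$strength,
                   p_corrected = prof$p_values),
        file.path(out_dir, "locking_profile.csv"), row.names = FALSE
      )
    } else {
      report$lock <- list(excluded = TRUE, reason = prof$reason)
    }

    # -- speed --------------------------------------------------------------
    sp_over <- as.list(config$speed)
    label <- if (is.null(sp_over$label)) "up" else sp_over$label
    direction <- if (is.null(sp_over$direction)) "greater" else sp_over$direction
    sp_over$label <- NULL; sp_over$direction <- NULL
    scfg <- do.call(stretch_config, c(sp_over, list(seed = seed + 202L)))
    speed_tr <- phase_speed(phase)
    stretches <- collect_spike_stretches(spikes, det$states, speed_tr, scfg,
                                         label = label)
    report$speed <- list(n_stretches = nrow(stretches))
    if (nrow(stretches) >= 2) {
      pt <- pre_post_test(stretches, direction)
      ctl <- sample_control_stretches(spikes, det$states, speed_tr,
                                      stretches, scfg)
      report$speed <- c(report$speed, list(
        mean_change = pt$mean_change, p.value = pt$p.value,
        control_match_rate = ctl$match_rate,
        control_p = if (nrow(ctl$controls) >= 2) {
          pre_post_test(ctl$controls, direction)$p.value
        } else {
          NA_real_
        }
      ))
      stretches$data_center_time <- NA_real_
      all_stretches <- if (nrow(ctl$controls)) {
        rbind(stretches, ctl$controls)
      } else {
        stretches
      }
      utils::write.csv(all_stretches, file.path(out_dir, "stretches.csv"),
                       row.names = FALSE)
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
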