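#' Read behavior events from CSV
#'
#' The event format has columns `experiment_id`, `larva_id`, `event`
#' (`run_start`, `run_end` or `turn`) and `time_s`. A `turn` event both
#' records a turn and closes the current run; `run_end` closes a run
#' without a turn. Reading validates that every event label is known, that
#' runs are properly nested, and that turns fall at the end of a run.
#'
#' @param path CSV file path.
#' @param duration experiment duration (s); defaults to the latest event
#'   time.
#' @param frame_period behavior frame interval (s).
#' @return a `behavior_dataset`.
#' @export
read_events <- function(path, duration = NULL, frame_period = 1 / 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "larva_id", "event", "time_s")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!df$event %in% c("run_start", "run_end", "turn"))
  if (length(bad))
    stop("malformed event label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$time_s) else 0
  experiments <- lapply(split(df, df$experiment_id), function(de) {
    larvae <- lapply(split(de, de$larva_id), function(dl) {
      dl <- dl[order(dl$time_s), ]
      t0 <- NA_real_; runs <- list(); turns <- numeric(0)
      for (r in seq_len(nrow(dl))) {
        ev <- dl$event[r]; tt <- dl$time_s[r]
        if (ev == "run_start") {
          if (!is.na(t0)) stop("run_start inside an open run (larva ",
                               dl$larva_id[1], ")")
          t0 <- tt
        } else {
          if (is.na(t0)) stop(ev, " outside any run at time ", tt,
                              " (larva ", dl$larva_id[1], ")")
          runs[[length(runs) + 1L]] <- c(t0, tt)
          if (ev == "turn") turns <- c(turns, tt)
          t0 <- NA_real_
        }
      }
      if (!is.na(t0)) runs[[length(runs) + 1L]] <- c(t0, duration)
      ri <- if (length(runs))
        as.data.frame(do.call(rbind, runs)) else data.frame(V1 = numeric(0),
                                                            V2 = numeric(0))
      names(ri) <- c("t0", "t1")
      list(larva_id = dl$larva_id[1], run_intervals = ri,
           turn_times = turns)
    })
    list(experiment_id = de$experiment_id[1], stimulus = NULL,
         larvae = unname(larvae))
  })
  new_behavior_dataset(unname(experiments), duration, frame_period)
}

#' Write behavior events to CSV
#'
#' Inverse of [read_events()]: `write_events` then `read_events` restores
#' the run intervals and turn times exactly.
#'
#' @param data a `behavior_dataset`.
#' @param path output CSV path.
#' @export
write_events <- function(data, path) {
  rows <- list()
  for (e in data$experiments) for (l in e$larvae) {
    ri <- l$run_intervals
    for (k in seq_len(nrow(ri))) {
      is_turn <- any(abs(l$turn_times - ri$t1[k]) < 1e-9)
      end_ev <- if (is_turn) "turn"
                else if (abs(ri$t1[k] - data$duration) < 1e-9) NA
                else "run_end"
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = e$experiment_id, larva_id = l$larva_id,
        event = c("run_start", end_ev), time_s = c(ri$t0[k], ri$t1[k]))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(experiment_id = character(0), larva_id = character(0),
               event = character(0), time_s = numeric(0))
  df <- df[stats::complete.cases(df), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stimulus trace CSV + schedule JSON round trip
#'
#' `write_stimulus` writes columns `time_s`, `channel`, `intensity` and a
#' JSON sidecar `<path>.schedule.json` with the schedule
#' (`{mode, segments: [{t0, t1, value}]}`). `read_stimulus` restores the
#' trace (update period inferred from the time grid).
#'
#' @param trace a `stimulus_trace`.
#' @param path CSV path.
#' @export
write_stimulus <- function(trace, path) {
  t <- (seq_along(trace$intensities) - 1) * trace$update_period
  utils::write.csv(data.frame(time_s = t, channel = trace$channel,
                              intensity = trace$intensities),
                   path, row.names = FALSE)
  sch <- trace$schedule
  jsonlite::write_json(
    list(mode = sch$mode, duration = sch$duration,
         segments = sch$segments, period = sch$period,
         sigma_min = sch$sigma_min, sigma_max = sch$sigma_max),
    paste0(path, ".schedule.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @param kind trace kind (`"walk"` or `"levels"`).
#' @export
read_stimulus <- function(path, kind = "walk") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  js <- jsonlite::read_json(paste0(path, ".schedule.json"),
                            simplifyVector = TRUE)
  sch <- if (js$mode == "triangle_sd")
    variance_schedule("triangle_sd", duration = js$duration,
                      period = js$period, sigma_min = js$sigma_min,
                      sigma_max = js$sigma_max)
  else
    variance_schedule(js$mode, as.data.frame(js$segments),
                      duration = js$duration)
  up <- stats::median(diff(df$time_s))
  new_stimulus_trace(df$channel[1], up, df$intensity, sch, kind = kind)
}

#' Kernel JSON round trip
#'
#' @param k a [kernel()].
#' @param path JSON path.
#' @export
write_kernel <- function(k, path) {
  jsonlite::write_json(list(lag_s = k$lag, weight = k$weights,
                            normalization = k$normalization),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernel(js$lag_s, js$weight, normalization = js$normalization)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with the standard defaults: 20 Hz behavior
#' frames, 8 rate bins, 5 s tracker prior, 100 bootstrap replicates, 60 s
#' burn-in, and post-switch discards of 15 s (60 s half-cycles) or 10 s
#' (20 s half-cycles). One global seed spawns per-stage streams (stage
#' index offsets), so changing one stage's replicate count does not perturb
#' the simulation draws.
#'
#' @param n_experiments,n_larvae,duration study scale.
#' @param half_period variance switching half-period (s).
#' @param sigma2_high,sigma2_low increment variances of the two conditions.
#' @param rate generating [static_rate()].
#' @param alpha_by_condition generating gains for the step-control model,
#'   or NULL for no adaptation.
#' @param seed global RNG seed.
#' @param burn_in,cycle_discard discard policy (s); `cycle_discard = NA`
#'   picks 15 s or 10 s from the half-period.
#' @param n_bins,n_boot,prior_tau,track_step analysis settings.
#' @param do_track run the (slower) gain-tracking stage.
#' @export
pipeline_config <- function(n_experiments = 2, n_larvae = 20,
                            duration = 300, half_period = 20,
                            sigma2_high = 9, sigma2_low = 1,
                            rate = static_rate(3 / 60, b = 0.5, c = 0.03),
                            alpha_by_condition = c(high = 1, low = 2),
                            seed = 1, burn_in = 60, cycle_discard = NA,
                            n_bins = 8, n_boot = 100, prior_tau = 5,
                            track_step = 0.1, do_track = TRUE) {
  if (is.na(cycle_discard))
    cycle_discard <- if (half_period >= 60) 15 else 10
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> reverse correlation -> rescaling-model fits ->
#' gain tracking as configured, logging discard counts and stage progress,
#' and returns the bundled results. With an `out_dir`, events, kernel,
#' binned rates, fit report and a manifest (seed and config echo) are
#' written as CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with the dataset, kernel (+bootstrap band), per-condition
#'   binned rates and static fits, rescaling-model comparison, and (if
#'   enabled) the tracked gain trajectory.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sch <- switching_schedule(cfg$duration, cfg$half_period,
                            cfg$sigma2_high, cfg$sigma2_low)
  ktrue <- default_kernel()
  gain_fn <- if (is.null(cfg$alpha_by_condition)) NULL else
    function(schedule, n_frames, deriv)
      step_control_gain(schedule, cfg$alpha_by_condition,
                        n_frames = n_frames)
  data <- stage("simulate",
    simulate_study(cfg$n_experiments, cfg$n_larvae, cfg$duration, sch,
                   ktrue, cfg$rate, gain_fn, seed = cfg$seed))
  derivs <- lapply(data$experiments, `[[`, "deriv")
  message(sprintf("simulated %d experiments, %d turns",
                  cfg$n_experiments, n_turns(data)))
  keep <- analysis_mask(cfg$duration, data$frame_period, sch,
                        cfg$burn_in, cfg$cycle_discard)
  message(sprintf("analysis mask keeps %d of %d frames", sum(keep),
                  length(keep)))
  revc <- stage("revcorr", {
    tta <- turn_triggered_average(data, derivs, keep = keep)
    band <- bootstrap_tta(data, derivs, n_boot = cfg$n_boot,
                          seed = cfg$seed + 1L, keep = keep)
    knorm <- normalize_kernel(tta, derivs[[1]])
    filt <- lapply(derivs, function(d) filter_stimulus(knorm, d))
    rates <- lapply(c(high = "high", low = "low"), function(cond)
      binned_turn_rate(data, filt, cfg$n_bins,
                       keep & condition_keep(data, sch, cond)))
    list(tta = tta, band = band, kernel = knorm, filtered = filt,
         rates = rates)
  })
  fits <- stage("ratefit", {
    static <- fit_static_rate(data, revc$filtered, per_condition = TRUE,
                              keep = keep)
    cmp <- lapply(c(null = "null", input = "input", output = "output",
                    recentered_output = "recentered_output"),
                  function(kd) fit_rescaling_model(data, revc$filtered, kd,
                                                   keep))
    list(static = static, rescaling = cmp)
  })
  track <- NULL
  if (cfg$do_track)
    track <- stage("track",
      iterate_fit(data, revc$filtered, cfg$prior_tau, cfg$track_step,
                  keep = keep))
  out <- list(config = cfg, schedule = sch, data = data, revcorr = revc,
              fits = fits, track = track)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(data, file.path(out_dir, "events.csv"))
    write_kernel(revc$kernel, file.path(out_dir, "kernel.json"))
    utils::write.csv(do.call(rbind, lapply(names(revc$rates), function(cn)
      cbind(condition = cn, revc$rates[[cn]]))),
      file.path(out_dir, "binned_rates.csv"), row.names = FALSE)
    report <- lapply(fits$rescaling, function(f)
      list(model = f$kind, lam0_per_min = 60 * f$static$lam0,
           b = f$static$b, c = f$static$c, alpha_low = f$alpha_low,
           loglik = f$loglik, n_params = f$n_params,
           n_data_larva_seconds = f$n_data,
           bic = bic(f$loglik, f$n_data, f$n_params)))
    jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(track))
      utils::write.csv(data.frame(time_s = track$trajectory$times,
                                  alpha = track$trajectory$alpha,
                                  sigma_alpha = track$trajectory$sigma_alpha),
                       file.path(out_dir, "alpha_trajectory.csv"),
                       row.names = FALSE)
    cfg_echo <- cfg
    cfg_echo$rate <- unclass(cfg_echo$rate)
    jsonlite::write_json(list(seed = cfg$seed, config = cfg_echo),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
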