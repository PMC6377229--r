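#' Configuration for in-silico direction-selectivity experiments
#'
#' Bundles the stimulus grid, trial counts, seeds and mechanism toggles
#' used by [experiment_mechanism_dissection()] and
#' [experiment_velocity_sweep()].
#'
#' @param directions Stimulus directions (degrees; default 8 at 45 deg).
#' @param velocities Velocity grid (um/s) for the sweep. The default spans
#'   the inhibition's temporal footprint: at its low end the gap between
#'   inhibition and trailing excitation outlasts the inhibitory conductance
#'   and null-direction spikes leak through.
#' @param velocity_um_s Velocity (um/s) for single-velocity experiments.
#' @param trials Trials per condition (default 20).
#' @param seed Base seed; every trial derives its release and noise seeds
#'   deterministically from it.
#' @param noise Logical; membrane noise on (trial-to-trial variability).
#' @param preferred_axis_deg Configured preferred direction of the cell.
#' @param arbor_seed,arbor_radius_um,branch_order Arbor parameters.
#' @param target_spacing_um Synapse spacing along terminal branches.
#' @param receptors Receptor kinetics, see [receptor_defaults()].
#' @param biophysics A [biophysics_config()].
#' @param out_dir Optional directory; results are written there as CSV +
#'   JSON when given.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(directions = seq(0, 315, by = 45),
                              velocities = c(600, 1200, 2400),
                              velocity_um_s = 1000,
                              trials = 20, seed = 1, noise = TRUE,
                              preferred_axis_deg = 0,
                              arbor_seed = 1, arbor_radius_um = 150,
                              branch_order = 4, target_spacing_um = 5,
                              receptors = receptor_defaults(),
                              biophysics = biophysics_config(),
                              out_dir = NULL) {
  stopifnot(length(directions) >= 1, length(velocities) >= 1, trials >= 1)
  structure(list(directions = directions, velocities = velocities,
                 velocity_um_s = velocity_um_s, trials = trials,
                 seed = seed, noise = noise,
                 preferred_axis_deg = preferred_axis_deg,
                 arbor_seed = arbor_seed,
                 arbor_radius_um = arbor_radius_um,
                 branch_order = branch_order,
                 target_spacing_um = target_spacing_um,
                 receptors = receptors, biophysics = biophysics,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Tuning rules for a mechanism-dissection setting
#'
#' Maps the three mechanism settings onto per-transmitter tuning:
#' \itemize{
#'   \item `"both"`: direction-tuned GABA release probability and
#'     direction-tuned spatial offsets (control circuit);
#'   \item `"offsets_only"`: GABA release probability held at 0.5 in all
#'     directions (non-directional starburst output) with offsets intact —
#'     timing differences are the only DS mechanism;
#'   \item `"amplitude_only"`: release-probability tuning intact but all
#'     spatial offsets removed (excitation loses its lead and inhibition
#'     its direction-dependent advance), so E/I amplitude asymmetry is the
#'     only DS mechanism and no input precedes the glutamate receptive
#'     field.
#' }
#'
#' @param setting One of `"both"`, `"offsets_only"`, `"amplitude_only"`.
#' @return Named list of [directional_tuning()] objects.
#' @export
mechanism_tuning <- function(setting = c("both", "offsets_only",
                                         "amplitude_only")) {
  setting <- match.arg(setting)
  base <- transmitter_tuning("control")
  switch(setting,
    both = base,
    offsets_only = transmitter_tuning("nonds_starburst"),
    amplitude_only = {
      base$acetylcholine <- directional_tuning(p_pr = 0.5, n_pr = 0.5,
                                               p_off = 0, n_off = 0)
      base$gaba <- directional_tuning(p_pr = 0.012, n_pr = 0.5,
                                      p_off = 0, n_off = 0)
      base
    })
}

#' GABA gain fixing the E/I conductance ratio
#'
#' Returns the multiplier on GABA event conductances that scales the
#' summed inhibitory peak conductance (per-site quantal peak times the
#' release probability, summed over sites) to `ratio` times the summed
#' excitatory (AMPA + nicotinic) peak conductance, evaluated for
#' null-direction motion where both drives are fully recruited.
#'
#' @param sites `synapse_sites`.
#' @param tuning Per-transmitter tuning list.
#' @param receptors Receptor specs.
#' @param velocity_um_s Stimulus velocity (um/s, unused by the quantal-sum
#'   rule but kept so velocity-specific rules can slot in).
#' @param preferred_axis_deg Preferred axis (degrees).
#' @param ratio Target inhibition/excitation peak-conductance ratio.
#' @return Scalar gain.
#' @export
fixed_ratio_gaba_gain <- function(sites, tuning, receptors,
                                  velocity_um_s = 1000,
                                  preferred_axis_deg = 0, ratio = 2) {
  a_null <- 180
  n <- nrow(sites)
  e_sum <- n * (release_probability(a_null, tuning$glutamate) *
                  receptors$glutamate$gpeak_ns +
                release_probability(a_null, tuning$acetylcholine) *
                  receptors$acetylcholine$gpeak_ns)
  i_sum <- n * release_probability(a_null, tuning$gaba) *
    receptors$gaba$gpeak_ns
  if (i_sum <= 0) stop("no inhibitory drive to scale")
  ratio * e_sum / i_sum
}

# One battery: all directions x trials at one velocity for one tuning rule.
run_direction_battery <- function(cell, sites, tuning, directions, trials,
                                  velocity_um_s, preferred_axis_deg,
                                  base_seed, noise = TRUE, gaba_gain = 1) {
  recs <- list(); counts <- list(); entries <- numeric(length(directions))
  k <- 0L
  for (di in seq_along(directions)) {
    d <- directions[di]
    stim <- bar_stimulus(d, velocity_um_s, preferred_axis_deg)
    for (tr in seq_len(trials)) {
      k <- k + 1L
      sd_rel <- base_seed * 1013L + k
      sch <- activation_schedule(stim, sites, tuning, seed = sd_rel,
                                 trial_id = tr)
      if (tr == 1L) entries[di] <- attr(sch, "glut_rf_entry_ms")
      cc <- run_current_clamp(cell, sch, noise_seed = sd_rel + 500000L,
                              noise = noise, gaba_gain = gaba_gain)
      recs[[k]] <- cc$spikes
      counts[[k]] <- data.frame(direction_deg = d, trial = tr,
                                n_spikes = length(cc$spikes$values))
    }
  }
  list(spikes = recs, counts = do.call(rbind, counts),
       glut_rf_entry_ms = entries)
}

battery_tuning <- function(bat, directions) {
  agg <- stats::aggregate(n_spikes ~ direction_deg + trial, bat$counts, sum)
  s <- direction_series(agg$direction_deg, agg$n_spikes, trial = agg$trial)
  direction_selectivity_index(s)
}

#' Mechanism-dissection experiment
#'
#' Runs the moving-bar battery (all directions, `trials` repeats) for the
#' three mechanism settings — timing + amplitude asymmetries, timing
#' alone, amplitude alone — and reports per-direction spike counts,
#' whole-response DSI/preferred angle, and early/peak phase tuning for
#' each. Early responses are the spikes preceding entry of the stimulus
#' into the glutamate receptive field; peak responses a 50 ms window
#' centred on the preferred-direction rate peak.
#'
#' @param config An [experiment_config()].
#' @param settings Subset of the three settings to run.
#' @return An `experiment_result` list, one element per setting, each with
#'   `counts`, `tuning`, `phase`, `mean_counts`; attribute `config`.
#' @export
experiment_mechanism_dissection <- function(config = experiment_config(),
                                            settings = c("both",
                                                         "offsets_only",
                                                         "amplitude_only")) {
  stopifnot(inherits(config, "experiment_config"))
  geom <- experiment_cell(config)
  out <- list()
  for (si in seq_along(settings)) {
    setting <- settings[si]
    tun <- mechanism_tuning(setting)
    bat <- run_direction_battery(geom$cell, geom$sites, tun,
                                 config$directions, config$trials,
                                 config$velocity_um_s,
                                 config$preferred_axis_deg,
                                 base_seed = config$seed + 7919L * si,
                                 noise = config$noise)
    if (sum(bat$counts$n_spikes) == 0)
      warning(sprintf("calibration failure: no spikes in any direction (%s)",
                      setting))
    phase <- if (sum(bat$counts$n_spikes) > 0)
      phase_tuning(bat$spikes, glut_rf_entry_ms = bat$glut_rf_entry_ms)
    else NULL
    mean_counts <- stats::aggregate(n_spikes ~ direction_deg, bat$counts,
                                    mean)
    out[[setting]] <- list(setting = setting, counts = bat$counts,
                           mean_counts = mean_counts,
                           tuning = battery_tuning(bat, config$directions),
                           phase = phase,
                           glut_rf_entry_ms = bat$glut_rf_entry_ms)
  }
  res <- structure(out, config = config, class = "experiment_result")
  if (!is.null(config$out_dir)) write_dissection(res, config$out_dir)
  res
}

#' Velocity-sweep experiment with fixed E/I ratio
#'
#' Runs the offsets-only configuration (non-directional GABA release, all
#' timing offsets intact) across the velocity grid. The E/I amplitude
#' ratio is fixed by construction — release probabilities and quantal
#' conductances are direction- and velocity-independent in this mode — so
#' timing offsets are the only direction-dependent quantity. Reports
#' per-velocity DSI, preferred angle, and mean preferred- and
#' null-direction spike counts, exposing the slow-velocity leak-through of
#' null-direction spikes once the inhibition-to-glutamate gap outlasts the
#' inhibitory conductance.
#'
#' @param config An [experiment_config()].
#' @param ei_ratio Optional inhibition/excitation quantal-sum conductance
#'   ratio; when given, GABA events are rescaled via
#'   [fixed_ratio_gaba_gain()], otherwise the calibrated conductances are
#'   used unchanged (their ratio is already fixed across directions).
#' @return A `velocity_sweep` list: `table` (one row per velocity),
#'   `counts` (direction x trial x velocity), attribute `config`.
#' @export
experiment_velocity_sweep <- function(config = experiment_config(),
                                      ei_ratio = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  geom <- experiment_cell(config)
  tun <- mechanism_tuning("offsets_only")
  rows <- list(); all_counts <- list()
  for (vi in seq_along(config$velocities)) {
    v <- config$velocities[vi]
    gain <- if (is.null(ei_ratio)) 1 else
      fixed_ratio_gaba_gain(geom$sites, tun, config$receptors,
                            velocity_um_s = v,
                            preferred_axis_deg = config$preferred_axis_deg,
                            ratio = ei_ratio)
    bat <- run_direction_battery(geom$cell, geom$sites, tun,
                                 config$directions, config$trials, v,
                                 config$preferred_axis_deg,
                                 base_seed = config$seed + 104729L * vi,
                                 noise = config$noise, gaba_gain = gain)
    tunres <- battery_tuning(bat, config$directions)
    mean_by_dir <- stats::aggregate(n_spikes ~ direction_deg, bat$counts,
                                    mean)
    pref_d <- config$preferred_axis_deg %% 360
    null_d <- (config$preferred_axis_deg + 180) %% 360
    cnt <- bat$counts; cnt$velocity_um_s <- v
    all_counts[[vi]] <- cnt
    rows[[vi]] <- data.frame(
      velocity_um_s = v, gaba_gain = gain, dsi = tunres$dsi,
      preferred_angle_deg = tunres$preferred_angle_deg,
      pref_spikes = mean_by_dir$n_spikes[mean_by_dir$direction_deg == pref_d],
      null_spikes = mean_by_dir$n_spikes[mean_by_dir$direction_deg == null_d])
  }
  res <- structure(list(table = do.call(rbind, rows),
                        counts = do.call(rbind, all_counts)),
                   config = config, class = "velocity_sweep")
  if (!is.null(config$out_dir)) write_sweep(res, config$out_dir)
  res
}

experiment_cell <- function(config) {
  m <- generate_arbor(arbor_radius_um = config$arbor_radius_um,
                      branch_order = config$branch_order,
                      seed = config$arbor_seed)
  s <- place_synapses(m, target_spacing_um = config$target_spacing_um,
                      receptors = config$receptors)
  list(morphology = m, sites = s,
       cell = build_cell(m, s, config$biophysics))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  for (r in x) {
    ph <- if (!is.null(r$phase))
      sprintf(" | early DSI %.3f, peak DSI %.3f",
              r$phase$early$dsi, r$phase$peak$dsi) else ""
    cat(sprintf("  %-14s DSI %.3f at %.0f deg%s\n", r$setting,
                r$tuning$dsi, r$tuning$preferred_angle_deg, ph))
  }
  invisible(x)
}

#' @export
print.velocity_sweep <- function(x, ...) {
  cat("<velocity_sweep>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

write_dissection <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in res) {
    utils::write.csv(r$counts,
                     file.path(dir, paste0("counts_", r$setting, ".csv")),
                     row.names = FALSE)
  }
  summ <- lapply(res, function(r) list(
    setting = r$setting, dsi = r$tuning$dsi,
    preferred_angle_deg = r$tuning$preferred_angle_deg,
    early_dsi = if (!is.null(r$phase)) r$phase$early$dsi else NA,
    peak_dsi = if (!is.null(r$phase)) r$phase$peak$dsi else NA))
  jsonlite::write_json(summ, file.path(dir, "dissection_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_sweep <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$table, file.path(dir, "velocity_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(res$counts, file.path(dir, "velocity_sweep_counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Measure the excitation/inhibition temporal offset in voltage clamp
#'
#' Reproduces the clamp protocol used to quantify E/I timing: the same
#' moving-bar schedule geometry is replayed over `n_trials` independent
#' release draws while the soma is held first at the inhibitory reversal
#' (isolating the EPSC) and then at 0 mV, the excitatory reversal
#' (isolating the IPSC). Trial-averaged traces are trimmed of the clamp
#' settling transient and passed to the 20-80% rise-fit onset estimator;
#' the offset is inhibition onset minus excitation onset (positive when
#' excitation leads).
#'
#' @param cell A `ds_cell`.
#' @param sites The `synapse_sites` used to build the cell.
#' @param tuning Per-transmitter tuning (default control circuit).
#' @param direction_deg Stimulus direction (degrees; default the preferred
#'   direction, 0).
#' @param velocity_um_s Bar velocity (um/s).
#' @param n_trials Release-seed trials averaged per holding potential.
#' @param seed Base seed for the release draws.
#' @param pre_ms Input-free baseline before the first possible event (ms);
#'   realised by extending the stimulus lead distance.
#' @param settle_ms Initial clamp-settling span discarded from the traces.
#' @param hold_e_mv,hold_i_mv Holding potentials for the EPSC and IPSC.
#' @param ... Passed to [ei_temporal_offset()] / [onset_latency()].
#' @return An `offset_estimate` (see [ei_temporal_offset()]) with the
#'   averaged `epsc`/`ipsc` recordings attached.
#' @export
measure_ei_offset <- function(cell, sites, tuning = transmitter_tuning("control"),
                              direction_deg = 0, velocity_um_s = 1000,
                              n_trials = 10, seed = 1, pre_ms = 250,
                              settle_ms = 50, hold_e_mv = -60,
                              hold_i_mv = 0, ...) {
  lead <- (pre_ms + settle_ms) * velocity_um_s / 1000
  stim <- bar_stimulus(direction_deg, velocity_um_s, lead_um = lead)
  avg_trace <- function(hold) {
    acc <- NULL; tt <- NULL
    for (k in seq_len(n_trials)) {
      sch <- activation_schedule(stim, sites, tuning, seed = seed + 37L * k,
                                 trial_id = k)
      dur <- max(sch$time_ms) + 200
      r <- run_voltage_clamp(cell, sch, hold_mv = hold, duration_ms = dur,
                             noise = FALSE)
      keep <- r$time_ms >= settle_ms
      vals <- r$values[keep]
      acc <- if (is.null(acc)) vals else acc + vals
      tt <- r$time_ms[keep]
    }
    recording("voltage_clamp_current", tt, acc / n_trials,
              metadata = list(hold_mv = hold, direction_deg = direction_deg,
                              velocity_um_s = velocity_um_s,
                              n_trials = n_trials, seed = seed))
  }
  epsc <- avg_trace(hold_e_mv)
  ipsc <- avg_trace(hold_i_mv)
  est <- ei_temporal_offset(epsc, ipsc, ...)
  est$epsc <- epsc
  est$ipsc <- ipsc
  est
}
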