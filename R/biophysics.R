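#' Biophysical configuration for the compartmental model
#'
#' Passive and active membrane parameters. Densities are given per region
#' (soma / primary dendrite / terminal dendrite) in mS/cm^2; the defaults
#' are the model cell's printed values: sodium 150/150/30, potassium
#' rectifier 70/70/35, and a low-density slow delayed rectifier 3/0.8/0.4.
#' Passive parameters default to 1 uF/cm^2 capacitance, 100 Ohm-cm axial
#' resistivity, and a non-voltage-gated leak reversing at -60 mV.
#'
#' Channel noise is an additive Ornstein-Uhlenbeck current per compartment
#' (total SD `noise_sd_pa`, apportioned by membrane area; correlation time
#' `noise_tau_ms`), giving trial-to-trial spike-count variability; set
#' `noise_sd_pa = 0` for deterministic runs.
#'
#' @param cm_uf_cm2 Specific membrane capacitance (uF/cm^2).
#' @param ra_ohm_cm Axial resistivity (Ohm-cm).
#' @param e_leak_mv Leak reversal potential (mV).
#' @param leak_ms_cm2 Leak conductance density (mS/cm^2); 0.1 gives a
#'   10 ms membrane time constant at 1 uF/cm^2.
#' @param na_ms_cm2,k_ms_cm2,km_ms_cm2 Named density vectors
#'   `c(soma=, primary_dendrite=, terminal_dendrite=)` for the sodium,
#'   potassium-rectifier and slow delayed-rectifier conductances.
#' @param e_na_mv,e_k_mv Channel reversal potentials (mV).
#' @param na_shift_mv,k_shift_mv Depolarising shifts (mV) applied to the
#'   canonical sodium and potassium-rectifier rate functions so that the
#'   cell rests near the leak reversal with negligible window current.
#' @param km_half_mv Half-activation voltage of the slow delayed
#'   rectifier.
#' @param dt_ms Integration step (ms, must be in (0, 0.05]).
#' @param noise_sd_pa Total OU noise current SD (pA); 0 disables noise.
#' @param noise_tau_ms OU correlation time (ms).
#' @return A `biophysics_config` list.
#' @export
biophysics_config <- function(cm_uf_cm2 = 1, ra_ohm_cm = 100,
                              e_leak_mv = -60, leak_ms_cm2 = 0.1,
                              na_ms_cm2 = c(soma = 150, primary_dendrite = 150,
                                            terminal_dendrite = 30),
                              k_ms_cm2 = c(soma = 70, primary_dendrite = 70,
                                           terminal_dendrite = 35),
                              km_ms_cm2 = c(soma = 3, primary_dendrite = 0.8,
                                            terminal_dendrite = 0.4),
                              e_na_mv = 50, e_k_mv = -77,
                              na_shift_mv = 10, k_shift_mv = 25,
                              km_half_mv = -10,
                              dt_ms = 0.025,
                              noise_sd_pa = 30, noise_tau_ms = 2) {
  if (dt_ms <= 0 || dt_ms > 0.05) stop("dt_ms must be in (0, 0.05]")
  for (dn in list(na_ms_cm2, k_ms_cm2, km_ms_cm2))
    if (any(dn < 0)) stop("channel densities must be >= 0")
  if (noise_sd_pa < 0) stop("noise_sd_pa must be >= 0")
  structure(list(cm_uf_cm2 = cm_uf_cm2, ra_ohm_cm = ra_ohm_cm,
                 e_leak_mv = e_leak_mv, leak_ms_cm2 = leak_ms_cm2,
                 na_ms_cm2 = na_ms_cm2, k_ms_cm2 = k_ms_cm2,
                 km_ms_cm2 = km_ms_cm2, e_na_mv = e_na_mv, e_k_mv = e_k_mv,
                 na_shift_mv = na_shift_mv, k_shift_mv = k_shift_mv,
                 km_half_mv = km_half_mv,
                 dt_ms = dt_ms, noise_sd_pa = noise_sd_pa,
                 noise_tau_ms = noise_tau_ms),
            class = "biophysics_config")
}

#' Assemble a simulatable cell
#'
#' Converts a morphology, its synapse sites and a biophysical configuration
#' into the flat electrical representation the cable integrator consumes:
#' per-compartment capacitance, leak and channel conductances (region
#' densities times membrane area), axial conductances to the parent
#' compartment, and one synaptic conductance channel per (compartment,
#' transmitter) with the site-to-channel map used when scheduling events.
#'
#' @param morphology A `morphology` object.
#' @param synapse_sites A `synapse_sites` data frame; every
#'   `compartment_id` must exist in the morphology.
#' @param config A [biophysics_config()] object.
#' @return A `ds_cell` object.
#' @export
build_cell <- function(morphology, synapse_sites,
                       config = biophysics_config()) {
  validate_morphology(morphology)
  stopifnot(inherits(config, "biophysics_config"))
  if (!all(synapse_sites$compartment_id %in% morphology$id))
    stop("synapse site references a missing compartment")
  regions <- c("soma", "primary_dendrite", "terminal_dendrite")
  if (!all(morphology$region %in% regions))
    stop("unknown region label: ",
         paste(setdiff(morphology$region, regions), collapse = ", "))

  # Hines ordering: parents before children
  ord <- order(morphology$id)
  m <- morphology[ord, ]
  if (any(!is.na(m$parent) & m$parent >= m$id))
    stop("compartment ids must be topologically ordered (parent < child)")
  parent0 <- match(m$parent, m$id) - 1L   # 0-based, NA -> root
  parent0[is.na(parent0)] <- -1L

  is_soma <- m$region == "soma"
  area_um2 <- ifelse(is_soma, pi * m$diameter_um^2,
                     pi * m$diameter_um * m$length_um)
  # uF/cm^2 * um^2 -> nF ; mS/cm^2 * um^2 -> uS : both scale by 1e-5
  cap_nf <- config$cm_uf_cm2 * area_um2 * 1e-5
  dens <- function(v) unname(v[m$region]) * area_um2 * 1e-5
  g_leak <- config$leak_ms_cm2 * area_um2 * 1e-5
  g_na <- dens(config$na_ms_cm2)
  g_k <- dens(config$k_ms_cm2)
  g_km <- dens(config$km_ms_cm2)

  # axial conductance between compartment centre and parent centre
  half_r <- function(i) {                 # MOhm
    r <- m$diameter_um[i] / 2
    config$ra_ohm_cm * (m$length_um[i] / 2) / (pi * r^2) * 1e-2
  }
  g_ax <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- parent0[i] + 1L
    if (p > 0) g_ax[i] <- 1 / (half_r(i) + half_r(p))
  }

  receptors <- attr(synapse_sites, "receptors")
  if (is.null(receptors)) receptors <- receptor_defaults()
  comp0 <- match(synapse_sites$compartment_id, m$id) - 1L
  chan <- unique(data.frame(comp0 = rep(comp0, times = length(receptors)),
                            transmitter = rep(names(receptors),
                                              each = nrow(synapse_sites))))
  chan$tau_r <- vapply(receptors[chan$transmitter], `[[`, 0, "rise_ms")
  chan$tau_d <- vapply(receptors[chan$transmitter], `[[`, 0, "decay_ms")
  chan$e_rev <- vapply(receptors[chan$transmitter], `[[`, 0, "e_rev_mv")
  chan$chan_id <- seq_len(nrow(chan)) - 1L
  rownames(chan) <- NULL

  structure(list(parent0 = parent0, cap_nf = cap_nf, g_ax_us = g_ax,
                 g_leak_us = g_leak, g_na_us = g_na, g_k_us = g_k,
                 g_km_us = g_km, area_um2 = area_um2,
                 channels = chan, site_comp0 = comp0,
                 sites = synapse_sites, receptors = receptors,
                 config = config, n_comp = nrow(m)),
            class = "ds_cell")
}

#' @export
print.ds_cell <- function(x, ...) {
  cat(sprintf("<ds_cell> %d compartments, %d synapse sites, %d synaptic channels\n",
              x$n_comp, nrow(x$sites), nrow(x$channels)))
  invisible(x)
}

# peak-normalisation factor of the bi-exponential e^{-t/td} - e^{-t/tr}
biexp_norm <- function(tau_r, tau_d) {
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

# translate released schedule rows into integrator event arrays
schedule_events <- function(cell, schedule, gaba_gain = 1) {
  rel <- schedule[schedule$released & schedule$time_ms >= 0, , drop = FALSE]
  if (nrow(rel) == 0L)
    return(list(chan = integer(), time = numeric(), weight = numeric()))
  comp0 <- cell$site_comp0[match(rel$site, cell$sites$site_id)]
  key <- paste(comp0, rel$transmitter)
  ckey <- paste(cell$channels$comp0, cell$channels$transmitter)
  cidx <- cell$channels$chan_id[match(key, ckey)]
  if (anyNA(cidx)) stop("schedule references a transmitter without a channel")
  spec <- cell$receptors[rel$transmitter]
  w <- vapply(spec, function(s)
    s$gpeak_ns * 1e-3 * biexp_norm(s$rise_ms, s$decay_ms), numeric(1))
  w <- unname(w) * ifelse(rel$transmitter == "gaba", gaba_gain, 1)
  o <- order(rel$time_ms)
  list(chan = as.integer(cidx[o]), time = rel$time_ms[o], weight = w[o])
}

run_sim <- function(cell, events, duration_ms, mode, hold_mv = 0,
                    noise_seed = 0, noise = TRUE, i_inj = NULL,
                    dt_ms = NULL, v_init = NULL, block_active = FALSE,
                    record_all = FALSE) {
  cfg <- cell$config
  dt <- if (is.null(dt_ms)) cfg$dt_ms else dt_ms
  nsteps <- as.integer(ceiling(duration_ms / dt))
  if (is.null(v_init)) v_init <- cfg$e_leak_mv
  zero <- numeric(cell$n_comp)
  sd_na <- if (noise && cfg$noise_sd_pa > 0)
    cfg$noise_sd_pa * 1e-3 * sqrt(cell$area_um2 / sum(cell$area_um2))
  else numeric(0)
  inj <- if (is.null(i_inj)) numeric(0) else {
    if (is.list(i_inj)) {
      v <- numeric(nsteps)
      on <- pmax(1L, as.integer(i_inj$onset_ms / dt))
      off <- min(nsteps, as.integer((i_inj$onset_ms + i_inj$duration_ms) / dt))
      v[on:off] <- i_inj$amplitude_na
      v
    } else rep_len(i_inj, nsteps)
  }
  res <- cable_sim_cpp(
    parent = cell$parent0, cap_nf = cell$cap_nf, g_ax_us = cell$g_ax_us,
    g_leak_us = cell$g_leak_us, e_leak = cfg$e_leak_mv,
    g_na_us = if (block_active) zero else cell$g_na_us,
    g_k_us = if (block_active) zero else cell$g_k_us,
    g_km_us = if (block_active) zero else cell$g_km_us,
    e_na = cfg$e_na_mv, e_k = cfg$e_k_mv,
    na_shift_mv = cfg$na_shift_mv, k_shift_mv = cfg$k_shift_mv,
    km_half_mv = cfg$km_half_mv,
    chan_comp = cell$channels$comp0, chan_tau_r = cell$channels$tau_r,
    chan_tau_d = cell$channels$tau_d, chan_erev = cell$channels$e_rev,
    ev_chan = events$chan, ev_time = events$time,
    ev_weight_us = events$weight,
    dt = dt, nsteps = nsteps, v_init = v_init,
    mode = mode, hold_mv = hold_mv,
    i_inj_soma_na = inj, noise_sigma_na = sd_na,
    noise_tau_ms = cfg$noise_tau_ms, noise_seed = as.integer(noise_seed),
    record_all = record_all)
  res$time_ms <- seq(0, by = dt, length.out = nsteps + 1L)
  res$dt <- dt
  res
}

#' Construct a recording object
#'
#' A `recording` wraps a uniformly sampled trace (clamp current in pA or
#' membrane voltage in mV) or a strictly increasing spike-time list, plus
#' acquisition metadata.
#'
#' @param mode One of `"voltage_clamp_current"`, `"membrane_voltage"`,
#'   `"spike_times"`.
#' @param time_ms Sample times (trace modes) or `NULL`.
#' @param values Trace values, or spike times (ms) for `"spike_times"`.
#' @param metadata Named list (direction, velocity, trial, seed, hold, ...).
#' @return A `recording` object.
#' @export
recording <- function(mode, time_ms = NULL, values,
                      metadata = list()) {
  mode <- match.arg(mode, c("voltage_clamp_current", "membrane_voltage",
                            "spike_times"))
  if (mode == "spike_times") {
    if (is.unsorted(values, strictly = TRUE) && length(values) > 1)
      stop("spike times must be strictly increasing")
  } else {
    stopifnot(length(time_ms) == length(values))
    if (length(time_ms) > 1) {
      dts <- diff(time_ms)
      if (max(abs(dts - dts[1])) > 1e-9) stop("non-uniform sampling")
    }
    if (mode == "voltage_clamp_current" && is.null(metadata$hold_mv))
      stop("clamp recordings must carry hold_mv metadata")
  }
  structure(list(mode = mode, time_ms = time_ms, values = values,
                 metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  if (x$mode == "spike_times")
    cat(sprintf("<recording spike_times> %d spikes\n", length(x$values)))
  else
    cat(sprintf("<recording %s> %d samples, %.1f ms\n", x$mode,
                length(x$values), utils::tail(x$time_ms, 1)))
  invisible(x)
}

#' Detect spikes from a somatic voltage trace
#'
#' Upward threshold crossings with a refractory lockout.
#'
#' @param time_ms,v_mv Uniformly sampled time and voltage.
#' @param threshold_mv Crossing threshold (default -20 mV).
#' @param refractory_ms Lockout after each detected spike (default 1 ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(time_ms, v_mv, threshold_mv = -20,
                          refractory_ms = 1) {
  up <- which(v_mv[-1] >= threshold_mv & v_mv[-length(v_mv)] < threshold_mv) + 1L
  if (!length(up)) return(numeric(0))
  t <- time_ms[up]
  keep <- rep(TRUE, length(t))
  last <- t[1]
  for (i in seq_along(t)[-1]) {
    if (t[i] - last < refractory_ms) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

#' Run a current-clamp trial
#'
#' Integrates the full active model with the given activation schedule and
#' returns both the somatic membrane-voltage recording and the spike-time
#' recording (upward crossings of -20 mV with a 1 ms lockout).
#'
#' @param cell A `ds_cell` from [build_cell()].
#' @param schedule An `activation_schedule` (released events are applied).
#' @param duration_ms Simulated duration; defaults to the last scheduled
#'   event plus 150 ms.
#' @param noise_seed Seed for the OU membrane-noise stream.
#' @param noise Logical; `FALSE` forces a deterministic run.
#' @param i_inj Optional somatic current injection: either a numeric vector
#'   (nA per step) or `list(onset_ms=, duration_ms=, amplitude_na=)`.
#' @param gaba_gain Scalar multiplier on GABA event conductances (used by
#'   fixed-ratio experiments).
#' @param dt_ms Optional integration-step override.
#' @return List with elements `spikes` and `voltage`, both `recording`s.
#' @export
run_current_clamp <- function(cell, schedule, duration_ms = NULL,
                              noise_seed = 1, noise = TRUE, i_inj = NULL,
                              gaba_gain = 1, dt_ms = NULL) {
  stopifnot(inherits(cell, "ds_cell"))
  ev <- schedule_events(cell, schedule, gaba_gain = gaba_gain)
  if (is.null(duration_ms))
    duration_ms <- (if (length(ev$time)) max(ev$time) else
      max(schedule$time_ms, 0)) + 150
  if (length(ev$time) && max(ev$time) > duration_ms)
    stop("schedule extends beyond the simulated duration")
  res <- run_sim(cell, ev, duration_ms, mode = 0, noise_seed = noise_seed,
                 noise = noise, i_inj = i_inj, dt_ms = dt_ms)
  meta <- list(direction_deg = attr(schedule, "direction_deg"),
               velocity_um_s = attr(schedule, "velocity_um_s"),
               trial = schedule$trial[1], seed = attr(schedule, "seed"),
               noise_seed = noise_seed, noise = noise,
               glut_rf_entry_ms = attr(schedule, "glut_rf_entry_ms"))
  st <- detect_spikes(res$time_ms, res$trace)
  list(spikes = recording("spike_times", values = st, metadata = meta),
       voltage = recording("membrane_voltage", res$time_ms, res$trace,
                           metadata = meta))
}

#' Run a somatic voltage-clamp trial
#'
#' Holds the soma at `hold_mv` and records the electrode current. Sodium
#' and potassium conductances are blocked in this mode, mirroring the
#' experimental pharmacology: holding at the inhibitory reversal isolates
#' excitation (inward, negative) and holding at 0 mV (the excitatory
#' reversal) isolates inhibition (outward, positive).
#'
#' @inheritParams run_current_clamp
#' @param hold_mv Holding potential (mV).
#' @return A `recording` of mode `"voltage_clamp_current"` (pA).
#' @export
run_voltage_clamp <- function(cell, schedule, hold_mv, duration_ms = NULL,
                              noise_seed = 1, noise = FALSE,
                              gaba_gain = 1, dt_ms = NULL) {
  stopifnot(inherits(cell, "ds_cell"), is.finite(hold_mv))
  ev <- schedule_events(cell, schedule, gaba_gain = gaba_gain)
  if (is.null(duration_ms))
    duration_ms <- (if (length(ev$time)) max(ev$time) else
      max(schedule$time_ms, 0)) + 150
  res <- run_sim(cell, ev, duration_ms, mode = 1, hold_mv = hold_mv,
                 noise_seed = noise_seed, noise = noise, dt_ms = dt_ms,
                 block_active = TRUE, v_init = hold_mv)
  recording("voltage_clamp_current", res$time_ms, res$trace,
            metadata = list(hold_mv = hold_mv,
                            direction_deg = attr(schedule, "direction_deg"),
                            velocity_um_s = attr(schedule, "velocity_um_s"),
                            trial = schedule$trial[1],
                            seed = attr(schedule, "seed"),
                            glut_rf_entry_ms = attr(schedule, "glut_rf_entry_ms")))
}
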