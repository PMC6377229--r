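#' Ground truth for synthetic recordings
#'
#' Defines the generative parameters for surrogate EPSC/IPSC pairs and
#' spike trains with known direction tuning, emulating the structure of
#' moving-bar measurements: excitation (cholinergic-like) advanced by an
#' isotropic spatial offset, inhibition arriving with a direction-tuned
#' spatial offset (sigmoidal, ~0 um preferred to ~50 um null) and,
#' optionally, a direction-tuned amplitude following the same sigmoid
#' vocabulary as the release-probability rule.
#'
#' @param preferred_angle_deg The configured preferred direction (degrees).
#' @param velocity_um_s Stimulus velocity (um/s).
#' @param stim_arrival_ms Time the stimulus reaches the (unshifted)
#'   receptive-field reference point; all onsets are offsets/velocity
#'   ahead of this.
#' @param excitation_offset_um Isotropic spatial advance of excitation.
#' @param inhibition_offset Either a [directional_tuning()] whose offset
#'   sigmoid gives the inhibitory spatial advance per angular distance, or
#'   a function(angle_dist_deg) -> um, or a single number.
#' @param epsc_peak_pa Excitatory peak amplitude (pA, reported as inward
#'   negative).
#' @param ipsc_peak_pa Inhibitory peak amplitude in the null direction
#'   (pA, outward positive).
#' @param amplitude_tuning Logical; `TRUE` scales the inhibitory amplitude
#'   with the release-probability sigmoid (small at preferred, maximal at
#'   null), `FALSE` holds it constant at `ipsc_peak_pa`.
#' @param temporal_offsets Logical; `FALSE` removes E/I timing differences
#'   (inhibition adopts the excitatory offset in every direction).
#' @param e_rise_ms,e_decay_ms,i_rise_ms,i_decay_ms Bi-exponential current
#'   kinetics (ms).
#' @param noise_sd_pa Additive Gaussian noise SD (pA, >= 0).
#' @param glut_amp_pa,glut_rise_ms,glut_decay_ms Untuned glutamate-like
#'   drive entering at `stim_arrival_ms` with no offset; it sustains
#'   firing in the spike generator even when starburst timing and
#'   amplitude asymmetries are switched off.
#' @param rate_gain_hz_per_pa Gain converting the rectified net drive
#'   (E - I + glut) to firing rate for spike-train synthesis.
#' @param seed Base seed recorded in the truth.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(preferred_angle_deg = 0, velocity_um_s = 1000,
                            stim_arrival_ms = 300,
                            excitation_offset_um = 50,
                            inhibition_offset = directional_tuning(
                              p_pr = 0.012, n_pr = 0.5, p_off = 0, n_off = 50),
                            epsc_peak_pa = 100, ipsc_peak_pa = 200,
                            amplitude_tuning = TRUE,
                            temporal_offsets = TRUE,
                            e_rise_ms = 1, e_decay_ms = 15,
                            i_rise_ms = 2, i_decay_ms = 20,
                            noise_sd_pa = 0,
                            glut_amp_pa = 60, glut_rise_ms = 2,
                            glut_decay_ms = 40,
                            rate_gain_hz_per_pa = 2,
                            seed = 1) {
  if (noise_sd_pa < 0) stop("noise_sd_pa must be >= 0")
  if (epsc_peak_pa < 0 || ipsc_peak_pa < 0) stop("amplitudes must be >= 0")
  inh_off_fun <-
    if (inherits(inhibition_offset, "directional_tuning")) {
      tun <- inhibition_offset
      function(a) spatial_offset(a, tun)
    } else if (is.function(inhibition_offset)) {
      inhibition_offset
    } else {
      off <- as.numeric(inhibition_offset)
      function(a) rep_len(off, length(a))
    }
  amp_tun <- if (inherits(inhibition_offset, "directional_tuning"))
    inhibition_offset else directional_tuning(p_pr = 0.012, n_pr = 0.5)
  structure(list(preferred_angle_deg = preferred_angle_deg,
                 velocity_um_s = velocity_um_s,
                 stim_arrival_ms = stim_arrival_ms,
                 excitation_offset_um = excitation_offset_um,
                 inh_off_fun = inh_off_fun, amp_tun = amp_tun,
                 epsc_peak_pa = epsc_peak_pa, ipsc_peak_pa = ipsc_peak_pa,
                 amplitude_tuning = amplitude_tuning,
                 temporal_offsets = temporal_offsets,
                 e_rise_ms = e_rise_ms, e_decay_ms = e_decay_ms,
                 i_rise_ms = i_rise_ms, i_decay_ms = i_decay_ms,
                 noise_sd_pa = noise_sd_pa,
                 glut_amp_pa = glut_amp_pa, glut_rise_ms = glut_rise_ms,
                 glut_decay_ms = glut_decay_ms,
                 rate_gain_hz_per_pa = rate_gain_hz_per_pa,
                 seed = seed),
            class = "synthetic_truth")
}

# peak-normalised bi-exponential waveform, zero before onset
biexp_wave <- function(t, onset, tau_r, tau_d) {
  x <- t - onset
  w <- ifelse(x > 0, exp(-x / tau_d) - exp(-x / tau_r), 0)
  w * biexp_norm(tau_r, tau_d)
}

truth_params <- function(truth, direction_deg) {
  a <- angle_distance(direction_deg, truth$preferred_angle_deg)
  e_off <- truth$excitation_offset_um
  i_off <- if (truth$temporal_offsets) truth$inh_off_fun(a) else e_off
  ms_per_um <- 1000 / truth$velocity_um_s
  amp_i <- if (truth$amplitude_tuning)
    truth$ipsc_peak_pa *
      release_probability(a, truth$amp_tun) / truth$amp_tun$n_pr
  else truth$ipsc_peak_pa
  list(angle_dist = a,
       e_onset_ms = truth$stim_arrival_ms - e_off * ms_per_um,
       i_onset_ms = truth$stim_arrival_ms - i_off * ms_per_um,
       e_amp_pa = truth$epsc_peak_pa, i_amp_pa = amp_i,
       e_off_um = e_off, i_off_um = i_off)
}

#' Synthesise a matched EPSC/IPSC pair
#'
#' Generates bi-exponential excitatory (inward negative) and inhibitory
#' (outward positive) current traces at the ground-truth onsets and
#' amplitudes for one stimulus direction, plus optional additive Gaussian
#' noise. The recording metadata carries the ground truth for test
#' harnesses.
#'
#' @param truth A [synthetic_truth()] object.
#' @param direction_deg Stimulus direction (degrees).
#' @param seed Seed for the noise draws.
#' @param dt_ms Sampling step (ms).
#' @param duration_ms Trace length (ms).
#' @return List with `epsc` and `ipsc` `recording`s.
#' @export
synth_current_pair <- function(truth, direction_deg, seed = truth$seed,
                               dt_ms = 0.1, duration_ms = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth_params(truth, direction_deg)
  if (is.null(duration_ms))
    duration_ms <- truth$stim_arrival_ms + 8 * truth$e_decay_ms + 100
  tt <- seq(0, duration_ms, by = dt_ms)
  e <- -p$e_amp_pa * biexp_wave(tt, p$e_onset_ms, truth$e_rise_ms,
                                truth$e_decay_ms)
  i <- p$i_amp_pa * biexp_wave(tt, p$i_onset_ms, truth$i_rise_ms,
                               truth$i_decay_ms)
  if (truth$noise_sd_pa > 0) {
    rng <- local_rng(seed)
    e <- e + rng$rnorm(length(tt), 0, truth$noise_sd_pa)
    i <- i + rng$rnorm(length(tt), 0, truth$noise_sd_pa)
  }
  meta <- list(direction_deg = direction_deg,
               velocity_um_s = truth$velocity_um_s, synthetic = TRUE,
               truth = p, seed = seed)
  list(epsc = recording("voltage_clamp_current", tt, e,
                        metadata = c(meta, hold_mv = -60)),
       ipsc = recording("voltage_clamp_current", tt, i,
                        metadata = c(meta, hold_mv = 0)))
}

# per-direction firing-rate profile: rectified net drive
# (starburst E - I plus the untuned glutamate component) times gain
synth_rate_profile <- function(truth, direction_deg, dt_ms = 0.5,
                               duration_ms = NULL) {
  p <- truth_params(truth, direction_deg)
  if (is.null(duration_ms))
    duration_ms <- truth$stim_arrival_ms +
      8 * max(truth$e_decay_ms, truth$glut_decay_ms) + 100
  tt <- seq(dt_ms / 2, duration_ms, by = dt_ms)
  e <- p$e_amp_pa * biexp_wave(tt, p$e_onset_ms, truth$e_rise_ms,
                               truth$e_decay_ms)
  i <- p$i_amp_pa * biexp_wave(tt, p$i_onset_ms, truth$i_rise_ms,
                               truth$i_decay_ms)
  glut <- truth$glut_amp_pa * biexp_wave(tt, truth$stim_arrival_ms,
                                         truth$glut_rise_ms,
                                         truth$glut_decay_ms)
  data.frame(time_ms = tt,
             rate_hz = truth$rate_gain_hz_per_pa * pmax(e - i + glut, 0))
}

#' Expected spike counts of the synthetic rate profile
#'
#' Integrates the per-direction rate profile; the Poisson spike sampler's
#' per-direction mean counts converge to these values.
#'
#' @param truth A [synthetic_truth()] object.
#' @param directions Stimulus directions (degrees).
#' @param dt_ms Integration step (ms).
#' @return Named numeric vector of expected counts per direction.
#' @export
synth_expected_counts <- function(truth, directions, dt_ms = 0.5) {
  out <- vapply(directions, function(d) {
    pr <- synth_rate_profile(truth, d, dt_ms = dt_ms)
    sum(pr$rate_hz) * dt_ms / 1000
  }, numeric(1))
  names(out) <- directions
  out
}

#' Synthesise direction-tuned spike trains
#'
#' Draws inhomogeneous Poisson spike trains from a rate profile built from
#' the rectified difference of the ground-truth excitatory and inhibitory
#' drives. Early-window rates depend only on the timing (offset) mechanism
#' and sustained rates on the amplitude mechanism, so the truth's toggles
#' map directly onto window-specific tuning.
#'
#' @param truth A [synthetic_truth()] object.
#' @param directions Stimulus directions (degrees).
#' @param trials Number of trials per direction (>= 1).
#' @param seed Integer seed.
#' @param dt_ms Sampling resolution of the rate profile (ms).
#' @return List of spike-time `recording`s with `direction_deg` and
#'   `trial` metadata.
#' @export
synth_spike_trains <- function(truth, directions = seq(0, 315, by = 45),
                               trials = 10, seed = truth$seed, dt_ms = 0.5) {
  stopifnot(inherits(truth, "synthetic_truth"), trials >= 1)
  rng <- local_rng(seed)
  out <- list()
  for (d in directions) {
    pr <- synth_rate_profile(truth, d, dt_ms = dt_ms)
    lam <- pr$rate_hz * dt_ms / 1000
    for (tr in seq_len(trials)) {
      counts <- rng$rpois(length(lam), lam)
      idx <- rep(seq_along(lam), counts)
      ts <- sort(pr$time_ms[idx] +
                   rng$runif(length(idx), -dt_ms / 2, dt_ms / 2))
      ts <- ts[!duplicated(ts)]
      out[[length(out) + 1L]] <- recording(
        "spike_times", values = ts,
        metadata = list(direction_deg = d, trial = tr, synthetic = TRUE,
                        velocity_um_s = truth$velocity_um_s,
                        glut_rf_entry_ms = truth$stim_arrival_ms,
                        seed = seed))
    }
  }
  out
}
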