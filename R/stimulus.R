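#' Moving-bar stimulus
#'
#' Describes a bar sweeping across the retinal plane. The bar is modelled as
#' a leading edge of infinite extent perpendicular to the motion axis;
#' synaptic activation keys on the leading edge crossing each synapse's
#' (offset-shifted) position. Directions are degrees counter-clockwise from
#' the +x axis; the soma sits at the origin.
#'
#' @param direction_deg Motion direction of the bar (degrees).
#' @param velocity_um_s Bar speed (micrometres per second, > 0).
#' @param preferred_axis_deg The cell's preferred direction; angular
#'   distance 0 means the bar moves along this axis.
#' @param bar_width_um Bar extent along the motion axis (micrometres); only
#'   the leading (ON) edge schedules activation.
#' @param start_position_um Leading-edge coordinate (projected on the motion
#'   axis) at time 0. `NULL` (default) places it automatically outside the
#'   arbor plus the maximum spatial offset.
#' @param lead_um Extra travel distance (micrometres) between the automatic
#'   start position and the first synapse; larger values give a longer
#'   input-free baseline (useful for clamp measurements).
#' @return A `bar_stimulus` object.
#' @examples
#' bar_stimulus(direction_deg = 0, velocity_um_s = 1000)
#' @export
bar_stimulus <- function(direction_deg, velocity_um_s = 1000,
                         preferred_axis_deg = 0, bar_width_um = 200,
                         start_position_um = NULL, lead_um = 20) {
  if (!is.finite(direction_deg)) stop("direction_deg must be finite")
  if (velocity_um_s <= 0) stop("velocity_um_s must be positive")
  if (lead_um < 0) stop("lead_um must be >= 0")
  structure(list(direction_deg = direction_deg,
                 velocity_um_s = velocity_um_s,
                 preferred_axis_deg = preferred_axis_deg,
                 bar_width_um = bar_width_um,
                 start_position_um = start_position_um,
                 lead_um = lead_um),
            class = "bar_stimulus")
}

#' Per-transmitter directional tuning rules
#'
#' Returns the default tuning configuration for the three transmitter
#' systems converging on the model DSGC:
#' \itemize{
#'   \item glutamate (bipolar cells): non-directional, release probability
#'     0.5, no spatial offset;
#'   \item acetylcholine (starbursts all around the cell): non-directional
#'     release probability 0.5, isotropic 50 um offset toward the stimulus
#'     entry side;
#'   \item GABA (null-side starbursts): release probability rising from
#'     0.012 (preferred) to 0.5 (null) and offset from ~0 um (preferred) to
#'     ~50 um (null), both sigmoidal in angular distance.
#' }
#' `mode = "nonds_starburst"` emulates a starburst population rendered
#' non-directional: GABA release probability is held constant at 0.5 while
#' the spatial-offset tuning is retained, so direction selectivity can only
#' arise from excitation/inhibition timing.
#'
#' @param mode `"control"` or `"nonds_starburst"`.
#' @return Named list of [directional_tuning()] objects for `glutamate`,
#'   `acetylcholine`, `gaba`.
#' @export
transmitter_tuning <- function(mode = c("control", "nonds_starburst")) {
  mode <- match.arg(mode)
  gaba_pr <- if (mode == "control") c(0.012, 0.5) else c(0.5, 0.5)
  list(
    glutamate = directional_tuning(p_pr = 0.5, n_pr = 0.5,
                                   p_off = 0, n_off = 0),
    acetylcholine = directional_tuning(p_pr = 0.5, n_pr = 0.5,
                                       p_off = 50, n_off = 50),
    gaba = directional_tuning(p_pr = gaba_pr[1], n_pr = gaba_pr[2],
                              p_off = 0, n_off = 50)
  )
}

#' Schedule synaptic activation for one moving-bar pass
#'
#' Converts a bar stimulus, a set of synapse sites and per-transmitter
#' directional tuning into a per-trial activation schedule. For each site
#' and transmitter the scheduled time is the moment the bar's leading edge
#' reaches the site's position projected on the motion axis, advanced by
#' `spatial_offset / velocity` (the receptive field is displaced toward the
#' stimulus entry side). One Bernoulli draw per (site, transmitter) with the
#' tuned release probability decides whether the event releases.
#'
#' @param stimulus A [bar_stimulus()] object.
#' @param sites A `synapse_sites` data frame from [place_synapses()].
#' @param tuning Named list of [directional_tuning()] objects, one per
#'   transmitter (see [transmitter_tuning()]).
#' @param seed Integer seed for the release draws.
#' @param trial_id Integer trial label carried in the output.
#' @return An `activation_schedule` data frame with columns `trial`, `site`,
#'   `transmitter`, `time_ms`, `released`, `pr`, `offset_um`, and attributes
#'   `direction_deg`, `velocity_um_s`, `angle_dist_deg`, `seed`,
#'   `glut_rf_entry_ms` (time the leading edge reaches the first glutamate
#'   site position).
#' @examples
#' m <- generate_arbor(seed = 1)
#' s <- place_synapses(m)
#' sched <- activation_schedule(bar_stimulus(0), s, seed = 1)
#' head(sched)
#' @export
activation_schedule <- function(stimulus, sites,
                                tuning = transmitter_tuning("control"),
                                seed = 1, trial_id = 1L) {
  stopifnot(inherits(stimulus, "bar_stimulus"), is.data.frame(sites),
            nrow(sites) > 0)
  if (!all(vapply(tuning, inherits, TRUE, "directional_tuning")))
    stop("every tuning entry must be a directional_tuning object")
  v <- stimulus$velocity_um_s
  a <- angle_distance(stimulus$direction_deg, stimulus$preferred_axis_deg)
  th <- stimulus$direction_deg * pi / 180
  proj <- sites$x * cos(th) + sites$y * sin(th)

  max_off <- max(vapply(tuning, function(tt)
    max(abs(spatial_offset(c(0, 180), tt))), numeric(1)))
  x0 <- stimulus$start_position_um
  if (is.null(x0)) x0 <- min(proj) - max_off - stimulus$lead_um
  if (x0 > min(proj) - max_off)
    stop("leading edge must start outside the arbor plus the maximum spatial offset")

  rng <- local_rng(seed)
  out <- vector("list", length(tuning))
  for (k in seq_along(tuning)) {
    trans <- names(tuning)[k]
    pr <- release_probability(a, tuning[[k]])
    off <- spatial_offset(a, tuning[[k]])
    t_sched <- (proj - x0) / v * 1000 - off / v * 1000
    out[[k]] <- data.frame(trial = trial_id, site = sites$site_id,
                           transmitter = trans, time_ms = t_sched,
                           released = rng$runif(nrow(sites)) < pr,
                           pr = pr, offset_um = off,
                           stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, out)
  rownames(sched) <- NULL
  glut_entry <- if ("glutamate" %in% names(tuning))
    min(sched$time_ms[sched$transmitter == "glutamate"]) else NA_real_
  structure(sched,
            direction_deg = stimulus$direction_deg,
            velocity_um_s = v,
            angle_dist_deg = a,
            seed = seed,
            start_position_um = x0,
            glut_rf_entry_ms = glut_entry,
            class = c("activation_schedule", class(sched)))
}
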