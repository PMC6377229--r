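#' Directional tuning of synaptic release probability and spatial offset
#'
#' A `directional_tuning` object parameterises how a synapse population's
#' probability of release (Pr) and receptive-field spatial offset vary with
#' the angular distance between stimulus motion direction and the cell's
#' preferred axis. Both quantities follow a sigmoid of the angular distance:
#' Pr interpolates from `p_pr` (preferred, 0 deg) to `n_pr` (null, 180 deg),
#' and the spatial offset from `p_off` to `n_off` micrometres. The sigmoid
#' midpoints/slopes default to fits of inhibitory tuning curves and
#' excitation/inhibition temporal-offset measurements in mouse DSGCs.
#'
#' @param p_pr Release probability in the preferred direction, in \[0, 1\].
#' @param n_pr Release probability in the null direction, in \[0, 1\].
#' @param p_off Spatial offset (micrometres) in the preferred direction.
#' @param n_off Spatial offset (micrometres) in the null direction.
#' @param pr_midpoint_deg,pr_slope_deg Midpoint and slope (degrees) of the
#'   release-probability sigmoid.
#' @param off_midpoint_deg,off_slope_deg Midpoint and slope (degrees) of the
#'   spatial-offset sigmoid.
#' @param span Saturating span of the sigmoid (dimensionless, default 0.98);
#'   the residual `1 - span` keeps the endpoints slightly inside
#'   `[p_pr, n_pr]` (resp. `[p_off, n_off]`).
#' @return An object of class `directional_tuning`.
#' @examples
#' tun <- directional_tuning(p_pr = 0.012, n_pr = 0.5, p_off = 0, n_off = 50)
#' release_probability(180, tun)
#' spatial_offset(0, tun)
#' @export
directional_tuning <- function(p_pr = 0.012, n_pr = 0.5,
                               p_off = 0, n_off = 50,
                               pr_midpoint_deg = 91.0, pr_slope_deg = 25.0,
                               off_midpoint_deg = 74.69, off_slope_deg = 24.36,
                               span = 0.98) {
  stopifnot(is.numeric(p_pr), is.numeric(n_pr), length(p_pr) == 1L,
            length(n_pr) == 1L, is.finite(p_pr), is.finite(n_pr))
  if (p_pr < 0 || p_pr > 1 || n_pr < 0 || n_pr > 1)
    stop("release probabilities must lie in [0, 1]")
  if (pr_midpoint_deg <= 0 || pr_midpoint_deg >= 180 ||
      off_midpoint_deg <= 0 || off_midpoint_deg >= 180)
    stop("sigmoid midpoints must lie in (0, 180) degrees")
  if (pr_slope_deg <= 0 || off_slope_deg <= 0)
    stop("sigmoid slopes must be positive")
  structure(
    list(p_pr = p_pr, n_pr = n_pr, p_off = p_off, n_off = n_off,
         pr_midpoint_deg = pr_midpoint_deg, pr_slope_deg = pr_slope_deg,
         off_midpoint_deg = off_midpoint_deg, off_slope_deg = off_slope_deg,
         span = span),
    class = "directional_tuning"
  )
}

#' @export
print.directional_tuning <- function(x, ...) {
  cat("<directional_tuning>\n")
  cat(sprintf("  Pr:     %.4g (preferred) -> %.4g (null), midpoint %.4g deg, slope %.4g deg\n",
              x$p_pr, x$n_pr, x$pr_midpoint_deg, x$pr_slope_deg))
  cat(sprintf("  offset: %.4g um (preferred) -> %.4g um (null), midpoint %.4g deg, slope %.4g deg\n",
              x$p_off, x$n_off, x$off_midpoint_deg, x$off_slope_deg))
  invisible(x)
}

#' Angular distance between a stimulus direction and the preferred axis
#'
#' Wraps both angles modulo 360 and returns the absolute angular difference
#' in degrees, folded into \[0, 180\]: 0 means motion along the preferred
#' direction, 180 means null-direction motion.
#'
#' @param stimulus_direction_deg Stimulus motion direction (degrees,
#'   counter-clockwise from the +x axis). Vectorised.
#' @param preferred_axis_deg The cell's preferred direction (degrees).
#' @return Angular distance(s) in degrees, in \[0, 180\].
#' @examples
#' angle_distance(350, 10)  # 20
#' @export
angle_distance <- function(stimulus_direction_deg, preferred_axis_deg) {
  stopifnot(is.numeric(stimulus_direction_deg), is.numeric(preferred_axis_deg),
            all(is.finite(stimulus_direction_deg)),
            all(is.finite(preferred_axis_deg)))
  d <- (stimulus_direction_deg - preferred_axis_deg) %% 360
  ifelse(d > 180, 360 - d, d)
}

ds_sigmoid <- function(angle_dist_deg, midpoint, slope, span) {
  1 - span / (1 + exp((angle_dist_deg - midpoint) / slope))
}

#' Release probability as a function of angular distance
#'
#' Evaluates the sigmoidal tuning of transmitter release probability:
#' `Pr = p_pr + (n_pr - p_pr) * (1 - span / (1 + exp((a - m) / s)))`
#' with angular distance `a`, midpoint `m` and slope `s` in degrees.
#'
#' @param angle_dist_deg Angular distance from the preferred axis, degrees in
#'   \[0, 180\]. Vectorised.
#' @param tuning A [directional_tuning()] object.
#' @return Release probability (dimensionless).
#' @examples
#' tun <- directional_tuning(p_pr = 0.012, n_pr = 0.5)
#' release_probability(c(0, 91, 180), tun)
#' @export
release_probability <- function(angle_dist_deg, tuning) {
  stopifnot(inherits(tuning, "directional_tuning"),
            all(angle_dist_deg >= 0), all(angle_dist_deg <= 180))
  tuning$p_pr + (tuning$n_pr - tuning$p_pr) *
    ds_sigmoid(angle_dist_deg, tuning$pr_midpoint_deg, tuning$pr_slope_deg,
               tuning$span)
}

#' Receptive-field spatial offset as a function of angular distance
#'
#' Evaluates the sigmoidal tuning of the synaptic receptive-field
#' displacement:
#' `off = p_off - (p_off - n_off) * (1 - span / (1 + exp((a - m) / s)))`.
#' A positive offset displaces the input's receptive field toward the side
#' from which the stimulus enters, advancing its activation by
#' `offset / velocity`.
#'
#' @inheritParams release_probability
#' @return Spatial offset in micrometres.
#' @examples
#' tun <- directional_tuning(p_off = 0, n_off = 50)
#' spatial_offset(c(0, 74.69, 180), tun)
#' @export
spatial_offset <- function(angle_dist_deg, tuning) {
  stopifnot(inherits(tuning, "directional_tuning"),
            all(angle_dist_deg >= 0), all(angle_dist_deg <= 180))
  tuning$p_off - (tuning$p_off - tuning$n_off) *
    ds_sigmoid(angle_dist_deg, tuning$off_midpoint_deg, tuning$off_slope_deg,
               tuning$span)
}
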