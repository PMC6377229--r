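#' Write a recording to CSV with a JSON metadata sidecar
#'
#' Trace recordings become two-column CSVs (`time_ms`, `value`); spike
#' recordings a one-column CSV (`spike_time_ms`). Metadata (mode, hold
#' potential, direction, velocity, trial, seeds) goes to `<path>.json`.
#'
#' @param rec A `recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (rec$mode == "spike_times") {
    utils::write.csv(data.frame(spike_time_ms = rec$values), path,
                     row.names = FALSE)
  } else {
    utils::write.csv(data.frame(time_ms = rec$time_ms, value = rec$values),
                     path, row.names = FALSE)
  }
  meta <- rec$metadata
  meta$mode <- rec$mode
  meta$truth <- NULL    # ground truth stays out of serialized fixtures
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (the `.json` sidecar must sit alongside).
#' @return A `recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mode <- meta$mode
  meta$mode <- NULL
  df <- utils::read.csv(path)
  if (mode == "spike_times")
    recording("spike_times", values = df$spike_time_ms, metadata = meta)
  else
    recording(mode, time_ms = df$time_ms, values = df$value, metadata = meta)
}

#' Write an activation schedule to CSV
#'
#' Columns: `trial`, `site`, `transmitter`, `time_ms`, `released`, `pr`,
#' `offset_um`; stimulus attributes go to a JSON sidecar.
#'
#' @param schedule An `activation_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  jsonlite::write_json(
    list(direction_deg = attr(schedule, "direction_deg"),
         velocity_um_s = attr(schedule, "velocity_um_s"),
         angle_dist_deg = attr(schedule, "angle_dist_deg"),
         seed = attr(schedule, "seed"),
         start_position_um = attr(schedule, "start_position_um"),
         glut_rf_entry_ms = attr(schedule, "glut_rf_entry_ms")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a morphology and synapse sites to JSON
#'
#' @param morphology A `morphology`.
#' @param synapse_sites Optional `synapse_sites`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(morphology, path, synapse_sites = NULL) {
  obj <- list(arbor_radius_um = attr(morphology, "arbor_radius_um"),
              compartments = as.data.frame(morphology))
  if (!is.null(synapse_sites)) {
    obj$synapse_sites <- as.data.frame(synapse_sites)
    obj$receptors <- attr(synapse_sites, "receptors")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a morphology (and synapse sites) written by [write_morphology()]
#'
#' @param path JSON path.
#' @return List with `morphology` and (if present) `synapse_sites`.
#' @export
read_morphology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$compartments
  attr(m, "arbor_radius_um") <- obj$arbor_radius_um
  class(m) <- c("morphology", class(m))
  validate_morphology(m)
  out <- list(morphology = m)
  if (!is.null(obj$synapse_sites)) {
    s <- obj$synapse_sites
    attr(s, "receptors") <- lapply(obj$receptors, function(r) r)
    class(s) <- c("synapse_sites", class(s))
    out$synapse_sites <- s
  }
  out
}
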