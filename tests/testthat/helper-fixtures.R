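# Shared fixtures, built once per test run.

.fixtures <- new.env()

default_geometry <- function() {
  if (is.null(.fixtures$cell)) {
    m <- generate_arbor(seed = 1)
    s <- place_synapses(m)
    .fixtures$morph <- m
    .fixtures$sites <- s
    .fixtures$cell <- build_cell(m, s)
  }
  list(morph = .fixtures$morph, sites = .fixtures$sites,
       cell = .fixtures$cell)
}

# a bare soma (cylinder with length = diameter) for closed-form checks
soma_morphology <- function(diameter_um = 12) {
  m <- data.frame(id = 1L, parent = NA_integer_, x = 0, y = 0,
                  length_um = diameter_um, diameter_um = diameter_um,
                  region = "soma", stringsAsFactors = FALSE)
  attr(m, "arbor_radius_um") <- diameter_um
  class(m) <- c("morphology", class(m))
  m
}

empty_sites <- function(receptors = receptor_defaults()) {
  s <- data.frame(site_id = integer(), compartment_id = integer(),
                  x = numeric(), y = numeric())
  attr(s, "receptors") <- receptors
  class(s) <- c("synapse_sites", class(s))
  s
}

soma_site <- function(receptors = receptor_defaults()) {
  s <- data.frame(site_id = 1L, compartment_id = 1L, x = 0, y = 0)
  attr(s, "receptors") <- receptors
  class(s) <- c("synapse_sites", class(s))
  s
}

# hand-built schedule (bypasses the bar geometry) for clamp unit tests
manual_schedule <- function(events, direction_deg = 0,
                            velocity_um_s = 1000) {
  structure(events, direction_deg = direction_deg,
            velocity_um_s = velocity_um_s, seed = 0,
            glut_rf_entry_ms = min(events$time_ms),
            class = c("activation_schedule", class(events)))
}

one_event <- function(transmitter, time_ms, site = 1L, trial = 1L) {
  data.frame(trial = trial, site = site, transmitter = transmitter,
             time_ms = time_ms, released = TRUE, pr = 1, offset_um = 0,
             stringsAsFactors = FALSE)
}

# release schedules restricted to a subset of transmitters
tuning_only <- function(keep, base = transmitter_tuning("control")) {
  for (nm in names(base))
    if (!nm %in% keep)
      base[[nm]] <- directional_tuning(p_pr = 0, n_pr = 0,
                                       p_off = base[[nm]]$p_off,
                                       n_off = base[[nm]]$n_off)
  base
}

# closed-form peak-normalised bi-exponential, independent of package code
ref_biexp <- function(t, onset, tau_r, tau_d) {
  x <- pmax(t - onset, 0)
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  pk <- exp(-tp / tau_d) - exp(-tp / tau_r)
  ifelse(t > onset, (exp(-x / tau_d) - exp(-x / tau_r)) / pk, 0)
}
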