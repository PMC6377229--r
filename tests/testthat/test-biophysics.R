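test_that("passive soma follows the analytic RC step response", {
  m <- soma_morphology(diameter_um = 12)
  cfg <- biophysics_config(leak_ms_cm2 = 0.05,
                           na_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                         terminal_dendrite = 0),
                           k_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                        terminal_dendrite = 0),
                           km_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                         terminal_dendrite = 0),
                           noise_sd_pa = 0)
  cell <- build_cell(m, empty_sites(), cfg)
  area <- pi * 12^2                        # um^2
  g_us <- 0.05 * area * 1e-5
  c_nf <- 1 * area * 1e-5
  tau <- c_nf / g_us                       # = cm / leak density = 20 ms
  expect_equal(tau, 20)
  i_na <- 2e-4
  sch <- manual_schedule(one_event("glutamate", 1e6))  # no released event in window
  sch$released <- FALSE
  cc <- run_current_clamp(cell, sch, duration_ms = 120, noise = FALSE,
                          i_inj = list(onset_ms = 0, duration_ms = 120,
                                       amplitude_na = i_na))
  v <- cc$voltage
  pred <- -60 + (i_na / g_us) * (1 - exp(-v$time_ms / tau))
  rms <- sqrt(mean((v$values - pred)^2)) / (i_na / g_us)
  expect_lt(rms, 0.01)
})

test_that("the cell rests at the leak reversal", {
  m <- soma_morphology()
  cfg <- biophysics_config(na_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                         terminal_dendrite = 0),
                           k_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                        terminal_dendrite = 0),
                           km_ms_cm2 = c(soma = 0, primary_dendrite = 0,
                                         terminal_dendrite = 0),
                           noise_sd_pa = 0)
  cell <- build_cell(m, empty_sites(), cfg)
  sch <- manual_schedule(one_event("glutamate", 1e6)); sch$released <- FALSE
  cc <- run_current_clamp(cell, sch, duration_ms = 200, noise = FALSE)
  expect_equal(max(abs(cc$voltage$values + 60)), 0, tolerance = 1e-9)
  # with the printed active densities the resting potential stays close
  g <- default_geometry()
  sch2 <- manual_schedule(one_event("glutamate", 1e6)); sch2$released <- FALSE
  cc2 <- run_current_clamp(g$cell, sch2, duration_ms = 300, noise = FALSE)
  expect_lt(max(abs(cc2$voltage$values + 60)), 5)
})

test_that("printed channel densities support somatic spiking", {
  g <- default_geometry()
  sch <- manual_schedule(one_event("glutamate", 1e6)); sch$released <- FALSE
  cc <- run_current_clamp(g$cell, sch, duration_ms = 100, noise = FALSE,
                          i_inj = list(onset_ms = 20, duration_ms = 5,
                                       amplitude_na = 0.5))
  expect_gte(length(cc$spikes$values), 1)
  expect_gt(max(cc$voltage$values) - (-60), 40)  # regenerative upstroke
})

test_that("an empty schedule produces no spikes", {
  g <- default_geometry()
  sch <- manual_schedule(one_event("glutamate", 1e6)); sch$released <- FALSE
  cc <- run_current_clamp(g$cell, sch, duration_ms = 300, noise = FALSE)
  expect_length(cc$spikes$values, 0)
})

test_that("a bar-evoked excitatory schedule drives spiking", {
  g <- default_geometry()
  tun <- tuning_only(c("glutamate", "acetylcholine"))
  sch <- activation_schedule(bar_stimulus(0), g$sites, tun, seed = 2)
  cc <- run_current_clamp(g$cell, sch, noise = FALSE)
  expect_gte(length(cc$spikes$values), 1)
})

test_that("different noise seeds produce variable spike counts", {
  g <- default_geometry()
  tun <- tuning_only(c("glutamate", "acetylcholine"))
  sch <- activation_schedule(bar_stimulus(0), g$sites, tun, seed = 2)
  counts <- vapply(1:6, function(ns)
    length(run_current_clamp(g$cell, sch, noise_seed = ns,
                             noise = TRUE)$spikes$values), numeric(1))
  expect_gt(stats::sd(counts), 0)
  # identical seeds reproduce exactly
  c1 <- run_current_clamp(g$cell, sch, noise_seed = 3, noise = TRUE)
  c2 <- run_current_clamp(g$cell, sch, noise_seed = 3, noise = TRUE)
  expect_identical(c1$voltage$values, c2$voltage$values)
})

test_that("voltage clamp nulls synaptic currents at their reversals", {
  g <- default_geometry()
  tun_gaba <- tuning_only("gaba",
                          base = transmitter_tuning("nonds_starburst"))
  sch_g <- activation_schedule(bar_stimulus(180), g$sites, tun_gaba, seed = 4)
  at_rev <- run_voltage_clamp(g$cell, sch_g, hold_mv = -60)
  at_0 <- run_voltage_clamp(g$cell, sch_g, hold_mv = 0)
  dev <- function(r) max(abs(r$values - stats::median(r$values)))
  expect_lt(dev(at_rev), 0.01 * dev(at_0))

  # excitatory null requires the perfect-clamp limit: on the distributed
  # cell the unclamped dendrites keep a real driving force
  cell1 <- build_cell(soma_morphology(), soma_site(),
                      biophysics_config(noise_sd_pa = 0))
  sch_e <- manual_schedule(rbind(one_event("glutamate", 60),
                                 one_event("acetylcholine", 60)))
  e_at_0 <- run_voltage_clamp(cell1, sch_e, hold_mv = 0, duration_ms = 200)
  e_at_rest <- run_voltage_clamp(cell1, sch_e, hold_mv = -60,
                                 duration_ms = 200)
  expect_lt(dev(e_at_0), 0.01 * dev(e_at_rest))
})

test_that("single-synapse clamp current matches the closed-form waveform", {
  # perfect-clamp small-cell limit: one compartment, one released synapse
  m <- soma_morphology(diameter_um = 12)
  rec <- receptor_defaults()
  cell <- build_cell(m, soma_site(rec), biophysics_config(noise_sd_pa = 0))
  sch <- manual_schedule(one_event("gaba", 50))
  r <- run_voltage_clamp(cell, sch, hold_mv = 0, duration_ms = 300)
  base <- mean(r$values[r$time_ms < 45])
  spec <- rec$gaba
  g_ns <- spec$gpeak_ns * ref_biexp(r$time_ms, 50, spec$rise_ms,
                                    spec$decay_ms)
  pred_pa <- g_ns * (0 - spec$e_rev_mv)   # driving force 60 mV
  got <- r$values - base
  expect_lt(max(abs(got - pred_pa)) / max(pred_pa), 0.05)
})

test_that("halving the integration step leaves results stable", {
  g <- default_geometry()
  tun <- transmitter_tuning("control")
  sch <- activation_schedule(bar_stimulus(0, lead_um = 150), g$sites, tun,
                             seed = 9)
  n1 <- length(run_current_clamp(g$cell, sch, noise = FALSE)$spikes$values)
  n2 <- length(run_current_clamp(g$cell, sch, noise = FALSE,
                                 dt_ms = 0.0125)$spikes$values)
  expect_lte(abs(n1 - n2), 1)
  clamp_peak <- function(dt) {
    r <- run_voltage_clamp(g$cell, sch, hold_mv = 0, dt_ms = dt)
    base <- mean(r$values[r$time_ms > 60 & r$time_ms < 140])
    max(abs(r$values[r$time_ms > 140] - base))
  }
  p1 <- clamp_peak(NULL); p2 <- clamp_peak(0.0125)
  expect_lt(abs(p1 - p2) / p2, 0.02)
})

test_that("with no synapses and no noise the clamp current is the leak current", {
  m <- soma_morphology(diameter_um = 12)
  cfg <- biophysics_config(noise_sd_pa = 0)
  cell <- build_cell(m, empty_sites(), cfg)
  sch <- manual_schedule(one_event("glutamate", 1e6)); sch$released <- FALSE
  hold <- -50
  r <- run_voltage_clamp(cell, sch, hold_mv = hold, duration_ms = 50)
  g_us <- cfg$leak_ms_cm2 * pi * 12^2 * 1e-5
  want_pa <- g_us * (hold - (-60)) * 1000
  expect_equal(max(abs(r$values[-1] - want_pa)), 0, tolerance = 1e-9)
})

test_that("peak IPSC grows monotonically with released GABA conductance", {
  m <- soma_morphology(diameter_um = 12)
  cell <- build_cell(m, soma_site(), biophysics_config(noise_sd_pa = 0))
  peaks <- vapply(c(1, 3, 6), function(k) {
    ev <- do.call(rbind, lapply(seq_len(k), function(i)
      one_event("gaba", 50, site = 1L)))
    r <- run_voltage_clamp(cell, manual_schedule(ev), hold_mv = 0,
                           duration_ms = 200)
    max(r$values) - mean(r$values[r$time_ms < 45])
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("recordings enforce their structural invariants", {
  expect_error(recording("spike_times", values = c(3, 2, 1)), "increasing")
  expect_error(recording("voltage_clamp_current", time_ms = 0:10,
                         values = 0:10, metadata = list()), "hold_mv")
  expect_error(recording("membrane_voltage", time_ms = c(0, 1, 3),
                         values = c(0, 0, 0)), "uniform")
})
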