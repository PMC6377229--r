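test_that("Gaussian-kernel rate has the analytic peak and unit mass", {
  r <- smooth_firing_rate(100, sigma_ms = 25, dt_ms = 0.5)
  # single spike: peak = 1000 / (sigma * sqrt(2 pi)) Hz at the spike time
  expect_equal(max(r$rate_hz), 1000 / (25 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(r$time_ms[which.max(r$rate_hz)], 100)
  expect_equal(sum(r$rate_hz) * 0.5 / 1000, 1, tolerance = 1e-3)
  # N coincident spikes scale the peak exactly N-fold
  r3 <- smooth_firing_rate(rep(100, 3), sigma_ms = 25, dt_ms = 0.5)
  expect_equal(max(r3$rate_hz), 3 * max(r$rate_hz), tolerance = 1e-12)
  # integral equals the spike count for arbitrary trains
  tr <- sort(stats::runif(37, 0, 500))
  ri <- smooth_firing_rate(tr, sigma_ms = 25, dt_ms = 0.25)
  expect_equal(sum(ri$rate_hz) * 0.25 / 1000, 37, tolerance = 37 * 1e-3)
  # empty train: all-zero trace, not an error
  r0 <- smooth_firing_rate(numeric(0), sigma_ms = 25, dt_ms = 1,
                           t_range = c(0, 100))
  expect_true(all(r0$rate_hz == 0))
})

test_that("DSI extremes match the definition", {
  dirs <- seq(0, 315, by = 45)
  one <- direction_selectivity_index(
    direction_series(dirs, c(7, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(one$dsi, 1)
  expect_equal(one$preferred_angle_deg, 0)
  flat <- direction_selectivity_index(direction_series(dirs, rep(4, 8)))
  expect_equal(flat$dsi, 0, tolerance = 1e-12)
  # seven-plus-one decomposition: the unit vectors cancel, one remains
  lop <- direction_selectivity_index(
    direction_series(dirs, c(2, 1, 1, 1, 1, 1, 1, 1)))
  expect_equal(lop$dsi, 1 / 9, tolerance = 1e-12)
  expect_equal(lop$preferred_angle_deg, 0)
})

test_that("DSI equals the complex-resultant oracle and is scale invariant", {
  set.seed(7)
  dirs <- seq(0, 315, by = 45)
  for (rep in 1:20) {
    r <- stats::rexp(8)
    got <- direction_selectivity_index(direction_series(dirs, r))
    z <- sum(r * exp(1i * dirs * pi / 180))
    expect_equal(got$dsi, Mod(z) / sum(r), tolerance = 1e-12)
    expect_equal(got$preferred_angle_deg, (Arg(z) * 180 / pi) %% 360,
                 tolerance = 1e-9)
    expect_lte(got$dsi, 1)
    scaled <- direction_selectivity_index(direction_series(dirs, 17.3 * r))
    expect_equal(scaled$dsi, got$dsi, tolerance = 1e-12)
    expect_equal(scaled$preferred_angle_deg, got$preferred_angle_deg)
  }
})

test_that("all-zero response series yields an explicit no-response result", {
  s <- direction_series(seq(0, 315, by = 45), rep(0, 8))
  res <- direction_selectivity_index(s)
  expect_true(res$no_response)
  expect_true(is.na(res$dsi))
})

test_that("multi-trial series report per-trial variability", {
  dirs <- rep(seq(0, 315, by = 45), times = 3)
  trials <- rep(1:3, each = 8)
  r <- c(10, 5, 1, 0, 0, 0, 1, 5,
         12, 4, 2, 1, 0, 1, 1, 6,
         9, 6, 1, 0, 1, 0, 2, 4)
  res <- direction_selectivity_index(direction_series(dirs, r, trial = trials))
  expect_equal(res$n_trials, 3L)
  expect_equal(nrow(res$per_trial), 3L)
  expect_gt(res$sd_dsi, 0)
  expect_gt(res$sd_angle_deg, 0)
  # identical trials collapse the variability to zero
  same <- direction_selectivity_index(
    direction_series(dirs, rep(c(10, 5, 1, 0, 0, 0, 1, 5), 3),
                     trial = trials))
  expect_equal(same$sd_dsi, 0)
  expect_equal(same$sd_angle_deg, 0)
})

test_that("onset fit recovers a piecewise-linear ramp exactly", {
  tt <- seq(0, 400, by = 0.1)
  y <- pmax(tt - 100, 0) * 2
  est <- onset_latency(data.frame(time_ms = tt, value = y),
                       baseline_window_ms = 90)
  expect_false(est$no_response)
  expect_equal(est$onset_ms, 100, tolerance = 1e-6)
  expect_lte(est$onset_ms, est$t20_ms)
  # translation equivariance
  y2 <- pmax(tt - 160, 0) * 2
  est2 <- onset_latency(data.frame(time_ms = tt, value = y2),
                        baseline_window_ms = 90)
  expect_equal(est2$onset_ms - est$onset_ms, 60, tolerance = 1e-6)
})

test_that("onset fit recovers bi-exponential activation times", {
  tt <- seq(0, 500, by = 0.1)
  t0 <- 250
  y <- 80 * ref_biexp(tt, t0, 1, 10)
  est <- onset_latency(data.frame(time_ms = tt, value = y))
  expect_lt(abs(est$onset_ms - t0), 1)
  # negative-going (EPSC) polarity handled identically
  estn <- onset_latency(data.frame(time_ms = tt, value = -y))
  expect_equal(estn$onset_ms, est$onset_ms, tolerance = 1e-9)
})

test_that("onset estimator tolerates additive noise (100 seeded draws)", {
  tt <- seq(0, 500, by = 0.1)
  t0 <- 250
  clean <- 80 * ref_biexp(tt, t0, 1, 10)
  set.seed(123)
  errs <- vapply(1:100, function(i) {
    y <- clean + stats::rnorm(length(tt), 0, 8)   # 10% of peak
    est <- onset_latency(data.frame(time_ms = tt, value = y))
    if (est$no_response) NA_real_ else est$onset_ms - t0
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(mean(abs(errs)), 5)
})

test_that("flat traces give a no-response sentinel", {
  tt <- seq(0, 300, by = 0.1)
  est <- onset_latency(data.frame(time_ms = tt, value = rep(0, length(tt))))
  expect_true(est$no_response)
  # noisy baseline with no peak above 5 SD also declines
  set.seed(1)
  est2 <- onset_latency(data.frame(time_ms = tt,
                                   value = stats::rnorm(length(tt))))
  expect_true(est2$no_response)
})

test_that("E/I offset sign convention and clamping follow the definition", {
  tt <- seq(0, 500, by = 0.1)
  mk <- function(t0, sign, hold) recording(
    "voltage_clamp_current", tt, sign * 100 * ref_biexp(tt, t0, 1, 10),
    metadata = list(hold_mv = hold))
  # excitation leads inhibition: positive offset
  est <- ei_temporal_offset(mk(100, -1, -60), mk(150, 1, 0))
  expect_equal(est$offset_ms, 50, tolerance = 0.5)
  expect_equal(est$clamped_offset_ms, est$offset_ms)
  # inhibition leads: negative offset, clamped to zero
  est2 <- ei_temporal_offset(mk(100, -1, -60), mk(90, 1, 0))
  expect_equal(est2$offset_ms, -10, tolerance = 0.5)
  expect_equal(est2$clamped_offset_ms, 0)
  # identical traces: zero offset
  x <- mk(100, 1, 0)
  est3 <- ei_temporal_offset(x, x)
  expect_equal(est3$offset_ms, 0, tolerance = 1e-9)
  # missing response propagates the sentinel
  flat <- recording("voltage_clamp_current", tt, rep(0, length(tt)),
                    metadata = list(hold_mv = 0))
  est4 <- ei_temporal_offset(mk(100, -1, -60), flat)
  expect_true(is.na(est4$offset_ms))
})

test_that("temporal-spatial offset conversion inverts the schedule division", {
  expect_equal(temporal_to_spatial_offset(50, 1000), 50)
  expect_equal(temporal_to_spatial_offset(0, 123), 0)
  expect_error(temporal_to_spatial_offset(10, 0), "positive")
  # round trip through the schedule's offset/velocity division
  g <- default_geometry()
  for (v in c(300, 1000, 2400)) {
    sch <- activation_schedule(bar_stimulus(180, velocity_um_s = v),
                               g$sites, seed = 1)
    gaba <- sch[sch$transmitter == "gaba", ][1, ]
    glut_t <- sch$time_ms[sch$transmitter == "glutamate" &
                            sch$site == gaba$site]
    lead_ms <- glut_t - gaba$time_ms
    expect_equal(temporal_to_spatial_offset(lead_ms, v), gaba$offset_um,
                 tolerance = 1e-9)
  }
})

test_that("phase windows separate timing-tuned from uniform responses", {
  # early burst tuned, late response uniform, by construction
  dirs <- seq(0, 315, by = 45)
  entry <- 100
  mk_train <- function(d, tr) {
    early <- if (d %in% c(0, 45, 315)) seq(60, 95, by = 10) else numeric(0)
    late <- seq(120, 300, by = 15)
    recording("spike_times", values = sort(c(early, late)) + tr * 1e-9,
              metadata = list(direction_deg = d, trial = tr))
  }
  recs <- list()
  for (d in dirs) for (tr in 1:2)
    recs[[length(recs) + 1]] <- mk_train(d, tr)
  ph <- phase_tuning(recs, glut_rf_entry_ms = entry)
  expect_gt(ph$early$dsi, ph$peak$dsi)
  expect_equal(ph$early$sd_dsi, 0)      # identical trains across trials
  expect_equal(ph$early$sd_angle_deg, 0)
})

test_that("phase tuning recovers the configured preferred angle", {
  truth <- synthetic_truth(preferred_angle_deg = 90, noise_sd_pa = 0,
                           glut_amp_pa = 30, rate_gain_hz_per_pa = 4)
  recs <- synth_spike_trains(truth, trials = 12, seed = 21)
  ph <- phase_tuning(recs, glut_rf_entry_ms = truth$stim_arrival_ms)
  da_early <- abs((ph$early$preferred_angle_deg - 90 + 180) %% 360 - 180)
  da_peak <- abs((ph$peak$preferred_angle_deg - 90 + 180) %% 360 - 180)
  expect_lt(da_early, 25)
  expect_lt(da_peak, 25)
})
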