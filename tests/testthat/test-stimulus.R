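test_that("activation times match a brute-force projection oracle", {
  # <= 10 sites, recomputed independently from raw coordinates
  set.seed(99)
  sites <- data.frame(site_id = 1:8, compartment_id = 1L,
                      x = stats::runif(8, -120, 120),
                      y = stats::runif(8, -120, 120))
  attr(sites, "receptors") <- receptor_defaults()
  class(sites) <- c("synapse_sites", class(sites))
  tun <- transmitter_tuning("control")
  for (dir in c(0, 30, 135, 250)) {
    stim <- bar_stimulus(dir, velocity_um_s = 700, lead_um = 35)
    sch <- activation_schedule(stim, sites, tun, seed = 1)
    th <- dir * pi / 180
    proj <- sites$x * cos(th) + sites$y * sin(th)
    a <- angle_distance(dir, 0)
    x0 <- min(proj) - 50 - 35          # max offset is 50 um (ACh)
    for (trans in names(tun)) {
      off <- spatial_offset(a, tun[[trans]])
      want <- (proj - x0) / 700 * 1000 - off / 700 * 1000
      got <- sch$time_ms[sch$transmitter == trans]
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("cholinergic offset advances activation by offset/velocity", {
  # single site at the soma origin, bar entering from the preferred side
  sites <- soma_site()
  sch <- activation_schedule(bar_stimulus(0, velocity_um_s = 1000), sites,
                             transmitter_tuning("control"), seed = 1)
  t_ach <- sch$time_ms[sch$transmitter == "acetylcholine"]
  t_glu <- sch$time_ms[sch$transmitter == "glutamate"]
  expect_equal(t_glu - t_ach, 50)      # 50 um at 1 mm/s = 50 ms lead
  # null-direction bar: GABA leads glutamate by ~49.36 um / v
  schn <- activation_schedule(bar_stimulus(180, velocity_um_s = 1000),
                              sites, transmitter_tuning("control"), seed = 1)
  lead_n <- schn$time_ms[schn$transmitter == "glutamate"] -
    schn$time_ms[schn$transmitter == "gaba"]
  expect_equal(lead_n, 49.36, tolerance = 1e-4)
  # preferred-direction GABA lead is only the ~3.18 um residual
  lead_p <- t_glu - sch$time_ms[sch$transmitter == "gaba"]
  expect_equal(lead_p, 3.18, tolerance = 1e-2)
})

test_that("zero release probability yields no released events", {
  g <- default_geometry()
  tun <- tuning_only(character(0))    # all transmitters at Pr = 0
  sch <- activation_schedule(bar_stimulus(0), g$sites, tun, seed = 5)
  expect_false(any(sch$released))
})

test_that("schedules are seed-deterministic", {
  g <- default_geometry()
  s1 <- activation_schedule(bar_stimulus(45), g$sites, seed = 11)
  s2 <- activation_schedule(bar_stimulus(45), g$sites, seed = 11)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("mirrored directions give mirror-image schedules", {
  # radially symmetric site layout; identical tuning for all transmitters
  ang <- seq(0, 2 * pi - 1e-9, by = pi / 4)
  sites <- data.frame(site_id = seq_along(ang), compartment_id = 1L,
                      x = 100 * cos(ang), y = 100 * sin(ang))
  attr(sites, "receptors") <- receptor_defaults()
  class(sites) <- c("synapse_sites", class(sites))
  tun <- list(glutamate = directional_tuning(0.5, 0.5, 10, 40),
              acetylcholine = directional_tuning(0.5, 0.5, 10, 40),
              gaba = directional_tuning(0.5, 0.5, 10, 40))
  for (theta in c(30, 75, 120)) {
    sa <- activation_schedule(bar_stimulus(theta, lead_um = 20), sites, tun,
                              seed = 1)
    sb <- activation_schedule(bar_stimulus(-theta, lead_um = 20), sites, tun,
                              seed = 1)
    # site (x, y) under +theta maps onto site (x, -y) under -theta
    mirror <- match(paste(round(sites$x, 6), round(-sites$y, 6)),
                    paste(round(sites$x, 6), round(sites$y, 6)))
    for (trans in names(tun)) {
      ta <- sa$time_ms[sa$transmitter == trans]
      tb <- sb$time_ms[sb$transmitter == trans]
      expect_equal(ta, tb[mirror], tolerance = 1e-9)
    }
  }
})

test_that("invalid stimuli are rejected", {
  g <- default_geometry()
  expect_error(bar_stimulus(0, velocity_um_s = 0), "positive")
  expect_error(bar_stimulus(0, velocity_um_s = -5), "positive")
  expect_error(
    activation_schedule(bar_stimulus(0, start_position_um = 0), g$sites),
    "outside")
})

test_that("schedule CSV round trip preserves events", {
  g <- default_geometry()
  sch <- activation_schedule(bar_stimulus(90), g$sites, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sch, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(sch))
  expect_equal(back$time_ms, sch$time_ms, tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$direction_deg, 90)
})
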