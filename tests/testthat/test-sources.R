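test_that("flow waveform integrates to the stroke volume", {
  for (sv in c(60, 72)) {
    fw <- flow_waveform(sv_ml = sv, T_beat = 1, fs = 10000)
    expect_equal(sum(fw$Q) / fw$fs, sv * 1e-6, tolerance = 1e-4)
    # cardiac output at 60 bpm, in l/min
    expect_equal(mean(fw$Q) * 1000 * 60, sv * 60 / 1000, tolerance = 1e-4)
    # peak at t/T = 0.12 (grid-nearest sample), zero after t/T = 0.35
    expect_equal(fw$time[which.max(fw$Q)], 0.12, tolerance = 1e-4)
    expect_equal(max(abs(fw$Q[fw$time > 0.35])), 0)
  }
  expect_equal(max(abs(flow_waveform(sv_ml = 0)$Q)), 0)
})

test_that("orifice pressure drop follows the Bernoulli hand calculation", {
  # steady flow, quadratic term only
  expect_equal(orifice_pressure_drop(0, 3e-4, dQdt = 0), 0)
  q <- 20 / 60000 # 20 l/min in m^3/s
  dp <- orifice_pressure_drop(q, 3e-4, dQdt = 0)
  expect_equal(dp, 0.5 * 1060 * (q / 3e-4)^2)
  # doubling the flow quadruples the quadratic term
  expect_equal(orifice_pressure_drop(2 * q, 3e-4, dQdt = 0), 4 * dp)
  # area floor engages below the minimum opening
  expect_equal(orifice_pressure_drop(q, 0, dQdt = 0),
               0.5 * 1060 * (q / 1.5e-4)^2)
  expect_error(orifice_pressure_drop(q, -1e-5, dQdt = 0), "negative PVOA")
})

test_that("murmur envelope is the crescendo-decrescendo diamond", {
  t <- seq(0, 0.5, by = 1e-4)
  e <- murmur_envelope(t, T_beat = 1)
  expect_equal(max(abs(e[t < 0.06])), 0)
  expect_equal(max(abs(e[t > 0.35])), 0)
  expect_equal(e[which.min(abs(t - 0.18))], 1, tolerance = 1e-2)
  expect_true(all(diff(e[t >= 0.06 & t <= 0.18]) >= 0))
  expect_true(all(diff(e[t >= 0.18 & t <= 0.35]) <= 0))
  expect_true(all(e >= 0))
})

test_that("scenario definitions enforce their invariants", {
  h <- hemodynamic_scenario("healthy")
  expect_equal(h$multipliers, c(1, 1, 1))
  r1 <- hemodynamic_scenario("rlm1", multiplier = 4)
  expect_equal(sort(r1$multipliers), c(1, 1, 4))
  r2 <- hemodynamic_scenario("rlm2", multiplier = 4)
  expect_equal(sort(r2$multipliers), c(1, 4, 4))
  expect_error(hemodynamic_scenario("custom"), "multipliers")
  expect_error(hemodynamic_scenario("custom", multipliers = c(0.5, 1, 1)),
               ">= 1")
})

test_that("panel synthesis reproduces the healthy/stenotic phenomenology", {
  panels <- default_panels()
  fs <- 10000
  traj_h <- fixture_trajectory("healthy", 1)
  traj_s <- fixture_trajectory("rlm1", 8)

  scn_h <- hemodynamic_scenario("healthy", seed = 5L)
  src_h <- synthesize_panel_pressures(scn_h, traj_h, panels, fs)
  scn_s <- hemodynamic_scenario("rlm1", multiplier = 8, seed = 5L)
  src_s <- synthesize_panel_pressures(scn_s, traj_s, panels, fs)

  # all series zero-mean
  expect_lt(max(abs(colMeans(src_h$pressure))), 1e-12)
  expect_lt(max(abs(colMeans(src_s$pressure))), 1e-12)

  # healthy: no murmur -- systolic-band energy is only the noise floor,
  # and the dominant feature is a single synchronous S2
  t <- traj_h$time[-1]
  sys <- t >= 0.06 & t <= 0.30
  rms_h <- mean(apply(src_h$pressure[sys, ], 2, sd))
  expect_lt(rms_h, 1.5 * scn_h$noise_floor)
  ev_h <- detect_events(traj_h)
  expect_equal(length(unique(ev_h$closure)), 1)

  # stenotic: murmur raises the systolic band well above the floor
  rms_s <- mean(apply(src_s$pressure[sys, ], 2, sd))
  expect_gt(rms_s, 1.5 * rms_h)

  # RLM1: exactly two distinct S2 impulse times (stiff early, two healthy
  # leaflets synchronously late)
  ev_s <- detect_events(traj_s)
  expect_equal(length(unique(ev_s$closure)), 2)
  expect_lt(ev_s$closure[1], ev_s$closure[2])
  expect_equal(ev_s$closure[2], ev_s$closure[3])

  # determinism: same seed, same scenario -> bit-identical pressures
  src_s2 <- synthesize_panel_pressures(scn_s, traj_s, panels, fs)
  expect_identical(src_s$pressure, src_s2$pressure)
})

test_that("stenotic systolic RMS exceeds healthy across seeds at the monitor", {
  panels <- default_panels()
  med <- make_medium()
  mon <- monitor_point()
  traj_h <- fixture_trajectory("healthy", 1)
  traj_s <- fixture_trajectory("rlm1", 8)
  sys <- traj_h$time[-1] >= 0.06 & traj_h$time[-1] <= 0.35
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    # equal noise floor and murmur gain; only the valve condition differs
    rh <- propagate(synthesize_panel_pressures(
      hemodynamic_scenario("healthy", seed = s), traj_h, panels), mon, med)
    rs <- propagate(synthesize_panel_pressures(
      hemodynamic_scenario("rlm1", multiplier = 8, seed = 1000L + s),
      traj_s, panels), mon, med)
    wins <- wins + (sd(rs$a[sys]) > sd(rh$a[sys]))
  }
  expect_equal(wins, n_seeds)
})

test_that("ejection click of a strongly stiffened leaflet is early in acceleration", {
  traj <- fixture_trajectory("rlm1", 20)
  ev <- detect_events(traj)
  # stiffest leaflet's first direction reversal: t/T = 0.06 +- 0.04
  expect_gt(ev$reversal[1], 0.02)
  expect_lt(ev$reversal[1], 0.10)
  # and it precedes peak systole's end of acceleration window
  expect_lt(ev$reversal[1], 0.12)
})

test_that("dataset generation is reproducible and correctly labeled", {
  ds <- fixture_small_dataset()
  expect_equal(dim(ds$signals), c(4, 5000))
  expect_equal(ds$labels, c("healthy", "healthy", "stenotic", "stenotic"))
  # every record is zero-mean with N = fs * duration samples
  expect_lt(max(abs(rowMeans(ds$signals))), 1e-12 * max(abs(ds$signals)))
  # regenerating with the same seed reproduces records and manifest exactly
  ds2 <- generate_dataset(n_healthy = 2, n_stenotic = 2, seed = 42L)
  expect_identical(ds$signals, ds2$signals)
  expect_identical(ds$manifest, ds2$manifest)
  # empty request
  e <- generate_dataset(0, 0)
  expect_equal(nrow(e$signals), 0)
})
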