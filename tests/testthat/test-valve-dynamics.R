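# a minimal one-element "leaflet" for hand quadrature: a single flat
# right triangle pair... here one triangle of area 1 m^2 with b.n = 1 m
one_element_geometry <- function() {
  x_close <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  structure(list(
    x_close = x_close,
    x_open = x_close + matrix(c(0, 0, 1), 3, 3, byrow = TRUE), # b = +z
    b = cbind(0, 0, c(1, 1, 1)),
    node_leaflet = rep(1L, 3), node_s = c(0.5, 0.5, 0.5),
    tri = matrix(1:3, 1), tri_leaflet = 1L,
    normals = matrix(c(0, 0, 1), 1), ds = 1,
    free_edge = list(1L), radius = 1, leaflet_length = 1,
    axis = c(0, 0, 1), origin = c(0, 0, 0), n_leaflets = 1L
  ), class = "valve_geometry")
}

test_that("lumped forces vanish at rest and follow hand quadrature", {
  g <- default_geometry()
  lin <- valve_mapping("linear")
  p <- valve_params()
  ff <- lumped_forces(g, lin, p, c = rep(0, 3), dcdt = rep(0, 3), dp = 0)
  expect_equal(ff$F_P, rep(0, 3))
  expect_equal(ff$F_S, rep(0, 3))
  expect_equal(ff$F_mV, rep(0, 3))
  expect_true(all(ff$denominator > 0))
  # linear mapping: the nonlinear inertial force is identically zero
  ff2 <- lumped_forces(g, lin, p, c = c(0.3, 0.7, 0.5), dcdt = rep(5, 3),
                       dp = 100)
  expect_equal(ff2$F_mV, rep(0, 3))
  # one flat unit-area element with b.n = 1 m, c = 0.1:
  # F_S = kappa * (xi - xi0) * b.n * ds = 10600 * 0.1 * 1 = 1060 N
  g1 <- one_element_geometry()
  p1 <- valve_params(stiffness_multipliers = 1)
  f1 <- lumped_forces(g1, lin, p1, c = 0.1, dcdt = 0, dp = 0)
  expect_equal(f1$F_S, 1060)
  # and F_P is the plain pressure integral
  f2 <- lumped_forces(g1, lin, p1, c = 0.1, dcdt = 0, dp = 50)
  expect_equal(f2$F_P, 50)
})

test_that("unforced valve at rest stays stationary", {
  g <- default_geometry()
  traj <- integrate_valve(g, valve_mapping("linear"), valve_params(),
                          function(t) 0, t_span = c(0, 0.05))
  expect_equal(max(abs(traj$c)), 0)
  expect_equal(max(abs(traj$dcdt)), 0)
})

test_that("constant-load linear trajectory matches the closed-form oscillator", {
  g <- default_geometry()
  lin <- valve_mapping("linear")
  p <- valve_params() # alpha = 40, kappa = 10600 -> omega0 = sqrt(265)
  dp0 <- 20 # Pa, small enough that c never clamps
  traj <- integrate_valve(g, lin, p, function(t) dp0, t_span = c(0, 0.5),
                          dt = 1e-4)
  S <- sum(g$ds[g$tri_leaflet == 1])
  tabs <- stethosim:::element_tables(g)
  B <- sum(tabs[[1]]$bn_ds)
  c_eq <- dp0 * S / (p$kappa * B)
  w0 <- sqrt(p$kappa / p$alpha)
  expect_equal(w0, sqrt(265))
  c_exact <- c_eq * (1 - cos(w0 * traj$time))
  expect_lt(max(abs(traj$c[, 1] - c_exact)) / max(c_exact), 1e-4)
})

test_that("RK4 self-convergence is at least fourth order", {
  g <- default_geometry()
  lin <- valve_mapping("linear")
  p <- valve_params()
  dp <- function(t) 30 * sin(2 * pi * 3 * t) + 20
  sol <- function(dt) {
    tr <- integrate_valve(g, lin, p, dp, t_span = c(0, 0.1), dt = dt)
    tr$c[nrow(tr$c), 1]
  }
  ref <- sol(1.25e-5)
  e1 <- abs(sol(1e-4) - ref)
  e2 <- abs(sol(5e-5) - ref)
  # order-4 scheme: halving dt cuts the error by ~16; allow margin
  expect_gt(e1 / e2, 8)
})

test_that("displacement stays clamped in [0,1] under extreme forcing", {
  g <- default_geometry()
  p <- valve_params()
  # huge oscillating load slams the leaflets into both stops
  traj <- integrate_valve(g, valve_mapping("linear"), p,
                          function(t) 5e4 * sin(2 * pi * 10 * t),
                          t_span = c(0, 0.3))
  expect_true(all(traj$c >= 0 & traj$c <= 1))
  expect_equal(max(traj$c), 1)
  expect_equal(min(traj$c), 0)
})

test_that("stiffening one leaflet does not increase its peak displacement", {
  g <- default_geometry()
  lin <- valve_mapping("linear")
  dp <- function(t) 60 * sin(pi * t / 0.35) * (t < 0.35)
  peaks <- sapply(c(1, 2, 5, 10), function(m) {
    p <- valve_params(stiffness_multipliers = c(m, 1, 1))
    traj <- integrate_valve(g, lin, p, dp, t_span = c(0, 0.4))
    max(traj$c[, 1])
  })
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("kinematic events are detected from analytic test signals", {
  # synthetic trajectory: c(t) = sin(pi t / T) on [0, T]
  T <- 0.4
  tt <- seq(0, T, by = 1e-4)
  c1 <- sin(pi * tt / T)
  traj <- structure(list(time = tt,
                         c = cbind(c1, c1, c1),
                         dcdt = cbind(cos(pi * tt / T), cos(pi * tt / T),
                                      cos(pi * tt / T)) * pi / T),
                    class = "valve_trajectory")
  ev <- detect_events(traj)
  expect_equal(ev$reversal, rep(T / 2, 3), tolerance = 1e-3)
  expect_equal(ev$closure, rep(T, 3), tolerance = 1e-2)
  expect_equal(ev$halfway, rep(T * 5 / 6, 3), tolerance = 1e-2)
  # identical leaflets -> identical (synchronous) event times
  expect_equal(ev$closure[1], ev$closure[2])
  # monotone non-decreasing c: no reversal, no closure
  c2 <- seq(0, 1, length.out = length(tt))
  traj2 <- structure(list(time = tt, c = cbind(c2, c2, c2),
                          dcdt = matrix(1 / T, length(tt), 3)),
                     class = "valve_trajectory")
  ev2 <- detect_events(traj2)
  expect_true(all(is.na(ev2$reversal)))
  expect_true(all(is.na(ev2$closure)))
  # a leaflet that never opens reports absent events, not an error
  traj3 <- structure(list(time = tt, c = matrix(0.001, length(tt), 3),
                          dcdt = matrix(0, length(tt), 3)),
                     class = "valve_trajectory")
  ev3 <- detect_events(traj3)
  expect_true(all(is.na(ev3$reversal)))
})
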