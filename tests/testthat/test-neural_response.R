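# Small helper: a drive_series built directly (bypasses the field solve)
make_drive <- function(ve, dt, waveform = NULL) {
  structure(list(ve = ve, dt = dt,
                 times = (seq_len(ncol(ve)) - 1) * dt,
                 waveform = waveform, phi_nodes = NULL),
            class = "drive_series")
}

ref_cable <- function() cable_params(c_m = 1.4e-12, g_a = 6.4e-8,
                                     g_m = 2.1e-8)

test_that("node positions are collinear, centred and at the fiber depth", {
  lay <- electrode_centers(electrode_config(3.5, 1.0))
  f <- fiber_geometry(n_nodes = 21, internode_mm = 0.9, depth_mm = 0.8)
  pos <- node_positions(f, lay)
  expect_equal(nrow(pos), 21)
  expect_equal(diff(range(pos[, "x"])), 18.0)
  expect_equal(unname(pos[11, "x"]), 0)      # middle node under the centroid
  expect_equal(unname(pos[11, "y"]), 0)
  expect_true(all(pos[, "z"] == 0.8))
  expect_error(fiber_geometry(depth_mm = 2.0), "dermis")
  expect_error(fiber_geometry(n_nodes = 6), "n_nodes")
})

test_that("extracellular drive scales with the waveform and flips with polarity", {
  s <- training_subjects()[[1]]
  qc <- quick_run_config()
  grid <- build_grid(fingertip_model(s, qc), electrode_config(3.0, 1.0),
                     qc$solver)
  p <- solve_potential(grid, 3L, current_mA = 1)
  fib <- fiber_geometry(n_nodes = 9, depth_mm = 0.8)
  nodes <- node_positions(fib, grid$layout)
  wf0 <- biphasic_waveform(100, amplitude_ma = 0, window_us = 400)
  expect_true(all(extracellular_drive(p, nodes, wf0)$ve == 0))
  wf1 <- biphasic_waveform(100, amplitude_ma = 1, window_us = 400)
  wf2 <- biphasic_waveform(100, amplitude_ma = 2, window_us = 400)
  d1 <- extracellular_drive(p, nodes, wf1)
  d2 <- extracellular_drive(p, nodes, wf2)
  expect_equal(d2$ve, 2 * d1$ve, tolerance = 1e-12)
  # cathodic phase: Ve at the node under the active disc is negative and is
  # the extremum along the fiber, so the activating second difference
  # depolarizes there
  tcat <- 10   # a sample inside the first (cathodic) phase
  ve_cat <- d1$ve[, tcat]
  ctr <- 5     # middle node sits under the active (central) electrode
  expect_lt(ve_cat[ctr], 0)
  expect_gt(ve_cat[ctr - 1] - 2 * ve_cat[ctr] + ve_cat[ctr + 1], 0)
  expect_error(biphasic_waveform(5), "device range")
})

test_that("zero drive from rest stays at rest", {
  d <- make_drive(matrix(0, 5, 200), dt = 1e-7)
  tr <- integrate_cable(ref_cable(), d)
  expect_true(all(tr$v == 0))
  nf <- neural_features(tr)
  expect_equal(nf$v_peak_mv, -70)
  expect_false(nf$activated)
})

test_that("an isolated node relaxes with the membrane time constant", {
  # Ga effectively zero: pure RC decay exp(-t Gm/Cm) from the initial state
  p <- cable_params(c_m = 1.4e-12, g_a = 1e-30, g_m = 2.1e-8)
  tau <- p$c_m / p$g_m
  dt <- tau / 200
  d <- make_drive(matrix(0, 1, 400), dt = dt)
  tr <- integrate_cable(p, d, v0 = 0.01)
  expect_equal(tr$v[1, ], 0.01 * exp(-tr$times / tau), tolerance = 1e-8)
})

test_that("steady state under constant drive matches the dense equilibrium solve", {
  p <- ref_cable()
  nn <- 5
  ve_profile <- c(-0.2, -0.6, -1.0, -0.6, -0.2)   # V, cathodic-like dip
  tau <- p$c_m / (p$g_m + 2 * p$g_a)
  dt <- 0.05 * tau
  nt <- 4000                                       # ~200 tau: equilibrated
  d <- make_drive(matrix(ve_profile, nn, nt), dt = dt)
  tr <- integrate_cable(p, d)
  # oracle: Gm V = Ga L (V + Ve) with sealed-end second-difference L
  L <- matrix(0, nn, nn)
  for (i in 2:(nn - 1)) { L[i, i - 1] <- 1; L[i, i] <- -2; L[i, i + 1] <- 1 }
  L[1, 1] <- -1; L[1, 2] <- 1; L[nn, nn] <- -1; L[nn, nn - 1] <- 1
  v_eq <- solve(p$g_m * diag(nn) - p$g_a * L, p$g_a * L %*% ve_profile)
  expect_equal(tr$v[, nt], as.numeric(v_eq), tolerance = 1e-6)
})

test_that("trajectories match a high-accuracy dense ODE oracle on 5 nodes", {
  p <- ref_cable()
  nn <- 5
  tau <- p$c_m / (p$g_m + 2 * p$g_a)
  dt <- 0.02 * tau
  nt <- 1500
  times <- (seq_len(nt) - 1) * dt
  # smooth drive so both integrators see the same continuous input
  profile <- c(-0.1, -0.5, -1.2, -0.5, -0.1)
  freq <- 1 / (100 * tau)
  ve <- outer(profile, sin(2 * pi * freq * times))
  tr <- integrate_cable(p, make_drive(ve, dt))
  L <- matrix(0, nn, nn)
  for (i in 2:(nn - 1)) { L[i, i - 1] <- 1; L[i, i] <- -2; L[i, i + 1] <- 1 }
  L[1, 1] <- -1; L[1, 2] <- 1; L[nn, nn] <- -1; L[nn, nn - 1] <- 1
  rhs <- function(t, y, parms) {
    ve_t <- profile * sin(2 * pi * freq * t)
    list((p$g_a * L %*% (y + ve_t) - p$g_m * y) / p$c_m)
  }
  sol <- deSolve::lsoda(rep(0, nn), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-14)
  ref <- t(sol[, -1])
  expect_lt(max(abs(tr$v - ref)) / max(abs(ref)), 1e-6)
})

test_that("drive linearity carries through the passive cable", {
  p <- ref_cable()
  tau <- p$c_m / (p$g_m + 2 * p$g_a)
  ve <- outer(c(-0.1, -0.4, -0.1), rep(c(1, 0), each = 100))
  d1 <- make_drive(ve, dt = 0.05 * tau)
  d3 <- make_drive(3 * ve, dt = 0.05 * tau)
  t1 <- integrate_cable(p, d1)
  t3 <- integrate_cable(p, d3)
  expect_equal(t3$v, 3 * t1$v, tolerance = 1e-10)
})

test_that("stability margin is enforced and divergence impossible below it", {
  p <- ref_cable()
  dt_max <- 0.1 * p$c_m / (p$g_m + 2 * p$g_a)
  d_bad <- make_drive(matrix(0, 3, 10), dt = 2 * dt_max)
  expect_error(integrate_cable(p, d_bad), "stability margin")
})

test_that("peak features report the absolute potential and threshold crossing", {
  p <- ref_cable()
  # manufactured trajectory: deviation peaks at 15 mV = exactly threshold
  tr <- structure(list(v = matrix(c(0, 0.005, 0.015, 0.010), 1),
                       times = (0:3) * 1e-5, params = p, dt = 1e-5),
                  class = "cable_trajectory")
  nf <- neural_features(tr, p)
  expect_equal(nf$v_peak_mv, -55)
  expect_true(nf$activated)      # >= convention at the boundary
  expect_equal(nf$t_peak_s, 2e-5)
})

test_that("a single cathodic phase peaks at or after the phase end", {
  p <- ref_cable()
  tau <- p$c_m / (p$g_m + 2 * p$g_a)
  dt <- 0.05 * tau
  pw_s <- 1e-4
  npw <- round(pw_s / dt)
  # monophasic cathodic rectangle then off
  ve_profile <- c(-0.1, -0.5, -1.0, -0.5, -0.1)
  ve <- outer(ve_profile, c(rep(1, npw), rep(0, 3 * npw)))
  tr <- integrate_cable(p, make_drive(ve, dt))
  nf <- neural_features(tr)
  expect_gte(nf$t_peak_s, pw_s - dt)
})

test_that("halving the step changes the peak by well under 0.5%", {
  p <- ref_cable()
  tau <- p$c_m / (p$g_m + 2 * p$g_a)
  peak_at <- function(dt) {
    nper <- round(1e-4 / dt)
    ve <- outer(c(-0.1, -0.5, -1.0, -0.5, -0.1),
                c(rep(1, nper), rep(-1, nper), rep(0, nper)))
    max(integrate_cable(p, make_drive(ve, dt))$v)
  }
  v1 <- peak_at(0.08 * tau)
  v2 <- peak_at(0.04 * tau)
  expect_lt(abs(v1 - v2) / v2, 0.005)
})

test_that("derived cable constants follow the stated geometric formulas", {
  fib <- fiber_geometry()
  cp <- derive_cable_params(fib)
  d <- 9e-6; L <- 0.9e-3; gap <- 2.5e-6
  expect_equal(cp$g_a, pi * d^2 / (4 * 1.1 * L), tolerance = 1e-12)
  expect_equal(cp$c_m, 0.02 * pi * d * gap, tolerance = 1e-12)
  expect_equal(cp$g_m, 304 * pi * d * gap, tolerance = 1e-12)
  expect_equal(cp$v_rest, -70)
  expect_equal(cp$v_th, -55)
})
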