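test_that("homogeneous slab under a full-face plate gives a uniform vertical field", {
  sig <- 0.2; d_mm <- 5
  g <- make_slab_grid(sig, d_mm, 10, nx = 5, ny = 5)
  I_mA <- 1
  p <- solve_potential(g, active = "full_face", current_mA = I_mA)
  J <- I_mA * 1e-3 / (25 * 1e-6)        # A/m^2 over the 5 x 5 mm face
  E_expect <- J / sig
  f <- electric_field(p)
  # interior cells: uniform vertical field J/sigma, no lateral component
  expect_equal(max(abs(f$ex)), 0, tolerance = 1e-9 * E_expect)
  expect_equal(max(abs(f$ey)), 0, tolerance = 1e-9 * E_expect)
  # z increases with depth, so the field (high -> low potential) is +z
  inner <- f$ez[, , 2:9]
  expect_equal(mean(inner), E_expect, tolerance = 1e-6)
  expect_lt(diff(range(inner)) / E_expect, 1e-9)
  # potential profile is linear in depth; field points high -> low potential
  expect_gt(p$phi[3, 3, 1], p$phi[3, 3, 10])
  V_expect <- J * (d_mm * 1e-3) / sig
  expect_equal(max(p$phi), V_expect - J / sig * g$dz[10] / 2 * 1e-3,
               tolerance = 1e-6)
})

test_that("two-layer series slab matches the 1-D closed form within 2%", {
  # sigma 0.1 / 0.2 S/m, 2.5 mm each; drive chosen so the applied potential
  # across the 5 mm stack is 1 V: J = 1 / (t1/s1 + t2/s2) = 26.667 A/m^2
  g <- make_slab_grid(c(0.1, 0.2), c(2.5, 2.5), c(8, 8), nx = 4, ny = 4)
  J <- 1 / (2.5e-3 / 0.1 + 2.5e-3 / 0.2)
  area_m2 <- 16 * 1e-6
  p <- solve_potential(g, "full_face", current_mA = J * area_m2 * 1e3)
  f <- electric_field(p)
  E1 <- abs(f$ez[2, 2, 3])              # inside layer 1
  E2 <- abs(f$ez[2, 2, 14])             # inside layer 2
  expect_equal(E1, 266.6667, tolerance = 0.02)
  expect_equal(E2, 133.3333, tolerance = 0.02)
  # current continuity across the interface: s1 E1 = s2 E2
  expect_equal(0.1 * E1, 0.2 * E2, tolerance = 1e-6)
})

test_that("zero current yields an identically zero potential and features", {
  g <- make_slab_grid(c(0.1, 0.2), c(2.5, 2.5), c(4, 4), nx = 4, ny = 4)
  p <- solve_potential(g, "full_face", current_mA = 0)
  expect_true(all(p$phi == 0))
  f <- electric_field(p)
  ff <- extract_field_features(f, g, region = "all")
  expect_equal(ff$e_max, 0)
  expect_equal(ff$e_int, 0)
})

test_that("disc-source solve conserves current through every horizontal cut", {
  s <- training_subjects()[[1]]
  cfg <- electrode_config(3.0, 1.0)
  grid <- build_grid(fingertip_model(s, quick_run_config()), cfg,
                     quick_run_config()$solver)
  p <- solve_potential(grid, active = 3L, current_mA = 2)
  for (k in seq_len(length(grid$zc) - 1))
    expect_equal(plane_current_mA(p, k), 2, tolerance = 0.01)
})

test_that("the solve is linear in the injected current", {
  s <- training_subjects()[[2]]
  qc <- quick_run_config()
  grid <- build_grid(fingertip_model(s, qc), electrode_config(2.5, 1.5),
                     qc$solver)
  p1 <- solve_potential(grid, 3L, current_mA = 1)
  p2 <- solve_potential(grid, 3L, current_mA = 2)
  expect_equal(p2$phi, 2 * p1$phi, tolerance = 1e-8)
  f1 <- extract_field_features(electric_field(p1), grid)
  f2 <- extract_field_features(electric_field(p2), grid)
  expect_equal(f2$e_max, 2 * f1$e_max, tolerance = 1e-8)
  expect_equal(f2$e_avg, 2 * f1$e_avg, tolerance = 1e-8)
  expect_equal(f2$e_int, 2 * f1$e_int, tolerance = 1e-8)
})

test_that("gradient computation matches a brute-force loop oracle", {
  g <- make_slab_grid(0.3, 5, 5, nx = 5, ny = 5)
  fun <- function(x, y, z) 0.01 * x^2 - 0.02 * y * z + 0.005 * z^2 + 0.03 * x
  phi <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    phi[i, j, k] <- fun(g$xc[i], g$yc[j], g$zc[k])
  p <- structure(list(phi = phi, injected_current_mA = 1, residual = 0,
                      grid = g), class = "potential_field")
  f <- electric_field(p)
  # oracle: per-node central/one-sided differencing written as plain loops
  xm <- g$xc * 1e-3; ym <- g$yc * 1e-3; zm <- g$zc * 1e-3
  num_d <- function(vals, coords, idx) {
    n <- length(coords)
    if (idx == 1) (vals[2] - vals[1]) / (coords[2] - coords[1])
    else if (idx == n) (vals[n] - vals[n - 1]) / (coords[n] - coords[n - 1])
    else (vals[idx + 1] - vals[idx - 1]) / (coords[idx + 1] - coords[idx - 1])
  }
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_equal(f$ex[i, j, k], -num_d(phi[, j, k], xm, i), tolerance = 1e-10)
    expect_equal(f$ey[i, j, k], -num_d(phi[i, , k], ym, j), tolerance = 1e-10)
    expect_equal(f$ez[i, j, k], -num_d(phi[i, j, ], zm, k), tolerance = 1e-10)
  }
})

test_that("field features satisfy their definitional identities", {
  # equal conductivities: the field is uniform, but the grid still carries
  # two layer indices so the sub-corneum region is well defined
  g <- make_slab_grid(c(0.2, 0.2), c(1, 4), c(2, 8), nx = 4, ny = 4)
  p <- solve_potential(g, "full_face", current_mA = 0.5)
  f <- electric_field(p)
  ff_all <- extract_field_features(f, g, region = "all")
  expect_gte(ff_all$e_max, ff_all$e_avg)
  expect_gt(ff_all$e_avg, 0)
  # uniform-field region: Emax = Eavg = c and Eint = c * V
  ff2 <- extract_field_features(f, g, region = "below_stratum_corneum")
  vol2 <- sum((g$dx * 1e-3) * (g$dy * 1e-3) * (g$dz[g$layer_index >= 2] * 1e-3)) * 16
  expect_equal(ff2$e_max, ff2$e_avg, tolerance = 1e-6)
  expect_equal(ff2$e_int, ff2$e_avg * vol2, tolerance = 1e-6)
  expect_error(extract_field_features(f, g, region = "nowhere"), "region")
})

test_that("potential interpolation is nodal-exact and path-consistent", {
  g <- make_slab_grid(c(0.1, 0.2), c(2.5, 2.5), c(8, 8), nx = 4, ny = 4)
  J <- 1 / (2.5e-3 / 0.1 + 2.5e-3 / 0.2)
  p <- solve_potential(g, "full_face", current_mA = J * 16e-6 * 1e3)
  # exact at cell centres
  pts <- cbind(g$xc[2], g$yc[3], g$zc[c(2, 9, 14)])
  expect_equal(sample_potential(p, pts), p$phi[2, 3, c(2, 9, 14)],
               tolerance = 1e-12)
  # midpoint of a vertical edge inside the linear region
  mid <- (g$zc[3] + g$zc[4]) / 2
  expect_equal(sample_potential(p, cbind(g$xc[2], g$yc[2], mid)),
               mean(p$phi[2, 2, 3:4]), tolerance = 1e-12)
  # line-integral consistency: Phi(z) equals integral of -Ez from the
  # grounded face, here the series-resistance closed form
  z_test <- 1.0   # inside layer 1
  v_expect <- J * ((2.5 - z_test) * 1e-3 / 0.1 + 2.5e-3 / 0.2)
  got <- sample_potential(p, cbind(g$xc[2], g$yc[2], z_test))
  expect_equal(got, v_expect, tolerance = 0.02 * v_expect)
  expect_error(sample_potential(p, cbind(100, 0, 1)), "outside")
})

test_that("grid construction aligns layers and validates resolution", {
  s <- training_subjects()[[3]]
  qc <- quick_run_config()
  m <- fingertip_model(s, qc)
  g <- build_grid(m, electrode_config(3.0, 1.0), qc$solver)
  expect_equal(length(unique(as.vector(g$sigma))), 4)
  expect_equal(length(g$xc) * length(g$yc) * length(g$zc),
               length(g$sigma))
  # layer boundaries at identical depths when lateral resolution doubles
  res2 <- qc$solver; res2$dx_mm <- qc$solver$dx_mm / 2
  g2 <- build_grid(m, electrode_config(3.0, 1.0), res2)
  edges <- function(g) cumsum(c(0, g$dz))[cumsum(rle(g$layer_index)$lengths) + 1]
  expect_equal(edges(g), edges(g2))
  bad <- qc$solver; bad$layer_cells <- c(1L, 2L, 3L, 4L)
  expect_error(build_grid(m, electrode_config(3.0, 1.0), bad),
               "at least 2")
  # array too large for the extent
  tiny <- qc; tiny$solver$lateral_extent_mm <- c(10, 8)
  expect_error(build_grid(fingertip_model(s, tiny),
                          electrode_config(4.5, 3.0), tiny$solver),
               "exceeds lateral extent")
})

test_that("current outside the device range is rejected", {
  g <- make_slab_grid(0.2, 5, 4, nx = 4, ny = 4)
  expect_error(solve_potential(g, "full_face", current_mA = 11), "0-10 mA")
  expect_error(solve_potential(g, "full_face", current_mA = -1), "0-10 mA")
})
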