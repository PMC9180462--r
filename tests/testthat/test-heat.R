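test_that("stability limit matches the explicit-scheme bound", {
  g1 <- slab_grid(5, 5, 5, materials = simple_material())
  expect_equal(stable_timestep(g1, safety = 1), 4 / 3)
  # halving the voxel size quarters the admissible step
  g2 <- slab_grid(5, 5, 5, dx = 0.5, dy = 0.5, dz = 0.5,
                  materials = simple_material())
  expect_equal(stable_timestep(g2, safety = 1), 1 / 3)
  # a heterogeneous grid is limited by its most diffusive material
  mats <- dplyr::bind_rows(simple_material(name = "a"),
                           simple_material(k = 1, name = "b"))
  g3 <- slab_grid(5, 5, 6, materials = mats, split_z = 3)
  expect_lte(stable_timestep(g3, safety = 1), 4 / 3)
})

test_that("uniform field with zero source is a fixed point", {
  g <- slab_grid(6, 6, 6, materials = simple_material())
  f <- simulate_heat(g, config = adiabatic_config(10))
  expect_equal(max(abs(f$final - 37)), 0)
})

test_that("two-cell relaxation matches the hand-computed explicit update", {
  g <- slab_grid(1, 1, 2, materials = simple_material())
  T0 <- array(c(38, 36), c(1, 1, 2))
  dt <- 0.5
  T1 <- step_temperature(T0, g, dtau = dt, config = adiabatic_config(dt, dt))
  # conductance k*A/d = 0.5 * 1e-6 / 1e-3; c = dt/(rho cv V)
  flux <- 0.5 * 1e-6 / 1e-3 * (36 - 38)
  dT <- dt * flux / (1000 * 4000 * 1e-9)
  expect_equal(T1[1, 1, 1], 38 + dT)
  expect_equal(T1[1, 1, 2], 36 - dT)
  expect_equal(mean(T1), 37)
})

test_that("with conduction suppressed the source term heats a voxel linearly", {
  g <- slab_grid(3, 3, 3, materials = simple_material(k = 0))
  A <- array(0, c(3, 3, 3)); A[2, 2, 2] <- 0.4
  am <- structure(list(A = A), class = "absorption_map")
  dt <- 0.5; P <- 200  # mW
  T1 <- step_temperature(array(37, c(3, 3, 3)), g, absorption = am,
                         power = P, dtau = dt)
  dT_expect <- dt * 0.4 * P * 1e-3 / (1000 * 4000 * 1e-9)
  expect_equal(T1[2, 2, 2] - 37, dT_expect)
  expect_equal(T1[1, 1, 1], 37)
})

test_that("an unheated run stays at the initial temperature", {
  g <- coarse_treatment_grid(2)
  f <- simulate_heat(g, config = sim_config(duration = 10,
                                            snapshot_interval = 5, power = 0))
  expect_true(all(vapply(f$snapshots,
                         function(s) max(abs(s[inside_mask(g)] - 37)),
                         numeric(1)) == 0))
})

test_that("temperature rise is linear in the laser power", {
  g <- coarse_treatment_grid(2)
  am <- run_transport(g, beam_spec("gaussian", phi_r = 1, power = 1),
                      n_photons = 5000, seed = 21)
  f1 <- simulate_heat(g, am, sim_config(duration = 20, snapshot_interval = 20,
                                        power = 60), keep_snapshots = FALSE)
  f2 <- simulate_heat(g, am, sim_config(duration = 20, snapshot_interval = 20,
                                        power = 120), keep_snapshots = FALSE)
  r1 <- f1$final - 37; r2 <- f2$final - 37
  expect_lt(max(abs(r2 - 2 * r1)) / max(abs(r2)), 1e-9)
})

test_that("adiabatic no-source evolution conserves thermal energy over 1e4 steps", {
  g <- slab_grid(10, 10, 10, materials = simple_material())
  dt <- stable_timestep(g, safety = 0.9)
  set.seed(31)
  T0 <- array(runif(1000, 30, 60), c(10, 10, 10))
  dur <- 10000 * dt
  f <- simulate_heat(g, config = adiabatic_config(dur, dur, dt = dt),
                     initial = T0, keep_snapshots = FALSE)
  e0 <- thermal_energy(g, T0)
  expect_lt(abs(thermal_energy(g, f$final) - e0) / e0, 1e-9)
  # discrete maximum principle
  expect_gte(min(f$final), min(T0) - 1e-9)
  expect_lte(max(f$final), max(T0) + 1e-9)
})

test_that("a point release relaxes to the 3-D heat kernel", {
  tum <- tumor_baseline()
  n <- 41; vox <- 0.5
  g <- slab_grid(n, n, n, dx = vox, dy = vox, dz = vox, materials = tum)
  rcv <- tum$rho * tum$cv; V <- (vox * 1e-3)^3
  Q <- 0.5  # J
  T0 <- array(37, c(n, n, n)); T0[21, 21, 21] <- 37 + Q / (rcv * V)
  tau <- 10
  f <- simulate_heat(g, config = adiabatic_config(tau, tau, safety = 0.5),
                     initial = T0, keep_snapshots = FALSE)
  expect_gt(tau / f$dt, 20)
  for (off in 1:4) {
    r <- off * vox * 1e-3
    ana <- heat_kernel_rise(Q, r, tau, tum$k, tum$rho, tum$cv)
    expect_lt(abs((f$final[21 + off, 21, 21] - 37) / ana - 1), 0.02)
  }
})

test_that("bilayer steady state reproduces the series-resistance profile", {
  mats <- dplyr::bind_rows(simple_material(k = 0.2, name = "m1"),
                           simple_material(k = 0.6, name = "m2"))
  n <- 12
  col <- slab_grid(1, 1, 2 * n, materials = mats, split_z = n)
  cfg <- sim_config(duration = 4000, snapshot_interval = 4000, power = 0,
                    top = 57, lateral = "adiabatic", bottom = 37,
                    initial = 47)
  f <- simulate_heat(col, config = cfg, keep_snapshots = FALSE)
  d <- (1:(2 * n)) * 1e-3  # node depth from the hot wall (ghost nodes fixed)
  ana <- bilayer_interface_profile(d, L1 = (n + 0.5) * 1e-3,
                                   L2 = (n + 0.5) * 1e-3,
                                   k1 = 0.2, k2 = 0.6, T_hot = 57, T_cold = 37)
  expect_lt(max(abs(f$final[1, 1, ] - ana) / abs(ana)), 0.005)
})

test_that("an unstable time step aborts with a diagnostic", {
  g <- slab_grid(6, 6, 6, materials = simple_material())
  dt_bad <- 4 * stable_timestep(g, safety = 1)
  expect_error(
    simulate_heat(g, config = adiabatic_config(500 * dt_bad, 500 * dt_bad,
                                               dt = dt_bad),
                  initial = array(runif(216, 30, 60), c(6, 6, 6))),
    "stability"
  )
})
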