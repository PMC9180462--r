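# Coarse working point for unit tests: 1 mm voxels keep a full 600 s
# condition under a second while exercising the whole pipeline.
coarse_preset <- function() {
  list(name = "coarse", dx = 1, dy = 1, dz = 1,
       n_photons = 1e4, snapshot_interval = 10, safety = 0.9)
}

test_that("optimum search honours the metric direction and tie-breaks", {
  toy <- tibble::tibble(
    profile = "gaussian", phi_r = c(1, 1, 0.5, 1.5), f_v = 1e-6,
    P_l = c(10, 20, 30, 40),
    theta_eff_star = c(0.1, 0.3, 0.3, 0.2),
    theta_A_star = c(0.2, 0.5, 0.5, 0.4),
    theta_H_star = c(1.1, 1.2, 1.2, 1.3)
  )
  expect_equal(find_optimum(toy, "theta_eff_star")$P_l, 20)  # tie -> lower power
  expect_equal(find_optimum(toy, "theta_H_star")$P_l, 10)    # argmin
  expect_error(find_optimum(toy, "theta_eff_star", profile = "top_hat"),
               "no sweep rows")
})

test_that("a sweep cell reports consistent, reproducible metrics", {
  grid <- coarse_treatment_grid(1)
  pre <- coarse_preset()
  rc <- run_condition("gaussian", 1, 1e-6, power = c(0, 50, 100, 150, 200),
                      preset = pre, grid = grid, seed = 77)
  # zero power leaves the tissue unheated
  expect_equal(rc$theta_A_star[1], 0)
  expect_equal(rc$theta_H_star[1], 1)
  expect_equal(rc$peak_center_temp[1], 37)
  # the effective ratio is exactly the quotient of the starred metrics
  expect_identical(rc$theta_eff_star,
                   ifelse(rc$P_l == 0, 0, rc$theta_A_star / rc$theta_H_star))
  # collateral damage cannot decrease with laser power
  expect_true(all(diff(rc$theta_H_star) >= 0))
  expect_true(all(diff(rc$peak_center_temp) > 0))
  rc2 <- run_condition("gaussian", 1, 1e-6, power = c(0, 50, 100, 150, 200),
                       preset = pre, grid = grid, seed = 77)
  expect_identical(rc, rc2)
})

test_that("a single-cell sweep matches the standalone condition pipeline", {
  grid <- coarse_treatment_grid(1)
  pre <- coarse_preset()
  sw <- run_sweep(sweep_grid(profiles = "gaussian", phi_r = 1,
                             power = c(0, 100, 200), f_v = 1e-6),
                  preset = pre, grid = grid, master_seed = 4)
  direct <- run_condition("gaussian", 1, 1e-6, power = c(0, 100, 200),
                          preset = pre, grid = grid, seed = 4 + 1000)
  for (col in names(direct)) expect_identical(sw[[col]], direct[[col]])
  best <- find_optimum(sw, "theta_eff_star")
  expect_identical(best$theta_eff_star, max(sw$theta_eff_star))
})

test_that("sweep metrics agree with the double-precision scoring route", {
  grid <- coarse_treatment_grid(1)
  pre <- coarse_preset()
  rc <- run_condition("gaussian", 1, 1e-6, power = 100, preset = pre,
                      grid = grid, seed = 11)
  gc2 <- apply_nanoparticles(grid, nanoparticle_spec(1e-6))
  am <- run_transport(gc2, beam_spec("gaussian", phi_r = 1, power = 100),
                      n_photons = pre$n_photons, seed = 11)
  fld <- simulate_heat(gc2, am, sim_config(duration = 600,
                                           snapshot_interval = 10,
                                           power = 100))
  sm <- summarize_metrics(score_snapshots(fld, gc2))
  # single-precision rise field vs double-precision absolute field
  expect_equal(rc$theta_A_star, sm$theta_A_star, tolerance = 1e-3)
  expect_equal(rc$theta_H_star, sm$theta_H_star, tolerance = 1e-3)
  expect_equal(rc$peak_center_temp, max(fld$trace$temperature),
               tolerance = 1e-4)
})

test_that("power scaling reproduces a directly simulated double-power run", {
  grid <- coarse_treatment_grid(2)
  gc2 <- apply_nanoparticles(grid, nanoparticle_spec(1e-5))
  am <- run_transport(gc2, beam_spec("gaussian", phi_r = 1, power = 1),
                      n_photons = 5000, seed = 23)
  fP <- simulate_heat(gc2, am, sim_config(duration = 30, snapshot_interval = 30,
                                          power = 70), keep_snapshots = FALSE)
  f2P <- simulate_heat(gc2, am, sim_config(duration = 30, snapshot_interval = 30,
                                           power = 140), keep_snapshots = FALSE)
  rel <- max(abs((f2P$final - 37) - 2 * (fP$final - 37))) / max(f2P$final - 37)
  expect_lt(rel, 1e-9)
})

test_that("centre traces respond to power and stay flat unheated", {
  grid <- coarse_treatment_grid(1)
  pre <- coarse_preset()
  tr0 <- center_temperature_trace("gaussian", 1, 1e-6, power = 0,
                                  preset = pre, grid = grid, seed = 31)
  expect_true(all(tr0$temperature == 37))
  tr <- center_temperature_trace("gaussian", 1, 1e-6, power = 100,
                                 preset = pre, grid = grid, seed = 31)
  expect_true(all(diff(tr$temperature) >= 0))
  expect_gt(max(tr$temperature), 45)
})

test_that("sweep results expose tidy, glance and autoplot views", {
  grid <- coarse_treatment_grid(1)
  sw <- run_sweep(sweep_grid(profiles = "gaussian", phi_r = c(0.5, 1),
                             power = c(0, 100), f_v = 1e-6),
                  preset = coarse_preset(), grid = grid, master_seed = 8)
  td <- tidy(sw)
  expect_equal(nrow(td), 3 * nrow(sw))
  expect_true(all(c("metric", "value") %in% names(td)))
  gl <- glance(sw)
  expect_equal(gl$profile, "gaussian")
  expect_s3_class(autoplot(sw), "ggplot")
})
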