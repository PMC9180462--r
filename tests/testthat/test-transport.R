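test_that("deflection sampling evaluates the phase-function inverse CDF", {
  expect_equal(sample_deflection(0, 1), 1)
  expect_equal(sample_deflection(0, 0.25), -0.5)
  g <- 0.8
  tmp <- (1 - g^2) / (1 - g + 2 * g * 0.5)
  expect_equal(sample_deflection(g, 0.5), (1 + g^2 - tmp^2) / (2 * g))
  expect_true(all(abs(sample_deflection(0.99, runif(1000))) <= 1))
})

test_that("sampled mean scattering cosine matches the anisotropy factor", {
  set.seed(42)
  ct <- sample_deflection(0.9, runif(1e6))
  se <- sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - 0.9), 3 * se)
})

test_that("direction updates preserve unit norm and the deflection cosine", {
  # no deflection leaves the direction unchanged
  expect_equal(update_direction(c(0.6, 0, 0.8), 1, 2.2), c(0.6, 0, 0.8))
  # vertical special cases
  expect_equal(update_direction(c(0, 0, 1), 0, 0), c(1, 0, 0))
  d <- update_direction(c(0, 0, -1), 0.5, 1.3)
  expect_equal(d[3], -0.5)
  # random chains: norm drift and cosine preservation
  set.seed(7)
  dir <- c(0, 0, 1)
  worst_cos <- 0
  for (i in 1:10000) {
    ct <- sample_deflection(0.8, runif(1))
    nd <- update_direction(dir, ct, 2 * pi * runif(1))
    worst_cos <- max(worst_cos, abs(sum(dir * nd) - ct))
    dir <- nd
  }
  expect_lt(worst_cos, 1e-9)
  expect_lt(abs(sum(dir^2) - 1), 1e-6)
})

test_that("free-path sampling is exponential with mean 1/mu_tot", {
  expect_equal(sample_step(2, 1), 0)
  expect_equal(sample_step(2, exp(-1)), 0.5)
  set.seed(9)
  s <- sample_step(0.93, runif(1e5))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 0.93), 3 * se)
  expect_error(sample_step(0, 0.5), "positive")
})

test_that("weight deposition follows the single-scattering albedo", {
  d <- deposit_weight(1, 1, 4)
  expect_equal(d$delta_W, 0.25)
  expect_equal(d$W, 0.75)
  d2 <- deposit_weight(1, 0.047, 0.93)
  expect_equal(d2$delta_W, 0.047 / 0.93)
  expect_equal(deposit_weight(0.5, 0, 3)$delta_W, 0)
})

test_that("launch positions sample the beam's radial energy density", {
  set.seed(11)
  bg <- beam_spec("gaussian", radius = 2, power = 1)
  ph <- launch_photon(bg, 1e5)
  expect_true(all(ph$z == 0 & ph$mu_z == 1 & ph$weight == 1))
  r <- sqrt(ph$x^2 + ph$y^2)
  # encircled energy within the 1/e^2 radius
  p <- 1 - exp(-2)
  se <- sqrt(p * (1 - p) / length(r))
  expect_lt(abs(mean(r <= 2) - p), 3 * se)
  bt <- beam_spec("top_hat", radius = 2, power = 1)
  rt <- sqrt(rowSums(as.matrix(launch_photon(bt, 1e5)[, 1:2])^2))
  expect_true(all(rt <= 2))
  se_m <- 3 / sqrt(length(rt))  # generous bound on the median's error
  expect_lt(abs(median(rt) - 2 * sqrt(0.5)), se_m)
})

test_that("transport conserves energy and is seed-reproducible", {
  grid <- coarse_treatment_grid(1)
  beam <- beam_spec("gaussian", phi_r = 1, power = 100)
  a1 <- run_transport(grid, beam, n_photons = 5000, seed = 3)
  expect_lt(abs(sum(a1$A) + a1$escaped + a1$residual - 1), 1e-9)
  a2 <- run_transport(grid, beam, n_photons = 5000, seed = 3)
  expect_identical(a1$A, a2$A)
  expect_identical(a1$escaped, a2$escaped)
  expect_error(run_transport(grid, beam, n_photons = 0), "at least 1")
})

test_that("a transparent medium transmits every packet", {
  slab <- slab_grid(11, 11, 5, materials = simple_material(mu_a = 0, mu_s = 0))
  am <- run_transport(slab, beam_spec("top_hat", radius = 1, power = 1),
                      n_photons = 2000, seed = 5)
  expect_equal(sum(am$A), 0)
  expect_equal(am$escaped, 1)
})

test_that("a pure absorber reproduces exponential attenuation per depth bin", {
  mu_a <- 0.5; L <- 6
  slab <- slab_grid(15, 15, 12, dx = 1, dy = 1, dz = 0.5,
                    materials = simple_material(mu_a = mu_a))
  am <- run_transport(slab, beam_spec("top_hat", radius = 0.5, power = 1),
                      n_photons = 1e5, seed = 13)
  expect_lt(abs(sum(am$A) + am$escaped - 1), 1e-9)
  total_expect <- 1 - exp(-mu_a * L)
  se <- sqrt(total_expect * (1 - total_expect) / am$n_photons)
  expect_lt(abs(sum(am$A) - total_expect), 3 * se)
  # depth-resolved deposition against the Beer-Lambert profile (1 mm bins)
  dep <- apply(am$A, 3, sum)
  dep_bin <- colSums(matrix(dep, nrow = 2))
  zb <- seq(0, L, by = 1)
  expect_bin <- exp(-mu_a * utils::head(zb, -1)) - exp(-mu_a * utils::tail(zb, -1))
  n <- am$n_photons
  se_bin <- sqrt(expect_bin * (1 - expect_bin) / n)
  expect_true(all(abs(dep_bin - expect_bin) < 3.5 * se_bin))
})
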