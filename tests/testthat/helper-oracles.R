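# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: metrics are recomputed with explicit
# per-voxel loops and if-chains, quadrature with an explicit running sum.

oracle_metrics <- function(T, tumor, normal) {
  nt <- 0L; na <- 0L; nn <- 0L; wsum <- 0
  for (i in seq_along(T)) {
    Ti <- T[i]
    if (tumor[i]) {
      nt <- nt + 1L
      if (Ti >= 43 && Ti < 50) na <- na + 1L
    } else if (normal[i]) {
      nn <- nn + 1L
      w <- if (Ti < 43) 1 else if (Ti < 45) 2 else if (Ti < 50) 2 else
           if (Ti < 70) 3 else if (Ti < 80) 4 else if (Ti < 100) 5 else
           if (Ti < 150) 6 else if (Ti < 300) 7 else 8
      wsum <- wsum + w
    }
  }
  list(theta_A = na / nt, theta_H = wsum / nn)
}

oracle_trapz_mean <- function(v, t) {
  s <- 0
  for (i in 2:length(t)) s <- s + (t[i] - t[i - 1]) * (v[i] + v[i - 1]) / 2
  s / (t[length(t)] - t[1])
}

random_temperature_field <- function(dims, lo = 30, hi = 120) {
  array(runif(prod(dims), lo, hi), dims)
}

# disjoint random tumor / normal masks covering most of the field
random_masks <- function(dims) {
  u <- array(runif(prod(dims)), dims)
  list(tumor = u < 0.3, normal = u >= 0.3 & u < 0.9)
}

simple_material <- function(mu_a = 0.5, mu_s = 0, g = 0,
                            k = 0.5, cv = 4000, rho = 1000,
                            name = "medium") {
  tibble::tibble(name = name, k = k, cv = cv, rho = rho,
                 mu_a = mu_a, mu_s = mu_s, g = g)
}

adiabatic_config <- function(duration, snapshot_interval = duration,
                             safety = 0.9, dt = NULL, initial = 37) {
  sim_config(duration = duration, snapshot_interval = snapshot_interval,
             power = 0, top = "adiabatic", lateral = "adiabatic",
             bottom = "adiabatic", safety = safety, dt = dt,
             initial = initial)
}

coarse_treatment_grid <- function(voxel = 1) {
  suppressWarnings(build_treatment_domain(
    domain_spec(dx = voxel, dy = voxel, dz = voxel)
  ))
}
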