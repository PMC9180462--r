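#' Build the cross-study verification scenario
#'
#' The benchmark geometry used to verify the coupled transport + heat
#' pipeline: a homogeneous tissue cylinder of radius 30 mm and length
#' 30 mm with a 5 mm spherical tumor at its centre, irradiated for 800 s
#' at 1.7 W with a beam of radius 5 or 15 mm. The original study's
#' temperature curves are not redistributable, so the fixture checks
#' internal properties (monotone heating, radius ordering) and exports
#' the centre trace for manual comparison. Tissue properties default to
#' the tumor medium; the benchmark's own property set is unpublished.
#'
#' @param laser_radius Beam radius, 5 or 15 mm.
#' @param voxel Voxel size (mm); the default keeps the scenario
#'   desk-scale.
#' @param power Laser power (mW).
#' @param duration Irradiation time (s).
#' @param profile Beam profile; the benchmark irradiates a fixed-radius
#'   spot, modelled as a top-hat by default.
#' @param tissue Homogeneous tissue property row.
#' @return A `fixture_case` (name, domain spec, beam, solver config).
#' @export
make_crochet_case <- function(laser_radius = c(5, 15), voxel = 1,
                              power = 1700, duration = 800,
                              profile = "top_hat", tissue = tumor_baseline()) {
  laser_radius <- match.arg(as.character(laser_radius[1]), c("5", "15"))
  laser_radius <- as.numeric(laser_radius)
  structure(
    list(
      name = sprintf("crochet_r%g", laser_radius),
      domain = validation_domain_spec(voxel = voxel, tissue = tissue),
      beam = beam_spec(profile, radius = laser_radius, power = power),
      config = sim_config(duration = duration, snapshot_interval = 4,
                          power = power),
      expected = "centre-temperature trace monotone non-decreasing under continuous irradiation"
    ),
    class = "fixture_case"
  )
}

#' Run a fixture scenario end to end
#'
#' Builds the domain, runs transport and the heat solver, and returns the
#' centre-voxel temperature trace.
#'
#' @param case A `fixture_case` from [make_crochet_case()].
#' @param n_photons Photon packets for the transport stage.
#' @param seed Transport seed.
#' @return A tibble with columns `time` and `temperature`.
#' @export
run_fixture <- function(case, n_photons = 2e4, seed = 1) {
  stopifnot(inherits(case, "fixture_case"))
  grid <- build_validation_domain(case$domain)
  absorption <- run_transport(grid, case$beam, n_photons = n_photons,
                              seed = seed)
  field <- simulate_heat(grid, absorption, case$config,
                         keep_snapshots = FALSE)
  field$trace
}

#' Analytic oracle scenarios
#'
#' Closed-form benchmarks exercised by the test suite, each pairing a
#' small simulation setup with the analytic expectation:
#' Beer-Lambert attenuation in a pure absorber, the 3-D heat kernel for a
#' point release, and the series-resistance steady state of a two-layer
#' slab. Randomized metric fields (scored against a brute-force voxel
#' loop) complete the set.
#'
#' @return A named list of descriptors (`name`, `tolerance`, parameters).
#' @export
make_analytic_oracles <- function() {
  list(
    beer_lambert = list(
      name = "beer_lambert", tolerance = "3 standard errors",
      mu_a = 0.5, depth = 6, n_photons = 1e6,
      expected = function(mu_a, L) 1 - exp(-mu_a * L)
    ),
    heat_kernel = list(
      name = "heat_kernel", tolerance = "2% relative on interior rises",
      voxel = 0.5, n = 41, tau = 10, material = tumor_baseline(),
      expected = heat_kernel_rise
    ),
    bilayer = list(
      name = "bilayer_steady_state", tolerance = "0.5% on node temperatures",
      k1 = 0.2, k2 = 0.6, n_per_layer = 12,
      expected = bilayer_interface_profile
    ),
    metric_fields = list(
      name = "metric_brute_force", tolerance = "exact",
      dims = c(20, 20, 20), n_fields = 100, temp_range = c(30, 120)
    )
  )
}

#' Temperature rise of an instantaneous point heat release
#'
#' 3-D heat-kernel solution in an infinite homogeneous medium:
#' `dT(r, tau) = Q / (rho cv (4 pi alpha tau)^{3/2}) exp(-r^2 / (4 alpha tau))`.
#'
#' @param Q Released energy (J).
#' @param r Distance(s) from the release point (m).
#' @param tau Elapsed time (s).
#' @param k,rho,cv Conductivity, density, specific heat (SI).
#' @return Temperature rise(s) in K.
#' @export
heat_kernel_rise <- function(Q, r, tau, k, rho, cv) {
  alpha <- k / (rho * cv)
  Q / (rho * cv * (4 * pi * alpha * tau)^1.5) * exp(-r^2 / (4 * alpha * tau))
}

#' Steady-state profile of a two-layer slab between fixed temperatures
#'
#' Piecewise-linear conduction solution with flux continuity: the
#' interface temperature follows from the series thermal resistances
#' `L1/k1` and `L2/k2`. Evaluated at arbitrary depths between the two
#' fixed walls.
#'
#' @param z Depth(s) from the hot wall (m).
#' @param L1,L2 Layer thicknesses (m), layer 1 adjacent to the hot wall.
#' @param k1,k2 Conductivities (W/(m K)).
#' @param T_hot,T_cold Wall temperatures (degC).
#' @return Temperature(s) at `z`.
#' @export
bilayer_interface_profile <- function(z, L1, L2, k1, k2, T_hot, T_cold) {
  q <- (T_hot - T_cold) / (L1 / k1 + L2 / k2)  # flux, W/m^2
  ifelse(z <= L1, T_hot - q * z / k1,
         T_hot - q * L1 / k1 - q * (z - L1) / k2)
}
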