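#' Specify a laser beam
#'
#' The beam enters the tissue at `z = 0` travelling along +z. For a
#' Gaussian profile `radius` is the 1/e^2 intensity radius; for a top-hat
#' profile it is the hard edge. The radius may alternatively be given as
#' the radius ratio `phi_r` (beam radius / tumor radius).
#'
#' @param profile `"gaussian"` or `"top_hat"`.
#' @param radius Beam radius (mm); computed from `phi_r` when `NULL`.
#' @param phi_r Radius ratio of the beam to the tumor.
#' @param tumor_radius Tumor radius used to resolve `phi_r` (mm).
#' @param power Laser power `P_l` (mW).
#' @return An object of class `beam_spec`.
#' @export
#' @examples
#' beam_spec("gaussian", phi_r = 1, power = 100)
beam_spec <- function(profile = c("gaussian", "top_hat"), radius = NULL,
                      phi_r = NULL, tumor_radius = 5, power = 100) {
  profile <- match.arg(profile)
  if (is.null(radius)) {
    if (is.null(phi_r)) abort("give either radius or phi_r")
    radius <- phi_r * tumor_radius
  } else if (is.null(phi_r)) {
    phi_r <- radius / tumor_radius
  }
  if (radius <= 0) abort("beam radius must be positive")
  if (power < 0) abort("laser power must be non-negative")
  structure(
    list(profile = profile, radius = radius, phi_r = phi_r, power = power),
    class = "beam_spec"
  )
}

#' Sample the scattering deflection angle
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function:
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi))^2) / (2 g)` for
#' `g != 0`, and `2 xi - 1` for isotropic scattering. Results are clamped
#' to `[-1, 1]` against floating-point overshoot.
#'
#' @param g Anisotropy factor(s), `-1 < g < 1`.
#' @param xi Uniform variate(s) on (0, 1).
#' @return `cos(theta)`, vectorized over the longer argument.
#' @export
#' @examples
#' sample_deflection(0.8, 0.5)  # 0.944
sample_deflection <- function(g, xi) {
  n <- max(length(g), length(xi))
  g <- rep_len(g, n); xi <- rep_len(xi, n)
  ct <- ifelse(g == 0, 2 * xi - 1, {
    tmp <- (1 - g^2) / (1 - g + 2 * g * xi)
    (1 + g^2 - tmp^2) / (2 * g)
  })
  pmin(1, pmax(-1, ct))
}

#' Sample the azimuthal scattering angle
#'
#' @param xi Uniform variate(s) on `[0, 1)`.
#' @return `psi = 2 pi xi`, in `[0, 2 pi)`.
#' @export
sample_azimuth <- function(xi) 2 * pi * xi

#' Rotate a direction by a sampled scattering event
#'
#' Applies the standard direction-cosine update for a deflection
#' `cos(theta)` about the current direction with azimuth `psi`, switching
#' to the simplified axis-aligned form when the direction is within
#' `1e-6` of vertical. The result is renormalized to unit length.
#'
#' @param dir Length-3 direction cosines, or an `n x 3` matrix.
#' @param cos_theta Cosine(s) of the deflection angle.
#' @param psi Azimuth angle(s), radians.
#' @return Direction(s) with the same shape as `dir`.
#' @export
#' @examples
#' update_direction(c(0, 0, 1), cos_theta = 0, psi = 0)  # (1, 0, 0)
update_direction <- function(dir, cos_theta, psi) {
  v <- if (is.matrix(dir)) dir else matrix(dir, ncol = 3)
  n <- nrow(v)
  cos_theta <- rep_len(cos_theta, n); psi <- rep_len(psi, n)
  st <- sqrt(pmax(0, 1 - cos_theta^2))
  cp <- cos(psi); sp <- sin(psi)
  ux <- v[, 1]; uy <- v[, 2]; uz <- v[, 3]
  vert <- abs(uz) > 1 - 1e-6
  den <- sqrt(pmax(1e-300, 1 - uz^2))
  nx <- st * (ux * uz * cp - uy * sp) / den + ux * cos_theta
  ny <- st * (uy * uz * cp + ux * sp) / den + uy * cos_theta
  nz <- -st * cp * den + uz * cos_theta
  nx[vert] <- (st * cp)[vert]
  ny[vert] <- (st * sp)[vert]
  nz[vert] <- (sign(uz) * cos_theta)[vert]
  out <- cbind(nx, ny, nz, deparse.level = 0)
  out <- out / sqrt(rowSums(out^2))
  if (is.matrix(dir)) out else drop(out)
}

#' Sample a photon free-path length
#'
#' `S = -log(xi) / mu_tot`: exponentially distributed with mean
#' `1 / mu_tot`, the inverse of the total attenuation coefficient
#' `mu_tot = mu_a + mu_s`.
#'
#' @param mu_tot Total attenuation coefficient (1/mm), positive.
#' @param xi Uniform variate(s) on (0, 1].
#' @return Step length(s) in mm.
#' @export
sample_step <- function(mu_tot, xi) {
  if (any(mu_tot <= 0)) abort("mu_tot must be positive; void voxels are free flights handled by the caller")
  -log(xi) / mu_tot
}

#' Deposit the absorbed fraction of a packet's weight
#'
#' At each interaction the packet sheds `delta_W = W mu_a / mu_tot` into
#' the local voxel and continues with the remainder.
#'
#' @param W Packet weight(s) in `[0, 1]`.
#' @param mu_a,mu_tot Absorption and total attenuation coefficients (1/mm).
#' @return A tibble with columns `delta_W` and `W` (the remaining weight).
#' @export
#' @examples
#' deposit_weight(1, 0.047, 0.93)
deposit_weight <- function(W, mu_a, mu_tot) {
  stopifnot(all(mu_a <= mu_tot), all(mu_a >= 0))
  dW <- W * mu_a / mu_tot
  tibble::tibble(delta_W = dW, W = W - dW)
}

#' Launch photon packets from a beam
#'
#' Packets start at the surface (`z = 0`) travelling straight down with
#' unit weight. The radial launch position is sampled from the beam's
#' radial energy density: `r = radius / sqrt(2) * sqrt(-log(xi))` for the
#' 1/e^2 Gaussian, `r = radius * sqrt(xi)` for the top-hat; the azimuth is
#' uniform. Uses R's random number stream.
#'
#' @param beam A [beam_spec()].
#' @param n Number of packets.
#' @return A tibble with columns `x, y, z, mu_x, mu_y, mu_z, weight`.
#' @export
launch_photon <- function(beam, n = 1) {
  stopifnot(inherits(beam, "beam_spec"))
  xi <- runif(n)
  r <- if (beam$profile == "gaussian") {
    beam$radius / sqrt(2) * sqrt(-log(xi))
  } else {
    beam$radius * sqrt(xi)
  }
  phi <- 2 * pi * runif(n)
  tibble::tibble(
    x = r * cos(phi), y = r * sin(phi), z = 0,
    mu_x = 0, mu_y = 0, mu_z = 1, weight = 1
  )
}

#' Run Monte Carlo photon transport on a material grid
#'
#' Traces photon packets through the voxelized domain: free paths are
#' sampled from the local attenuation coefficient and truncated at voxel
#' boundaries with the residual optical depth carried across materials;
#' each interaction deposits `W mu_a / mu_tot` in the local voxel and
#' scatters the packet by Henyey-Greenstein sampling. Packets are
#' terminated by Russian roulette below weight `w_min` (survival
#' probability `roulette_p`, weight boost `1 / roulette_p`), which is
#' unbiased in expectation. Boundaries are refractive-index matched:
#' packets leaving the surface, the cylinder wall or the bottom escape and
#' are tallied.
#'
#' The absorbed map is normalized per launched unit power, so a single
#' transport run serves every laser power: the volumetric heat source at
#' power `P_l` is `A_v * P_l` per voxel.
#'
#' @param grid A `material_grid` (optical properties per material).
#' @param beam A [beam_spec()].
#' @param n_photons Number of packets (at least 1).
#' @param seed Optional integer seed for R's RNG; recorded in the result.
#' @param w_min,roulette_p Russian-roulette threshold and survival
#'   probability.
#' @return An `absorption_map`: list with the per-voxel absorbed-fraction
#'   array `A`, scalar tallies `escaped` and `residual` (roulette
#'   bookkeeping; `sum(A) + escaped + residual = 1`), `n_photons`, `seed`
#'   and the beam.
#' @export
run_transport <- function(grid, beam, n_photons = 1e5, seed = NULL,
                          w_min = 1e-4, roulette_p = 0.1) {
  stopifnot(inherits(grid, "material_grid"), inherits(beam, "beam_spec"))
  if (n_photons < 1) abort("n_photons must be at least 1")
  if (is.finite(grid$cylinder_radius) && beam$radius > grid$cylinder_radius) {
    warn("beam radius exceeds the domain radius; the escaped fraction will be inflated")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- dim(grid$ids)
  mat <- grid$materials
  nmat <- nrow(mat)
  mua <- c(0, mat$mu_a); mus <- c(0, mat$mu_s); gg <- c(0, mat$g)
  zb <- c(0, cumsum(grid$dz))
  res <- cpp_transport(
    as.integer(grid$ids), d[1], d[2], d[3],
    mua, mus, gg,
    grid$dx, grid$dy, zb,
    grid$x[1] - grid$dx / 2, grid$y[1] - grid$dy / 2,
    if (is.finite(grid$cylinder_radius)) grid$cylinder_radius else -1,
    if (beam$profile == "gaussian") 1L else 2L,
    beam$radius, as.double(n_photons), w_min, roulette_p
  )
  A <- array(res$A / n_photons, d)
  structure(
    list(
      A = A, escaped = res$escaped / n_photons,
      residual = res$residual / n_photons,
      n_photons = n_photons, seed = seed, beam = beam
    ),
    class = "absorption_map"
  )
}

#' @export
print.absorption_map <- function(x, ...) {
  cat(sprintf(
    "<absorption_map> %s voxels; deposited %.4f, escaped %.4f, residual %.2e (n = %g, seed = %s)\n",
    paste(dim(x$A), collapse = " x "), sum(x$A), x$escaped, x$residual,
    x$n_photons, if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}
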