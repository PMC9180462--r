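#' Specify a gold-nanorod loading
#'
#' Describes the nanoparticle agent mixed into the tumor medium: volume
#' fraction `f_v`, optical efficiencies `Q_a`/`Q_s` and effective radius
#' `r_eff`. The efficiencies of the reference nanorod (aspect ratio 6.67,
#' effective radius 20 nm) are not computed here; they are calibrated once
#' from the densest published loading via [calibrate_efficiencies()] and
#' used as constants, which keeps the mixing model exactly consistent with
#' the published coefficient table.
#'
#' @param f_v Volume fraction of nanoparticles (dimensionless, `0 <= f_v < 1`).
#' @param Q_a,Q_s Absorption/scattering efficiencies (dimensionless).
#'   Default: calibrated from [aunp_reference_optics()] at `f_v = 1e-3`.
#' @param r_eff Effective particle radius in mm (default 20 nm = `2e-5` mm).
#' @param aspect_ratio Rod aspect ratio (metadata only).
#' @return An object of class `nanoparticle_spec`.
#' @export
#' @examples
#' nanoparticle_spec(1e-6)
nanoparticle_spec <- function(f_v, Q_a = NULL, Q_s = NULL,
                              r_eff = 2e-5, aspect_ratio = 6.67) {
  if (f_v < 0 || f_v >= 1) abort("f_v must lie in [0, 1)")
  if (r_eff <= 0) abort("r_eff must be positive")
  if (is.null(Q_a) || is.null(Q_s)) {
    ref <- aunp_reference_optics()[1, ]
    q <- calibrate_efficiencies(ref$mu_a, ref$mu_s, ref$f_v,
                                base = tumor_baseline(), r_eff = r_eff)
    if (is.null(Q_a)) Q_a <- q$Q_a
    if (is.null(Q_s)) Q_s <- q$Q_s
  }
  if (Q_a < 0 || Q_s < 0) abort("optical efficiencies must be non-negative")
  structure(
    list(f_v = f_v, Q_a = Q_a, Q_s = Q_s, r_eff = r_eff,
         aspect_ratio = aspect_ratio),
    class = "nanoparticle_spec"
  )
}

#' Optical coefficients contributed by the nanoparticles
#'
#' The particle ensemble adds `mu = 0.75 * f_v * Q / r_eff` to the
#' absorption and scattering coefficients of the host medium; both
#' contributions are linear in the volume fraction.
#'
#' @param np A [nanoparticle_spec()].
#' @return A tibble with columns `mu_a_np` and `mu_s_np` (1/mm).
#' @export
#' @examples
#' nanoparticle_coefficients(nanoparticle_spec(1e-3))
nanoparticle_coefficients <- function(np) {
  stopifnot(inherits(np, "nanoparticle_spec"))
  tibble::tibble(
    mu_a_np = 0.75 * np$f_v * np$Q_a / np$r_eff,
    mu_s_np = 0.75 * np$f_v * np$Q_s / np$r_eff
  )
}

#' Mix nanoparticle optics into a base medium
#'
#' Adds the particle contributions to the base-medium coefficients:
#' `mu_a = mu_a_m + mu_a_np`, `mu_s = mu_s_m + mu_s_np`. The anisotropy
#' factor is left at the base-tissue value: the loading modifies only the
#' coefficient magnitudes.
#'
#' @param base One-row property table of the particle-free medium (e.g.
#'   [tumor_baseline()]), with columns `mu_a`, `mu_s`, `g`.
#' @param np A [nanoparticle_spec()].
#' @return A tibble with columns `mu_a`, `mu_s`, `g`, `mu_tot`.
#' @export
#' @examples
#' mix_optical_properties(tumor_baseline(), nanoparticle_spec(1e-6))
mix_optical_properties <- function(base, np) {
  co <- nanoparticle_coefficients(np)
  tibble::tibble(
    mu_a = base$mu_a + co$mu_a_np,
    mu_s = base$mu_s + co$mu_s_np,
    g = base$g,
    mu_tot = base$mu_a + co$mu_a_np + base$mu_s + co$mu_s_np
  )
}

#' Calibrate nanoparticle optical efficiencies from published coefficients
#'
#' Inverts the linear mixing model against a published (loaded-tissue)
#' coefficient pair at a reference volume fraction:
#' `Q = (mu_printed - mu_base) * r_eff / (0.75 * f_v_ref)`.
#'
#' @param printed_mu_a,printed_mu_s Published coefficients of the loaded
#'   tissue (1/mm).
#' @param f_v_ref Volume fraction of the published column.
#' @param base One-row property table of the particle-free medium.
#' @param r_eff Effective particle radius (mm).
#' @return A list with elements `Q_a` and `Q_s`.
#' @export
#' @examples
#' ref <- aunp_reference_optics()[1, ]
#' calibrate_efficiencies(ref$mu_a, ref$mu_s, ref$f_v)
calibrate_efficiencies <- function(printed_mu_a, printed_mu_s, f_v_ref,
                                   base = tumor_baseline(), r_eff = 2e-5) {
  if (f_v_ref <= 0) abort("f_v_ref must be positive")
  if (printed_mu_a < base$mu_a || printed_mu_s < base$mu_s) {
    abort("printed coefficients below the base medium imply a negative particle contribution")
  }
  list(
    Q_a = (printed_mu_a - base$mu_a) * r_eff / (0.75 * f_v_ref),
    Q_s = (printed_mu_s - base$mu_s) * r_eff / (0.75 * f_v_ref)
  )
}

#' Forward-predicted optics of the loaded tumor over volume fractions
#'
#' Evaluates the calibrated mixing model at each requested volume
#' fraction, reproducing (and extending) the published coefficient table.
#'
#' @param f_v Volume fractions.
#' @param base Particle-free medium.
#' @param r_eff Effective particle radius (mm).
#' @return A tibble with columns `f_v`, `mu_a`, `mu_s`, `g`, `mu_tot`.
#' @export
tumor_optics_table <- function(f_v = 10^-(3:6), base = tumor_baseline(),
                               r_eff = 2e-5) {
  purrr::map_dfr(f_v, function(fv) {
    out <- mix_optical_properties(base, nanoparticle_spec(fv, r_eff = r_eff))
    dplyr::mutate(out, f_v = fv, .before = 1)
  })
}

#' Apply a nanoparticle loading to the tumor of a material grid
#'
#' Returns a copy of the grid whose tumor material carries the mixed
#' optical coefficients. The loading is uniform across the tumor; thermal
#' properties are unchanged.
#'
#' @param grid A `material_grid` containing a tumor.
#' @param np A [nanoparticle_spec()].
#' @return The modified `material_grid`.
#' @export
apply_nanoparticles <- function(grid, np) {
  if (is.na(grid$tumor_id)) abort("grid has no tumor material")
  row <- which(grid$materials$id == grid$tumor_id)
  mixed <- mix_optical_properties(grid$materials[row, ], np)
  grid$materials$mu_a[row] <- mixed$mu_a
  grid$materials$mu_s[row] <- mixed$mu_s
  grid$nanoparticle <- np
  grid
}
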