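#' Thermal and optical properties of the skin layers
#'
#' Reference property set for the four-layer skin model used by the
#' treatment domain: epidermis, papillary dermis, reticular dermis and
#' subcutaneous fat, ordered from the surface downwards. Layer thicknesses
#' sum to the 20 mm depth of the treatment cylinder.
#'
#' @return A tibble with one row per layer and columns `name`,
#'   `t` (thickness, mm), `k` (thermal conductivity, W/(m K)),
#'   `cv` (specific heat, J/(kg K)), `rho` (density, kg/m^3),
#'   `mu_a` (absorption coefficient, 1/mm), `mu_s` (scattering
#'   coefficient, 1/mm) and `g` (scattering anisotropy).
#' @seealso [tumor_baseline()], [domain_spec()]
#' @export
#' @examples
#' skin_layers()
skin_layers <- function() {
  tibble::tibble(
    name = c("epidermis", "papillary_dermis", "reticular_dermis", "subcutaneous_fat"),
    t    = c(0.08, 0.5, 0.6, 18.82),
    k    = c(0.235, 0.445, 0.445, 0.19),
    cv   = c(3589, 3300, 3300, 2500),
    rho  = c(1200, 1200, 1200, 1000),
    mu_a = c(0.4, 0.38, 0.48, 0.43),
    mu_s = c(45, 30, 25, 5),
    g    = c(0.8, 0.9, 0.8, 0.75)
  )
}

#' Properties of the nanoparticle-free tumor medium
#'
#' Squamous-cell-carcinoma tissue before any gold-nanorod loading. The
#' optical coefficients are the base-medium values to which nanoparticle
#' contributions are added by [mix_optical_properties()].
#'
#' @return A one-row tibble with the same columns as [skin_layers()].
#' @export
#' @examples
#' tumor_baseline()$mu_a  # 0.047 mm^-1 at 1064 nm
tumor_baseline <- function() {
  tibble::tibble(
    name = "tumor", t = 2, k = 0.495, cv = 3421, rho = 1070,
    mu_a = 0.047, mu_s = 0.883, g = 0.8
  )
}

#' Thermal-hazard weights per temperature band
#'
#' Weighting table mapping tissue temperature to the severity of the
#' laser-induced thermal effect, from normothermia (weight 1) through
#' hyperthermia, coagulation, vaporization and carbonization up to rapid
#' ablation (weight 8). Bands are lower-closed/upper-open; temperatures
#' below 37 degC carry the baseline weight 1.
#'
#' @return A tibble with columns `lower`, `upper` (degC, `[lower, upper)`),
#'   `weight` and `effect`.
#' @seealso [hazard_weight()], [hazard_value()]
#' @export
hazard_weights <- function() {
  tibble::tibble(
    lower  = c(-Inf, 37, 43, 45, 50, 70, 80, 100, 150, 300),
    upper  = c(37, 43, 45, 50, 70, 80, 100, 150, 300, Inf),
    weight = c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8),
    effect = c(
      "normal", "biostimulation", "hyperthermia", "reduced enzyme activity",
      "protein denaturation (coagulation)", "welding",
      "permeabilization of cell membranes", "vaporization", "carbonization",
      "rapid cutting and ablation"
    )
  )
}

#' Reference optical coefficients of the nanorod-loaded tumor
#'
#' Published absorption and scattering coefficients of tumor tissue loaded
#' with rod-shaped gold nanoparticles (aspect ratio 6.67, effective radius
#' 20 nm) at four volume fractions. The densest column (`f_v = 1e-3`) is the
#' calibration anchor from which the nanoparticle optical efficiencies
#' `Q_a`, `Q_s` are backed out; the remaining columns serve as checks of the
#' linear mixing model.
#'
#' @return A tibble with columns `f_v`, `mu_a` and `mu_s` (1/mm).
#' @seealso [calibrate_efficiencies()], [tumor_optics_table()]
#' @export
aunp_reference_optics <- function() {
  tibble::tibble(
    f_v  = c(1e-3, 1e-4, 1e-5, 1e-6),
    mu_a = c(557.414, 55.784, 5.62, 0.604),
    mu_s = c(118.575, 12.652, 2.06, 1.001)
  )
}
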