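#' Hazard weight of a temperature
#'
#' Looks up the thermal-damage weight of the band containing each
#' temperature. Bands are lower-closed/upper-open; values below 37 degC
#' carry the baseline weight 1.
#'
#' @param T Temperature(s), degC.
#' @param weights Band table from [hazard_weights()].
#' @return Integer-valued weights, vectorized over `T`.
#' @export
#' @examples
#' hazard_weight(c(37, 44, 60))  # 1 2 3
hazard_weight <- function(T, weights = hazard_weights()) {
  stopifnot(all(is.finite(T)))
  breaks <- weights$lower[-1]
  weights$weight[findInterval(T, breaks) + 1L]
}

#' Apoptosis ratio of a temperature snapshot
#'
#' Fraction of the tumor volume inside the apoptosis temperature band
#' (43-50 degC, lower-closed/upper-open): tumor tissue in this range dies
#' by self-destruction without spilling its contents, whereas hotter
#' tissue necroses.
#'
#' @param T Temperature array, degC.
#' @param tumor_mask Logical array marking tumor voxels.
#' @param band Apoptosis band edges `[lower, upper)`, degC.
#' @return `theta_A` in `[0, 1]`.
#' @export
apoptosis_ratio <- function(T, tumor_mask, band = c(43, 50)) {
  if (!any(tumor_mask)) abort("tumor mask is empty")
  Tt <- T[tumor_mask]
  mean(Tt >= band[1] & Tt < band[2])
}

#' Thermal hazard value of a temperature snapshot
#'
#' Volume-weighted mean hazard weight over the normal (non-tumor) tissue:
#' `theta_H = sum_j V_j w_j / V_n`, equal to 1 for an unheated field and
#' increasing as normal tissue is pushed into higher damage bands.
#'
#' @param T Temperature array, degC.
#' @param normal_mask Logical array marking normal-tissue voxels.
#' @param weights Band table from [hazard_weights()].
#' @return `theta_H >= 1`.
#' @export
hazard_value <- function(T, normal_mask, weights = hazard_weights()) {
  if (!any(normal_mask)) abort("normal-tissue mask is empty")
  mean(hazard_weight(T[normal_mask], weights))
}

#' Time average of a metric series
#'
#' Trapezoidal approximation of `(1/tau) integral theta dt` over the
#' treatment window spanned by `times`.
#'
#' @param values Metric value per snapshot.
#' @param times Strictly increasing snapshot times (s).
#' @return The starred (time-averaged) value.
#' @export
#' @examples
#' time_average(c(0, 1), c(0, 600))  # 0.5
time_average <- function(values, times) {
  if (length(values) != length(times) || length(times) < 2) {
    abort("need at least two snapshots with matching times")
  }
  dt <- diff(times)
  if (any(dt <= 0)) abort("times must be strictly increasing")
  sum(dt * (utils::head(values, -1) + utils::tail(values, -1)) / 2) /
    (times[length(times)] - times[1])
}

#' Effective apoptosis retention ratio
#'
#' `theta_eff* = theta_A* / theta_H*`: the treatment-quality score trading
#' tumor apoptosis coverage against collateral thermal damage.
#'
#' @param theta_A_star Time-averaged apoptosis ratio.
#' @param theta_H_star Time-averaged hazard value (at least 1 by
#'   construction).
#' @return `theta_eff*`.
#' @export
effective_ratio <- function(theta_A_star, theta_H_star) {
  if (any(theta_H_star < 1)) {
    abort("theta_H* below 1 is inconsistent with the hazard weight table")
  }
  theta_A_star / theta_H_star
}

#' Score a simulated temperature series
#'
#' Evaluates `theta_A` and `theta_H` for every stored snapshot of a
#' [simulate_heat()] result.
#'
#' @param field A `thermal_field` with snapshots.
#' @param grid The `material_grid` the field was computed on.
#' @param weights Band table from [hazard_weights()].
#' @return A tibble with columns `time`, `theta_A`, `theta_H`.
#' @export
score_snapshots <- function(field, grid, weights = hazard_weights()) {
  if (is.null(field$snapshots)) abort("field has no stored snapshots")
  tm <- tumor_mask(grid); nm <- normal_mask(grid)
  tibble::tibble(
    time = field$times,
    theta_A = vapply(field$snapshots, apoptosis_ratio, numeric(1), tumor_mask = tm),
    theta_H = vapply(field$snapshots, hazard_value, numeric(1),
                     normal_mask = nm, weights = weights)
  )
}

#' Time-averaged treatment metrics of a scored series
#'
#' Collapses per-snapshot scores into the starred summary metrics.
#'
#' @param scores Tibble from [score_snapshots()].
#' @return A one-row tibble with `theta_A_star`, `theta_H_star`,
#'   `theta_eff_star`.
#' @export
summarize_metrics <- function(scores) {
  a <- time_average(scores$theta_A, scores$time)
  h <- time_average(scores$theta_H, scores$time)
  tibble::tibble(theta_A_star = a, theta_H_star = h,
                 theta_eff_star = effective_ratio(a, h))
}
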