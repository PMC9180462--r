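#' Parameter grid for a treatment sweep
#'
#' The default grid covers both beam profiles, radius ratios 0.5-1.75 in
#' steps of 0.25, laser powers 0-500 mW in steps of 10 and nanoparticle
#' volume fractions `1e-3` to `1e-6` in decade steps.
#'
#' @param profiles Beam profiles to sweep.
#' @param phi_r Radius ratios.
#' @param power Laser powers (mW).
#' @param f_v Nanoparticle volume fractions.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(profiles = c("gaussian", "top_hat"),
                       phi_r = seq(0.5, 1.75, by = 0.25),
                       power = seq(0, 500, by = 10),
                       f_v = 10^-(3:6)) {
  stopifnot(all(profiles %in% c("gaussian", "top_hat")),
            all(phi_r > 0), all(power >= 0), all(f_v >= 0))
  structure(
    list(profiles = profiles, phi_r = phi_r, power = sort(power), f_v = f_v),
    class = "sweep_grid"
  )
}

#' Resolution presets for sweeps
#'
#' `preset_scaled()` is the desk-scale working point used throughout the
#' package's own verification: 0.25 mm voxels, 1e5 photon packets per
#' transport run and 2 s metric snapshots. `preset_paper()` is the
#' fine-grained configuration (0.1 mm lateral voxels with a 0.04 mm axial
#' grid over the top 2.6 mm, 1e6 packets, 1 s snapshots); expect hours of
#' compute for a full sweep at this setting.
#'
#' @return A list of resolution settings consumed by [run_sweep()].
#' @export
preset_scaled <- function() {
  list(name = "scaled", dx = 0.25, dy = 0.25, dz = 0.25,
       n_photons = 1e5, snapshot_interval = 2, safety = 0.9)
}

#' @rdname preset_scaled
#' @export
preset_paper <- function() {
  list(name = "paper", dx = 0.1, dy = 0.1, dz = NULL,
       n_photons = 1e6, snapshot_interval = 1, safety = 0.9)
}

build_preset_grid <- function(preset) {
  build_treatment_domain(domain_spec(
    dx = preset$dx, dy = preset$dy, dz = preset$dz
  ))
}

# Temperature-rise thresholds (degC above baseline) at which the hazard
# weight increments, and the apoptosis band edges.
hazard_rise_edges <- function(weights = hazard_weights(), baseline = 37) {
  inc <- diff(weights$weight)
  edges <- weights$lower[-1][inc > 0] - baseline
  rep(edges, times = inc[inc > 0])  # supports multi-step increments
}

apoptosis_rise_edges <- function(band = c(43, 50), baseline = 37) band - baseline

# One physical simulation: transport + unit-power heat run; banded metrics
# for every requested power recovered by linear scaling of the rise field.
sweep_cell <- function(grid, profile, phi_r, f_v, powers, n_photons, seed,
                       duration, snapshot_interval, safety,
                       w_min = 1e-4, roulette_p = 0.1) {
  gcell <- if (f_v > 0) apply_nanoparticles(grid, nanoparticle_spec(f_v)) else grid
  beam <- beam_spec(profile, phi_r = phi_r,
                    tumor_radius = grid$spec$tumor_radius)
  absorption <- run_transport(gcell, beam, n_photons = n_photons, seed = seed,
                              w_min = w_min, roulette_p = roulette_p)

  config <- sim_config(duration = duration,
                       snapshot_interval = snapshot_interval, safety = safety)
  st <- solver_steps(gcell, config)
  d <- dim(gcell$ids)
  pad <- pad_for_solver(gcell, config, source_w = absorption$A * 1e-3)

  ea <- apoptosis_rise_edges()
  eh <- hazard_rise_edges()
  powers_pos <- powers[powers > 0]
  thr_t <- sort(unique(as.vector(outer(ea, powers_pos, `/`))))
  thr_n <- sort(unique(as.vector(outer(eh, powers_pos, `/`))))

  to_padded0 <- function(lin) {
    i0 <- lin - 1L
    (i0 %% d[1] + 1L) + pad$nxp * ((i0 %/% d[1]) %% d[2] + 1L) +
      pad$nxp * pad$nyp * (i0 %/% (d[1] * d[2]) + 1L)
  }
  t_idx <- to_padded0(which(tumor_mask(gcell)))
  n_idx <- to_padded0(which(normal_mask(gcell)))
  pc <- tumor_center_index(gcell)
  probe <- padded_index(pc[1], pc[2], pc[3], pad$nxp, pad$nyp)

  mat <- gcell$materials
  res <- cpp_heat_sweep(
    as.integer(pad$ids), d[1], d[2], d[3], pad$nmat,
    c(0, mat$k), c(1, mat$rho * mat$cv),
    as.double(pad$q), gcell$dx * 1e-3, gcell$dy * 1e-3, gcell$dz * 1e-3,
    st$dt, st$n_steps, st$per_snap, thr_t, thr_n,
    as.integer(t_idx), as.integer(n_idx), probe
  )

  Vt <- length(t_idx); Vn <- length(n_idx)
  Ct <- apply(res$hist_tumor, 2, function(h) rev(cumsum(rev(h))))
  Cn <- apply(res$hist_normal, 2, function(h) rev(cumsum(rev(h))))
  times <- seq(0, duration, by = snapshot_interval)
  trace <- c(0, res$trace)  # rise per mW at the tumor centre

  purrr::map_dfr(powers, function(P) {
    if (P <= 0) {
      return(tibble::tibble(
        profile = profile, phi_r = phi_r, P_l = P, f_v = f_v,
        theta_A_star = 0, theta_H_star = 1, theta_eff_star = 0,
        peak_center_temp = 37
      ))
    }
    ia <- match(ea / P, thr_t)
    th_a <- c(0, (Ct[ia[1] + 1, ] - Ct[ia[2] + 1, ]) / Vt)
    ih <- match(eh / P, thr_n)
    th_h <- c(1, 1 + colSums(Cn[ih + 1, , drop = FALSE]) / Vn)
    a <- time_average(th_a, times)
    h <- time_average(th_h, times)
    tibble::tibble(
      profile = profile, phi_r = phi_r, P_l = P, f_v = f_v,
      theta_A_star = a, theta_H_star = h,
      theta_eff_star = effective_ratio(a, h),
      peak_center_temp = 37 + P * max(trace)
    )
  })
}

#' Run a treatment-condition sweep
#'
#' Executes one Monte Carlo transport run and one unit-power heat
#' simulation per (profile, radius ratio, volume fraction) cell, then
#' recovers the banded treatment metrics for every laser power by linear
#' scaling of the temperature rise: the discrete heat update is linear in
#' the source and the boundary and initial conditions are
#' power-independent, so a 48-cell sweep covers the full 2448-condition
#' grid. Each cell uses the deterministic seed
#' `master_seed + 1000 * cell_index`.
#'
#' @param sweep A [sweep_grid()].
#' @param preset Resolution preset ([preset_scaled()] or [preset_paper()]).
#' @param grid Optional prebuilt treatment `material_grid` (overrides the
#'   preset's grid).
#' @param master_seed Integer master seed.
#' @param duration Treatment time (s).
#' @param progress Print per-cell progress lines.
#' @return A `photoheat_sweep` tibble with one row per grid point:
#'   `profile`, `phi_r`, `P_l`, `f_v`, `theta_A_star`, `theta_H_star`,
#'   `theta_eff_star`, `peak_center_temp`.
#' @export
run_sweep <- function(sweep = sweep_grid(), preset = preset_scaled(),
                      grid = NULL, master_seed = 1, duration = 600,
                      progress = FALSE) {
  stopifnot(inherits(sweep, "sweep_grid"))
  if (is.null(grid)) grid <- build_preset_grid(preset)
  cells <- tidyr::expand_grid(
    profile = sweep$profiles, phi_r = sweep$phi_r, f_v = sweep$f_v
  )
  rows <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    seed <- as.integer(master_seed + 1000 * i)
    if (progress) {
      message(sprintf("cell %d/%d: %s phi_r=%.2f f_v=%.0e (seed %d)",
                      i, nrow(cells), cell$profile, cell$phi_r, cell$f_v, seed))
    }
    sweep_cell(grid, cell$profile, cell$phi_r, cell$f_v, sweep$power,
               preset$n_photons, seed, duration,
               preset$snapshot_interval, preset$safety)
  })
  structure(
    rows,
    class = c("photoheat_sweep", class(rows)),
    master_seed = master_seed, preset = preset$name,
    n_photons = preset$n_photons, duration = duration,
    voxel = c(grid$dx, grid$dy, min(grid$dz))
  )
}

#' Evaluate a single treatment condition
#'
#' Runs the same transport + heat + metrics pipeline as one [run_sweep()]
#' cell, for one beam condition and one or more laser powers.
#'
#' @param profile,phi_r,f_v,power Condition to evaluate (power may be a
#'   vector, mW).
#' @param preset Resolution preset.
#' @param grid Optional prebuilt `material_grid`.
#' @param seed Transport seed.
#' @param duration Treatment time (s).
#' @return A tibble with one row per power.
#' @export
run_condition <- function(profile, phi_r, f_v, power,
                          preset = preset_scaled(), grid = NULL, seed = 1,
                          duration = 600) {
  if (is.null(grid)) grid <- build_preset_grid(preset)
  sweep_cell(grid, profile, phi_r, f_v, power, preset$n_photons, seed,
             duration, preset$snapshot_interval, preset$safety)
}

#' Locate the optimal condition in a sweep
#'
#' Returns the row maximizing the chosen metric (minimizing it for
#' `theta_H_star`, where less collateral damage is better). Ties are
#' broken towards the least dose: lowest power, then lowest volume
#' fraction, then smallest radius ratio.
#'
#' @param result A `photoheat_sweep` (or compatible tibble).
#' @param metric One of `"theta_eff_star"`, `"theta_A_star"`,
#'   `"theta_H_star"`.
#' @param profile,f_v,phi_r Optional filters restricting the search scope.
#' @return The optimal row as a one-row tibble.
#' @export
find_optimum <- function(result,
                         metric = c("theta_eff_star", "theta_A_star", "theta_H_star"),
                         profile = NULL, f_v = NULL, phi_r = NULL) {
  metric <- match.arg(metric)
  out <- result
  if (!is.null(profile)) out <- dplyr::filter(out, .data$profile %in% !!profile)
  if (!is.null(f_v)) out <- dplyr::filter(out, .data$f_v %in% !!f_v)
  if (!is.null(phi_r)) out <- dplyr::filter(out, .data$phi_r %in% !!phi_r)
  if (nrow(out) == 0) abort("no sweep rows match the requested scope")
  key <- if (metric == "theta_H_star") out[[metric]] else -out[[metric]]
  out <- out[order(key, out$P_l, out$f_v, out$phi_r), ]
  tibble::as_tibble(out[1, ])
}

#' Tumor-centre temperature trace for one condition
#'
#' Transport plus heat run reporting the temperature at the tumor-centre
#' voxel over the treatment, for profile/radius comparisons.
#'
#' @inheritParams run_condition
#' @param power Laser power (mW, scalar).
#' @return A `photoheat_trace` tibble with columns `time` and
#'   `temperature`.
#' @export
center_temperature_trace <- function(profile, phi_r, f_v, power,
                                     preset = preset_scaled(), grid = NULL,
                                     seed = 1, duration = 600) {
  if (is.null(grid)) grid <- build_preset_grid(preset)
  gcell <- if (f_v > 0) apply_nanoparticles(grid, nanoparticle_spec(f_v)) else grid
  beam <- beam_spec(profile, phi_r = phi_r,
                    tumor_radius = grid$spec$tumor_radius, power = power)
  absorption <- run_transport(gcell, beam, n_photons = preset$n_photons,
                              seed = seed)
  config <- sim_config(duration = duration,
                       snapshot_interval = preset$snapshot_interval,
                       safety = preset$safety)
  st <- solver_steps(gcell, config)
  d <- dim(gcell$ids)
  pad <- pad_for_solver(gcell, config, source_w = absorption$A * 1e-3)
  pc <- tumor_center_index(gcell)
  probe <- padded_index(pc[1], pc[2], pc[3], pad$nxp, pad$nyp)
  mat <- gcell$materials
  res <- cpp_heat_sweep(
    as.integer(pad$ids), d[1], d[2], d[3], pad$nmat,
    c(0, mat$k), c(1, mat$rho * mat$cv),
    as.double(pad$q), gcell$dx * 1e-3, gcell$dy * 1e-3, gcell$dz * 1e-3,
    st$dt, st$n_steps, st$per_snap, numeric(0), numeric(0),
    integer(0), integer(0), probe
  )
  out <- tibble::tibble(
    time = seq(0, duration, by = config$snapshot_interval),
    temperature = 37 + power * c(0, res$trace)
  )
  structure(out, class = c("photoheat_trace", class(out)),
            profile = profile, phi_r = phi_r, f_v = f_v, power = power)
}

#' @export
tidy.photoheat_sweep <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = c("theta_A_star", "theta_H_star", "theta_eff_star"),
    names_to = "metric", values_to = "value"
  )
}

#' @export
glance.photoheat_sweep <- function(x, ...) {
  purrr::map_dfr(unique(x$profile), function(p) {
    best <- find_optimum(x, "theta_eff_star", profile = p)
    tibble::tibble(
      profile = p, phi_r_opt = best$phi_r, P_l_opt = best$P_l,
      f_v_opt = best$f_v, theta_eff_star_max = best$theta_eff_star,
      n_conditions = sum(x$profile == p)
    )
  })
}

#' Plot sweep metrics against laser power
#'
#' @param object A `photoheat_sweep`.
#' @param metric Metric column to plot.
#' @param ... Unused.
#' @return A ggplot object: one line per radius ratio, faceted by volume
#'   fraction and profile.
#' @export
autoplot.photoheat_sweep <- function(object, metric = "theta_eff_star", ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$P_l, y = .data[[metric]],
                 colour = factor(.data$phi_r))
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$f_v),
      cols = ggplot2::vars(.data$profile),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "laser power (mW)", y = metric, colour = "phi_r")
}

#' Plot a tumor-centre temperature trace
#'
#' @param object A `photoheat_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.photoheat_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$temperature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "tumor-centre temperature (degC)")
}
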