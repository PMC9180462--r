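#' Heat-solver configuration
#'
#' Settings for the explicit bioheat integration. The model contains pure
#' conduction plus the laser source: no blood perfusion, metabolic heat or
#' surface convection terms. Boundaries default to a thermally insulated
#' skin-air surface (`top`) and far-field body temperature (Dirichlet
#' 37 degC) on the cylinder wall (`lateral`) and bottom.
#'
#' @param duration Treatment time (s).
#' @param snapshot_interval Interval between stored snapshots (s); must
#'   divide `duration`.
#' @param power Laser power `P_l` (mW).
#' @param top,lateral,bottom Boundary condition per face: `"adiabatic"`,
#'   `"dirichlet"` (at `boundary_value`), or a number (Dirichlet at that
#'   temperature).
#' @param boundary_value Temperature of plain `"dirichlet"` faces (degC).
#' @param initial Uniform initial temperature (degC).
#' @param safety Fraction of the stability-limit time step to use.
#' @param dt Time step (s); computed from [stable_timestep()] when `NULL`
#'   and then shortened to divide `snapshot_interval` exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 600, snapshot_interval = 1, power = 100,
                       top = "adiabatic", lateral = "dirichlet",
                       bottom = "dirichlet", boundary_value = 37,
                       initial = 37, safety = 0.9, dt = NULL) {
  if (duration <= 0) abort("duration must be positive")
  if (snapshot_interval <= 0 || snapshot_interval > duration) {
    abort("snapshot_interval must lie in (0, duration]")
  }
  if (safety <= 0 || safety > 1) abort("safety must lie in (0, 1]")
  structure(
    list(duration = duration, snapshot_interval = snapshot_interval,
         power = power, top = top, lateral = lateral, bottom = bottom,
         boundary_value = boundary_value, initial = initial,
         safety = safety, dt = dt),
    class = "sim_config"
  )
}

bc_value <- function(bc, default) {
  if (is.numeric(bc)) bc
  else if (identical(bc, "dirichlet")) default
  else NA_real_  # adiabatic
}

#' Stability-limited time step of the explicit scheme
#'
#' Upper bound on the forward-Euler time step:
#' `dt <= rho cv / (2 k_max (1/dx^2 + 1/dy^2 + 1/dz^2))` evaluated per
#' material, where `k_max` is the largest harmonic-mean conductivity the
#' material can form with any material present in the grid (a conservative
#' stand-in for the largest conductance actually adjacent to a voxel). The
#' smallest axial voxel is used for non-uniform grids.
#'
#' @param grid A `material_grid`.
#' @param safety Fraction of the limit to return.
#' @return Time step in seconds.
#' @export
#' @examples
#' g <- slab_grid(5, 5, 5, materials = tibble::tibble(
#'   name = "m", k = 0.5, cv = 4000, rho = 1000, mu_a = 0, mu_s = 0, g = 0))
#' stable_timestep(g, safety = 1)  # 4/3 s
stable_timestep <- function(grid, safety = 0.9) {
  if (safety <= 0 || safety > 1) abort("safety must lie in (0, 1]")
  present <- sort(unique(as.integer(grid$ids[grid$ids > 0L])))
  mat <- grid$materials[match(present, grid$materials$id), ]
  inv2 <- 1 / (grid$dx * 1e-3)^2 + 1 / (grid$dy * 1e-3)^2 +
    1 / (min(grid$dz) * 1e-3)^2
  dts <- vapply(seq_len(nrow(mat)), function(i) {
    ksum <- mat$k[i] + mat$k
    k_pairs <- ifelse(ksum > 0, 2 * mat$k[i] * mat$k / ksum, 0)
    kmax <- max(k_pairs, mat$k[i])
    if (kmax <= 0) return(Inf)  # no conduction constrains the step
    mat$rho[i] * mat$cv[i] / (2 * kmax * inv2)
  }, numeric(1))
  safety * min(dts)
}

# Pad grid/ids/fields with a one-voxel halo and encode boundary conditions.
# Fixed (Dirichlet) cells get id nmat + 1 and carry their temperature in T0.
pad_for_solver <- function(grid, config, initial = NULL, source_w = NULL) {
  d <- dim(grid$ids)
  nmat <- nrow(grid$materials)
  fixed_id <- nmat + 1L
  nxp <- d[1] + 2L; nyp <- d[2] + 2L; nzp <- d[3] + 2L

  lat_v <- bc_value(config$lateral, config$boundary_value)
  top_v <- bc_value(config$top, config$boundary_value)
  bot_v <- bc_value(config$bottom, config$boundary_value)

  ids <- array(0L, c(nxp, nyp, nzp))
  inner <- grid$ids
  if (!is.na(lat_v)) inner[inner == 0L] <- fixed_id
  ids[2:(nxp - 1), 2:(nyp - 1), 2:(nzp - 1)] <- inner
  if (!is.na(lat_v)) {
    ids[c(1, nxp), , ] <- fixed_id
    ids[, c(1, nyp), ] <- fixed_id
  }
  ids[, , 1] <- if (is.na(top_v)) 0L else fixed_id
  ids[, , nzp] <- if (is.na(bot_v)) 0L else fixed_id

  T0 <- array(config$initial, c(nxp, nyp, nzp))
  if (!is.null(initial)) {
    if (length(initial) == 1) T0[] <- initial
    else T0[2:(nxp - 1), 2:(nyp - 1), 2:(nzp - 1)] <- initial
  }
  if (!is.na(lat_v)) T0[ids == fixed_id] <- lat_v
  if (!is.na(top_v)) T0[, , 1] <- top_v
  if (!is.na(bot_v)) T0[, , nzp] <- bot_v

  q <- array(0, c(nxp, nyp, nzp))
  if (!is.null(source_w)) q[2:(nxp - 1), 2:(nyp - 1), 2:(nzp - 1)] <- source_w

  list(ids = ids, T0 = T0, q = q, nmat = nmat, fixed_id = fixed_id,
       dims = d, nxp = nxp, nyp = nyp, nzp = nzp)
}

padded_index <- function(i, j, k, nxp, nyp) {
  (i + 1L) + nxp * ((j + 1L - 1L) + nyp * (k + 1L - 1L)) - 1L  # 0-based
}

solver_steps <- function(grid, config) {
  dt <- if (is.null(config$dt)) stable_timestep(grid, config$safety) else config$dt
  per_snap <- max(1L, as.integer(ceiling(config$snapshot_interval / dt - 1e-9)))
  dt <- config$snapshot_interval / per_snap
  n_snaps <- round(config$duration / config$snapshot_interval)
  if (abs(n_snaps * config$snapshot_interval - config$duration) > 1e-9) {
    abort("snapshot_interval must divide duration")
  }
  list(dt = dt, per_snap = per_snap, n_steps = n_snaps * per_snap,
       n_snaps = n_snaps)
}

#' Integrate the temperature field over a treatment
#'
#' Forward-Euler integration of the heat-diffusion equation with
#' harmonic-mean face conductances and the Monte Carlo absorption map as
#' volumetric source (`A_v * P_l` watts per voxel). Snapshots of the full
#' field are stored every `snapshot_interval` seconds, starting from the
#' uniform initial state at `tau = 0`. The run is deterministic given its
#' inputs.
#'
#' @param grid A `material_grid` (thermal properties per material).
#' @param absorption An `absorption_map` from [run_transport()] on the same
#'   grid, or `NULL` for an unheated run.
#' @param config A [sim_config()].
#' @param initial Optional initial temperature: scalar or full array
#'   (overrides `config$initial`); used by the analytic benchmarks.
#' @param probe Voxel index `c(i, j, k)` traced at every snapshot; defaults
#'   to the tumor centre (or the grid centre without a tumor).
#' @param keep_snapshots Set `FALSE` to retain only the probe trace and
#'   final field (saves memory on large grids).
#' @return A `thermal_field`: list with `times`, `snapshots` (list of
#'   arrays, one per time), `trace` (tibble time/temperature), `final`,
#'   `dt` and the config.
#' @export
simulate_heat <- function(grid, absorption = NULL, config = sim_config(),
                          initial = NULL, probe = NULL,
                          keep_snapshots = TRUE) {
  stopifnot(inherits(grid, "material_grid"))
  d <- dim(grid$ids)
  source_w <- NULL
  if (!is.null(absorption)) {
    stopifnot(inherits(absorption, "absorption_map"),
              all(dim(absorption$A) == d))
    source_w <- absorption$A * config$power * 1e-3  # mW -> W per voxel
  }
  st <- solver_steps(grid, config)
  pad <- pad_for_solver(grid, config, initial = initial, source_w = source_w)
  if (is.null(probe)) {
    probe <- if (!is.na(grid$tumor_id)) tumor_center_index(grid)
             else ceiling(d / 2)
  }
  p0 <- padded_index(probe[1], probe[2], probe[3], pad$nxp, pad$nyp)

  mat <- grid$materials
  res <- cpp_heat_general(
    as.integer(pad$ids), d[1], d[2], d[3], pad$nmat,
    c(0, mat$k), c(1, mat$rho * mat$cv),
    as.double(pad$q), as.double(pad$T0),
    grid$dx * 1e-3, grid$dy * 1e-3, grid$dz * 1e-3,
    st$dt, st$n_steps, st$per_snap, p0, keep_snapshots
  )

  init_arr <- array(pad$T0[2:(pad$nxp - 1), 2:(pad$nyp - 1), 2:(pad$nzp - 1)], d)
  snaps <- NULL
  if (keep_snapshots) {
    snaps <- c(list(init_arr),
               lapply(seq_len(res$n_snaps), function(s) array(res$snapshots[, s], d)))
  }
  times <- seq(0, by = config$snapshot_interval, length.out = res$n_snaps + 1)
  trace <- tibble::tibble(
    time = times,
    temperature = c(init_arr[probe[1], probe[2], probe[3]], res$trace)
  )
  final <- array(res$T_final, c(pad$nxp, pad$nyp, pad$nzp))
  structure(
    list(times = times, snapshots = snaps, trace = trace,
         final = array(final[2:(pad$nxp - 1), 2:(pad$nyp - 1), 2:(pad$nzp - 1)], d),
         dt = st$dt, config = config, probe = probe),
    class = "thermal_field"
  )
}

#' Advance a temperature field by one explicit step
#'
#' Single forward-Euler update, mainly useful for verifying the discrete
#' scheme against hand calculations.
#'
#' @param T Temperature array matching the grid.
#' @param grid A `material_grid`.
#' @param absorption Optional `absorption_map` (source term).
#' @param power Laser power (mW).
#' @param dtau Time step (s); must not exceed the stability limit.
#' @param config A [sim_config()] supplying the boundary conditions.
#' @return The updated temperature array.
#' @export
step_temperature <- function(T, grid, absorption = NULL, power = 0,
                             dtau = stable_timestep(grid),
                             config = sim_config(power = power)) {
  d <- dim(grid$ids)
  stopifnot(all(dim(T) == d))
  source_w <- if (is.null(absorption)) NULL else absorption$A * power * 1e-3
  pad <- pad_for_solver(grid, config, initial = T, source_w = source_w)
  mat <- grid$materials
  res <- cpp_heat_general(
    as.integer(pad$ids), d[1], d[2], d[3], pad$nmat,
    c(0, mat$k), c(1, mat$rho * mat$cv),
    as.double(pad$q), as.double(pad$T0),
    grid$dx * 1e-3, grid$dy * 1e-3, grid$dz * 1e-3,
    dtau, 1L, 1L, -1L, TRUE
  )
  array(res$snapshots[, 1], d)
}

#' Total thermal energy of a field
#'
#' `sum(rho cv V T)` over the tissue voxels; conserved by the discrete
#' scheme under adiabatic boundaries with no source.
#'
#' @param grid A `material_grid`.
#' @param T Temperature array (degC).
#' @return Energy in joules (relative to 0 degC).
#' @export
thermal_energy <- function(grid, T) {
  mat <- grid$materials
  rcv <- c(0, mat$rho * mat$cv)[grid$ids + 1L]
  vol <- (grid$dx * 1e-3) * (grid$dy * 1e-3) *
    rep(grid$dz * 1e-3, each = dim(grid$ids)[1] * dim(grid$ids)[2])
  sum(rcv * vol * T)
}

#' @export
print.thermal_field <- function(x, ...) {
  cat(sprintf(
    "<thermal_field> %d snapshots over %.4g s (dt = %.4g s); probe peak %.2f degC\n",
    length(x$times), max(x$times), x$dt, max(x$trace$temperature)
  ))
  invisible(x)
}
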