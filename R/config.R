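#' Default simulation configuration
#'
#' Nested configuration mirroring the YAML layout used by the command-line
#' interface: domain geometry, nanoparticle loading, beam, solver and sweep
#' settings. Every default traces to the package's reference property
#' tables.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    domain = list(
      cylinder_radius = 15, cylinder_depth = 20,
      dx = 0.25, dy = 0.25, dz = 0.25,
      tumor = list(shape = "disc", radius = 5, depth_extent = 2,
                   top_offset = 0.1)
    ),
    nanoparticle = list(f_v = 1e-6, r_eff_nm = 20, aspect_ratio = 6.67,
                        Q_a = NULL, Q_s = NULL),
    beam = list(profile = "gaussian", phi_r = 1, power = 100),
    solver = list(duration = 600, snapshot_interval = 2, safety = 0.9,
                  initial = 37, boundary_value = 37),
    transport = list(n_photons = 1e5, seed = 1, w_min = 1e-4,
                     roulette_p = 0.1),
    sweep = list(profiles = c("gaussian", "top_hat"),
                 phi_r = seq(0.5, 1.75, by = 0.25),
                 power = seq(0, 500, by = 10), f_v = 10^-(3:6))
  )
}

#' Read or write a YAML configuration
#'
#' @param path File path.
#' @param config Configuration list (for writing).
#' @return `read_config()` returns the configuration list with defaults
#'   filled in; `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config = default_config(), path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a domain specification from a configuration
#'
#' @param config A configuration list as from [default_config()].
#' @return A [domain_spec()].
#' @export
as_domain_spec <- function(config) {
  d <- config$domain
  domain_spec(
    cylinder_radius = d$cylinder_radius, cylinder_depth = d$cylinder_depth,
    dx = d$dx, dy = d$dy, dz = d$dz,
    tumor_shape = d$tumor$shape, tumor_radius = d$tumor$radius,
    tumor_depth_extent = d$tumor$depth_extent,
    tumor_top_offset = d$tumor$top_offset
  )
}
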