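#' Specify a cylindrical simulation domain
#'
#' Describes the voxelized treatment (or validation) domain: a cylinder of
#' tissue embedded in a Cartesian voxel grid, a stack of horizontal layers,
#' and a tumor (disc or sphere). The beam travels along +z; `z = 0` is the
#' skin surface and indices grow downwards.
#'
#' The default axial grid is non-uniform: `dz_fine` voxels down to
#' `fine_depth` (resolving the 0.08 mm epidermis) and `dz_coarse` below.
#' Pass a scalar `dz` for a uniform axial grid (it must divide
#' `cylinder_depth`), or a full vector of voxel heights summing to
#' `cylinder_depth`.
#'
#' @param cylinder_radius,cylinder_depth Radius and depth of the tissue
#'   cylinder (mm). Layer thicknesses must sum to `cylinder_depth`.
#' @param dx,dy Lateral voxel sizes (mm).
#' @param dz Axial voxel size: `NULL` (default fine/coarse split), a scalar,
#'   or a vector of per-voxel heights (mm).
#' @param dz_fine,dz_coarse,fine_depth Parameters of the default axial grid
#'   (mm).
#' @param tumor_shape `"disc"` (axis-centred cylinder, treatment geometry) or
#'   `"sphere"` (validation geometry).
#' @param tumor_radius Tumor radius (mm).
#' @param tumor_depth_extent Axial extent of a disc tumor (mm); ignored for
#'   spheres.
#' @param tumor_top_offset Depth of the disc tumor's upper face below the
#'   surface (mm). A sphere is centred at `cylinder_depth / 2` instead.
#' @param layers Layer table as from [skin_layers()] (ordered from the
#'   surface).
#' @param tumor One-row property table for the tumor medium.
#' @return An object of class `domain_spec`.
#' @export
#' @examples
#' spec <- domain_spec(dx = 0.5, dy = 0.5, dz = 0.5)
domain_spec <- function(cylinder_radius = 15, cylinder_depth = 20,
                        dx = 0.1, dy = 0.1, dz = NULL,
                        dz_fine = 0.04, dz_coarse = 0.2, fine_depth = 2.6,
                        tumor_shape = c("disc", "sphere"),
                        tumor_radius = 5, tumor_depth_extent = 2,
                        tumor_top_offset = 0.1,
                        layers = skin_layers(), tumor = tumor_baseline()) {
  tumor_shape <- match.arg(tumor_shape)
  if (dx <= 0 || dy <= 0) abort("voxel sizes must be positive")
  if (abs(sum(layers$t) - cylinder_depth) > 1e-6) {
    abort("layer thicknesses must sum to cylinder_depth")
  }
  stopifnot(all(layers$t > 0), all(layers$k > 0), all(layers$cv > 0),
            all(layers$rho > 0), all(layers$mu_a >= 0), all(layers$mu_s >= 0),
            all(abs(layers$g) <= 1))

  if (is.null(dz)) {
    n_fine <- round(fine_depth / dz_fine)
    rest <- cylinder_depth - n_fine * dz_fine
    n_coarse <- round(rest / dz_coarse)
    if (abs(n_coarse * dz_coarse - rest) > 1e-9) {
      abort("dz_coarse must divide the depth below fine_depth")
    }
    dz <- c(rep(dz_fine, n_fine), rep(dz_coarse, n_coarse))
  } else if (length(dz) == 1) {
    n <- round(cylinder_depth / dz)
    if (abs(n * dz - cylinder_depth) > 1e-9) {
      abort("scalar dz must divide cylinder_depth")
    }
    dz <- rep(dz, n)
  } else if (abs(sum(dz) - cylinder_depth) > 1e-9) {
    abort("dz vector must sum to cylinder_depth")
  }
  if (any(dz <= 0)) abort("voxel sizes must be positive")

  if (tumor_shape == "disc") {
    if (tumor_radius > cylinder_radius ||
        tumor_top_offset + tumor_depth_extent > cylinder_depth) {
      abort("tumor extends beyond the domain")
    }
  } else {
    if (tumor_radius > cylinder_radius || tumor_radius > cylinder_depth / 2) {
      abort("spherical tumor does not fit inside the cylinder")
    }
  }

  structure(
    list(
      cylinder_radius = cylinder_radius, cylinder_depth = cylinder_depth,
      dx = dx, dy = dy, dz = dz,
      tumor_shape = tumor_shape, tumor_radius = tumor_radius,
      tumor_depth_extent = tumor_depth_extent,
      tumor_top_offset = tumor_top_offset,
      layers = layers, tumor = tumor
    ),
    class = "domain_spec"
  )
}

#' Domain specification for the homogeneous validation scenario
#'
#' Convenience wrapper for the verification geometry: a 30 mm radius,
#' 30 mm deep homogeneous tissue cylinder with a 5 mm spherical tumor at
#' its centre. Tissue properties default to the tumor medium since the
#' original benchmark does not publish its property set; override `tissue`
#' to explore alternatives.
#'
#' @param voxel Uniform voxel size (mm).
#' @param tissue One-row property table for the homogeneous tissue.
#' @param tumor_radius Sphere radius (mm).
#' @return A `domain_spec`.
#' @export
validation_domain_spec <- function(voxel = 0.5, tissue = tumor_baseline(),
                                   tumor_radius = 5) {
  tissue$name <- "tissue"
  tissue$t <- 30
  domain_spec(
    cylinder_radius = 30, cylinder_depth = 30,
    dx = voxel, dy = voxel, dz = voxel,
    tumor_shape = "sphere", tumor_radius = tumor_radius,
    layers = tissue, tumor = tumor_baseline()
  )
}

grid_axis <- function(radius, d) {
  nhalf <- floor(radius / d + 1e-9)
  (-nhalf:nhalf) * d
}

new_material_grid <- function(ids, materials, spec, x, y, z, tumor_id) {
  structure(
    list(
      ids = ids, materials = materials,
      dx = spec$dx, dy = spec$dy, dz = spec$dz,
      x = x, y = y, z = z,
      cylinder_radius = spec$cylinder_radius,
      cylinder_depth = spec$cylinder_depth,
      tumor_id = tumor_id, spec = spec
    ),
    class = "material_grid"
  )
}

#' Build the voxelized treatment domain
#'
#' Assigns every voxel (by its centre) to a skin layer, the tumor disc, or
#' the void region outside the tissue cylinder. The tumor is an
#' axis-centred cylindrical disc that overrides whichever layers occupy its
#' voxels; its upper face sits `tumor_top_offset` below the surface.
#'
#' @param spec A [domain_spec()] with `tumor_shape = "disc"`.
#' @return A `material_grid`: voxel material ids (0 = void), the material
#'   property table, voxel-centre coordinates and grid metadata.
#' @export
#' @examples
#' g <- build_treatment_domain(domain_spec(dx = 1, dy = 1, dz = 0.5))
#' sum(tumor_mask(g))
build_treatment_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  if (spec$tumor_shape != "disc") abort("treatment domain expects a disc tumor")
  if (min(spec$dz) > min(spec$layers$t)) {
    warn(sprintf(
      "axial voxel size (%.3g mm) exceeds the thinnest layer (%s, %.3g mm); material assignment by voxel centre is coarse",
      min(spec$dz), spec$layers$name[which.min(spec$layers$t)], min(spec$layers$t)
    ))
  }
  x <- grid_axis(spec$cylinder_radius, spec$dx)
  y <- grid_axis(spec$cylinder_radius, spec$dy)
  z <- cumsum(spec$dz) - spec$dz / 2
  nx <- length(x); ny <- length(y); nz <- length(z)

  r2 <- outer(x^2, y^2, `+`)
  inside <- r2 <= spec$cylinder_radius^2 + 1e-9
  bounds <- cumsum(c(0, spec$layers$t))
  layer_of_z <- findInterval(z, bounds, rightmost.closed = TRUE)

  ids <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) ids[, , k] <- ifelse(inside, layer_of_z[k], 0L)

  tumor_id <- nrow(spec$layers) + 1L
  in_disc_xy <- r2 <= spec$tumor_radius^2 + 1e-9
  z_lo <- spec$tumor_top_offset
  z_hi <- spec$tumor_top_offset + spec$tumor_depth_extent
  for (k in which(z >= z_lo & z <= z_hi)) {
    sl <- ids[, , k]
    sl[in_disc_xy & sl > 0L] <- tumor_id
    ids[, , k] <- sl
  }

  materials <- dplyr::bind_rows(spec$layers, spec$tumor)
  materials$id <- seq_len(nrow(materials))
  new_material_grid(ids, materials, spec, x, y, z, tumor_id)
}

#' Build the voxelized validation domain
#'
#' Homogeneous tissue cylinder with a spherical tumor at its centre, used
#' by the verification scenarios.
#'
#' @param spec A [domain_spec()] with `tumor_shape = "sphere"`, e.g. from
#'   [validation_domain_spec()].
#' @return A `material_grid`.
#' @export
build_validation_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  if (spec$tumor_shape != "sphere") abort("validation domain expects a spherical tumor")
  x <- grid_axis(spec$cylinder_radius, spec$dx)
  y <- grid_axis(spec$cylinder_radius, spec$dy)
  z <- cumsum(spec$dz) - spec$dz / 2
  nx <- length(x); ny <- length(y); nz <- length(z)
  zc <- spec$cylinder_depth / 2

  r2 <- outer(x^2, y^2, `+`)
  inside <- r2 <= spec$cylinder_radius^2 + 1e-9
  bounds <- cumsum(c(0, spec$layers$t))
  layer_of_z <- findInterval(z, bounds, rightmost.closed = TRUE)
  ids <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) ids[, , k] <- ifelse(inside, layer_of_z[k], 0L)

  tumor_id <- nrow(spec$layers) + 1L
  rt2 <- spec$tumor_radius^2 + 1e-9
  for (k in seq_len(nz)) {
    d2 <- r2 + (z[k] - zc)^2
    sl <- ids[, , k]
    sl[d2 <= rt2 & sl > 0L] <- tumor_id
    ids[, , k] <- sl
  }

  materials <- dplyr::bind_rows(spec$layers, spec$tumor)
  materials$id <- seq_len(nrow(materials))
  new_material_grid(ids, materials, spec, x, y, z, tumor_id)
}

#' Build a rectangular slab grid for analytic benchmarks
#'
#' A box-shaped grid with no void region, used by the analytic oracle
#' fixtures (absorbing slabs, point heat release, bilayer conduction).
#' Material ids default to 1 everywhere; pass an `ids` array or a
#' `split_z` index to create layered slabs.
#'
#' @param nx,ny,nz Grid dimensions.
#' @param dx,dy,dz Voxel sizes (mm); `dz` may be a vector of length `nz`.
#' @param materials Property table (rows indexed by material id).
#' @param ids Optional integer array of material ids.
#' @param split_z If given, voxels with z-index greater than `split_z` take
#'   material 2.
#' @return A `material_grid` whose cylinder mask covers the whole box.
#' @export
slab_grid <- function(nx, ny, nz, dx = 1, dy = 1, dz = 1,
                      materials = tumor_baseline(), ids = NULL,
                      split_z = NULL) {
  if (length(dz) == 1) dz <- rep(dz, nz)
  stopifnot(length(dz) == nz)
  if (is.null(ids)) {
    ids <- array(1L, c(nx, ny, nz))
    if (!is.null(split_z)) ids[, , seq_len(nz) > split_z] <- 2L
  }
  materials$id <- seq_len(nrow(materials))
  spec <- structure(
    list(
      cylinder_radius = Inf, cylinder_depth = sum(dz),
      dx = dx, dy = dy, dz = dz,
      tumor_shape = "disc", tumor_radius = 0, tumor_depth_extent = 0,
      tumor_top_offset = 0, layers = materials, tumor = materials[1, ]
    ),
    class = "domain_spec"
  )
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  y <- (seq_len(ny) - (ny + 1) / 2) * dy
  z <- cumsum(dz) - dz / 2
  g <- new_material_grid(ids, materials, spec, x, y, z, tumor_id = NA_integer_)
  g$cylinder_radius <- Inf
  g
}

#' @export
print.material_grid <- function(x, ...) {
  d <- dim(x$ids)
  cat(sprintf(
    "<material_grid> %d x %d x %d voxels (dx %.3g, dy %.3g, dz %.3g..%.3g mm)\n",
    d[1], d[2], d[3], x$dx, x$dy, min(x$dz), max(x$dz)
  ))
  cat(sprintf(
    "  materials: %s\n  tumor voxels: %d; void voxels: %d\n",
    paste(x$materials$name, collapse = ", "),
    sum(tumor_mask(x)), sum(x$ids == 0L)
  ))
  invisible(x)
}

#' Voxel masks of a material grid
#'
#' `tumor_mask()` marks tumor voxels, `inside_mask()` voxels inside the
#' tissue cylinder, and `normal_mask()` the non-tumor tissue voxels (all
#' skin layers). Tumor and normal masks are disjoint by construction.
#'
#' @param grid A `material_grid`.
#' @return A logical array of the grid's dimensions.
#' @export
tumor_mask <- function(grid) {
  if (is.na(grid$tumor_id)) array(FALSE, dim(grid$ids))
  else grid$ids == grid$tumor_id
}

#' @rdname tumor_mask
#' @export
inside_mask <- function(grid) grid$ids > 0L

#' @rdname tumor_mask
#' @export
normal_mask <- function(grid) inside_mask(grid) & !tumor_mask(grid)

#' Look up the material properties of one voxel
#'
#' @param grid A `material_grid`.
#' @param i,j,k Voxel indices (1-based).
#' @return A one-row tibble of material properties; void voxels return the
#'   sentinel material `"void"` with zero optical and thermal properties.
#' @export
material_at <- function(grid, i, j, k) {
  d <- dim(grid$ids)
  if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) {
    abort("voxel index out of bounds")
  }
  id <- grid$ids[i, j, k]
  if (id == 0L) {
    return(tibble::tibble(
      name = "void", t = NA_real_, k = 0, cv = 0, rho = 0,
      mu_a = 0, mu_s = 0, g = 0, id = 0L
    ))
  }
  grid$materials[grid$materials$id == id, ]
}

#' Index of the voxel at the tumor centre
#'
#' For a disc tumor this is the on-axis voxel nearest the tumor's
#' mid-depth; for a sphere, the voxel nearest the domain centre. Used as
#' the default probe for temperature traces.
#'
#' @param grid A `material_grid`.
#' @return Integer vector `c(i, j, k)`.
#' @export
tumor_center_index <- function(grid) {
  d <- dim(grid$ids)
  i <- which.min(abs(grid$x)); j <- which.min(abs(grid$y))
  zt <- if (grid$spec$tumor_shape == "sphere") grid$cylinder_depth / 2
        else grid$spec$tumor_top_offset + grid$spec$tumor_depth_extent / 2
  k <- which.min(abs(grid$z - zt))
  c(i, j, k)
}

#' Export a material grid to a legacy VTK file
#'
#' Writes the material ids and masks as an ASCII `RECTILINEAR_GRID` legacy
#' VTK file for inspection in ParaView or similar viewers.
#'
#' @param grid A `material_grid`.
#' @param path Output file.
#' @param field Optional numeric array (e.g. a temperature snapshot or an
#'   absorption map) written as an extra point field.
#' @param field_name Name for the extra field.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(grid, path, field = NULL, field_name = "field") {
  d <- dim(grid$ids)
  xb <- c(grid$x - grid$dx / 2, grid$x[d[1]] + grid$dx / 2)
  yb <- c(grid$y - grid$dy / 2, grid$y[d[2]] + grid$dy / 2)
  zb <- c(0, cumsum(grid$dz))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "photoheat material grid", "ASCII",
    "DATASET RECTILINEAR_GRID",
    sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
    sprintf("X_COORDINATES %d float", d[1] + 1), paste(xb, collapse = " "),
    sprintf("Y_COORDINATES %d float", d[2] + 1), paste(yb, collapse = " "),
    sprintf("Z_COORDINATES %d float", d[3] + 1), paste(zb, collapse = " "),
    sprintf("CELL_DATA %d", prod(d)),
    "SCALARS material_id int 1", "LOOKUP_TABLE default"
  ), con)
  writeLines(paste(as.integer(grid$ids), collapse = " "), con)
  writeLines(c("SCALARS tumor int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(tumor_mask(grid)), collapse = " "), con)
  if (!is.null(field)) {
    writeLines(c(sprintf("SCALARS %s float 1", field_name), "LOOKUP_TABLE default"), con)
    writeLines(paste(signif(as.numeric(field), 7), collapse = " "), con)
  }
  invisible(path)
}
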