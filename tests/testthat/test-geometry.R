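test_that("treatment domain assigns layers and tumor by voxel centre", {
  g <- build_treatment_domain(domain_spec(dx = 0.5, dy = 0.5))
  # default axial grid resolves the epidermis: centre at 0.06 mm, off-axis
  i10 <- which.min(abs(g$x - 10))
  j0 <- which.min(abs(g$y))
  k_epi <- which.min(abs(g$z - 0.06))
  expect_equal(material_at(g, i10, j0, k_epi)$name, "epidermis")
  # cumulative thicknesses put 0.6 mm depth in the reticular dermis
  k_ret <- which.min(abs(g$z - 0.6))
  expect_equal(material_at(g, i10, j0, k_ret)$name, "reticular_dermis")
  # on the beam axis at 1 mm depth the tumor overrides the layers
  i0 <- which.min(abs(g$x))
  k_mid <- which.min(abs(g$z - 1))
  expect_equal(material_at(g, i0, j0, k_mid)$name, "tumor")
  # tumor property bundle comes straight from the material table
  tum <- material_at(g, i0, j0, k_mid)
  expect_equal(tum$mu_a, 0.047)
  expect_equal(tum$mu_s, 0.883)
  expect_equal(tum$g, 0.8)
  # subcutaneous fat conductivity
  k_fat <- which.min(abs(g$z - 10))
  expect_equal(material_at(g, i10, j0, k_fat)$k, 0.19)
  # void sentinel outside the cylinder
  expect_equal(material_at(g, 1, 1, 1)$name, "void")
  expect_error(material_at(g, 0, 1, 1), "out of bounds")
})

test_that("masks partition the grid exactly and are axisymmetric", {
  g <- coarse_treatment_grid(1)
  total <- length(g$ids)
  expect_identical(sum(tumor_mask(g)) + sum(normal_mask(g)) + sum(g$ids == 0L),
                   total)
  expect_false(any(tumor_mask(g) & normal_mask(g)))
  expect_identical(g$ids, aperm(g$ids, c(2, 1, 3)))
})

test_that("tumor disc volume converges to the analytic cylinder volume", {
  g <- build_treatment_domain(domain_spec(dx = 0.1, dy = 0.1))
  # the disc lies entirely inside the fine axial region
  vol <- sum(tumor_mask(g)) * 0.1 * 0.1 * 0.04
  expect_lt(abs(vol / (pi * 5^2 * 2) - 1), 0.02)
})

test_that("validation domain places a central sphere in homogeneous tissue", {
  g <- build_validation_domain(validation_domain_spec(voxel = 1))
  ci <- tumor_center_index(g)
  expect_equal(material_at(g, ci[1], ci[2], ci[3])$name, "tumor")
  # a voxel just beyond the radius is plain tissue
  i_out <- which.min(abs(g$x - 5.6))
  expect_equal(material_at(g, i_out, ci[2], ci[3])$name, "tissue")
  vol <- sum(tumor_mask(g)) * 1
  expect_lt(abs(vol / (4 / 3 * pi * 5^3) - 1), 0.05)
})

test_that("invalid geometries are rejected and coarse voxels warned about", {
  expect_error(domain_spec(tumor_radius = 20), "beyond the domain")
  expect_error(
    domain_spec(tumor_shape = "sphere", tumor_radius = 12, dx = 1, dy = 1, dz = 1),
    "fit inside"
  )
  expect_error(domain_spec(dz = 0.3), "divide")
  expect_warning(build_treatment_domain(domain_spec(dx = 1, dy = 1, dz = 1)),
                 "thinnest layer")
})

test_that("layer thicknesses tile the cylinder depth", {
  spec <- domain_spec(dx = 0.5, dy = 0.5)
  expect_equal(sum(spec$layers$t), spec$cylinder_depth)
  expect_equal(sum(spec$dz), spec$cylinder_depth)
})
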