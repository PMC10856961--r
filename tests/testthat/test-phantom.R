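test_that("analytic volumes of single primitives are exact", {
  sph <- make_phantom(list(list(type = "sphere", center = c(0, 1, 0),
                                radius = 0.1)))
  expect_equal(sph$reference_volume_liters, 4 / 3 * pi * 0.1^3 * 1000,
               tolerance = 1e-12)
  cyl <- make_phantom(list(list(type = "cylinder", p0 = c(0, 0.2, 0),
                                p1 = c(0, 1.2, 0), radius = 0.15)))
  expect_equal(cyl$reference_volume_liters, pi * 0.15^2 * 1 * 1000,
               tolerance = 1e-12)
  cap <- make_phantom(list(list(type = "capsule", p0 = c(0, 0.3, 0),
                                p1 = c(0, 1.0, 0), radius = 0.08)))
  expect_equal(cap$reference_volume_liters,
               (pi * 0.08^2 * 0.7 + 4 / 3 * pi * 0.08^3) * 1000,
               tolerance = 1e-12)
})

test_that("disjoint-part phantoms sum analytic part volumes exactly", {
  ph <- make_phantom(list(
    list(type = "sphere", center = c(-0.4, 0.5, 0), radius = 0.1),
    list(type = "sphere", center = c(0.4, 0.5, 0), radius = 0.15)
  ))
  expect_equal(ph$reference_volume_liters,
               4 / 3 * pi * (0.1^3 + 0.15^3) * 1000, tolerance = 1e-12)
})

test_that("voxelized volume of overlapping parts agrees across resolutions", {
  # two overlapping spheres: exact union volume known in closed form
  r <- 0.1; d <- 0.12
  ph <- make_phantom(list(
    list(type = "sphere", center = c(-d / 2, 0.5, 0), radius = r),
    list(type = "sphere", center = c(d / 2, 0.5, 0), radius = r)
  ), voxel_mm = 2)
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)  # lens overlap
  exact <- (2 * 4 / 3 * pi * r^3 - lens) * 1000
  expect_equal(ph$reference_volume_liters, exact, tolerance = 5e-3)
  # humanoid preset: 3 mm voxelization within 0.5% of the 1 mm oracle
  hum3 <- humanoid_phantom(voxel_mm = 3)
  v1 <- bodyscan:::phantom_voxel_volume_l(hum3$prims, voxel_mm = 1)
  expect_lt(abs(hum3$reference_volume_liters - v1) / v1, 0.005)
})

test_that("humanoid preset has plausible adult volume", {
  hum <- humanoid_phantom(voxel_mm = 3)
  expect_gt(hum$reference_volume_liters, 50)
  expect_lt(hum$reference_volume_liters, 90)
})

test_that("invalid phantom specs are rejected", {
  expect_error(make_phantom(list()), class = "invalid_spec")
  expect_error(
    make_phantom(list(list(type = "sphere", center = c(0, 1, 0),
                           radius = -0.1))),
    class = "invalid_spec")
  expect_error(
    make_phantom(list(list(type = "cylinder", p0 = c(0, 0, 0),
                           p1 = c(0, 3, 0), radius = 0.1))),
    class = "invalid_spec")  # exceeds the 2.2 m scene box
})
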