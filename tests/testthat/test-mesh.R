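test_that("unit cube volume is exactly 1000 litres", {
  expect_identical(mesh_volume(unit_cube_mesh()), 1000)
})

test_that("icosphere volume approaches the closed form", {
  m <- icosphere(r = 0.1, level = 4)
  wt <- is_watertight(m)
  expect_true(wt$watertight && wt$oriented)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * 0.1^3 * 1000) /
              (4 / 3 * pi * 0.1^3 * 1000), 0.005)
})

test_that("a flipped face makes the volume undefined", {
  m <- unit_cube_mesh()
  m$faces[3, ] <- m$faces[3, c(1, 3, 2)]
  expect_error(mesh_volume(m), class = "volume_undefined")
})

test_that("mesh volume is invariant under rigid motion", {
  m <- icosphere(r = 0.08, level = 3)
  v0 <- mesh_volume(m)
  set.seed(9)
  for (i in 1:5) {
    w <- rnorm(3); w <- w / sqrt(sum(w^2)) * runif(1, 0, pi)
    R <- bodyscan:::rodrigues(w)
    t_ <- rnorm(3, sd = 2)
    m2 <- body_mesh(sweep(m$vertices %*% t(R), 2, t_, `+`), m$faces)
    expect_equal(mesh_volume(m2), v0, tolerance = 1e-9)
  }
})

test_that("clean_mesh removes small floating components without touching the
           main surface", {
  sph <- icosphere(r = 0.1, level = 3)
  v0 <- mesh_volume(sph)
  cube <- unit_cube_mesh()
  cube$vertices <- cube$vertices * 0.01 + 0.5   # 1 cm cube far from sphere
  combined <- body_mesh(rbind(sph$vertices, cube$vertices),
                        rbind(sph$faces, cube$faces + nrow(sph$vertices)))
  out <- clean_mesh(combined, min_component_frac = 0.01, smooth_iters = 0)
  expect_equal(mesh_volume(out), v0, tolerance = 1e-9)
})

test_that("clean_mesh with no work to do is the identity", {
  sph <- icosphere(r = 0.1, level = 2)
  out <- clean_mesh(sph, smooth_iters = 0)
  expect_equal(out$vertices, sph$vertices)
  expect_equal(out$faces, sph$faces)
})

test_that("a deleted face is refilled watertight with unchanged volume", {
  sph <- icosphere(r = 0.1, level = 3)
  v0 <- mesh_volume(sph)
  holed <- body_mesh(sph$vertices, sph$faces[-100, , drop = FALSE])
  expect_false(is_watertight(holed)$watertight)
  fixed <- clean_mesh(holed, smooth_iters = 0)
  wt <- is_watertight(fixed)
  expect_true(wt$watertight && wt$oriented)
  expect_lt(abs(mesh_volume(fixed) - v0) / v0, 0.001)
})

test_that("Taubin smoothing changes volume by well under one percent", {
  sph <- icosphere(r = 0.1, level = 3)
  sm <- clean_mesh(sph, smooth_iters = 5)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(sph)) / mesh_volume(sph), 0.01)
})

test_that("PLY round-trips meshes and clouds in both formats", {
  m <- icosphere(r = 0.05, level = 1)
  for (fmt in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_ply(m, f, format = fmt)
    m2 <- read_ply(f)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(m2$faces, m$faces)
  }
  cl <- point_cloud(matrix(rnorm(60), 20, 3),
                    normals = matrix(1 / sqrt(3), 20, 3))
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl, f)
  cl2 <- read_ply(f)
  expect_equal(cl2$points, cl$points, tolerance = 1e-6)
  expect_equal(cl2$normals, cl$normals, tolerance = 1e-6)
})
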