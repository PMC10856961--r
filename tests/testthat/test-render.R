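test_that("central depth pixel of an on-axis sphere matches geometry", {
  sph <- make_phantom(list(list(type = "sphere", center = c(0, 1.1, 0),
                                radius = 0.2)))
  cams <- default_cameras()
  rv <- render_views(sph, cams$anterior, cams$posterior,
                     platform_height_m = 0, seed = 1)
  # principal pixel (u = cx, v = cy): 0-based (256, 212) -> R index [213, 257]
  expect_equal(rv$anterior$depth[213, 257], 1700L)  # (1.9 - 0.2) m in mm
  expect_equal(rv$posterior$depth[213, 257], 1700L)
})

test_that("noiseless depth equals the analytic ray intersection to < 1 mm", {
  sph <- make_phantom(list(list(type = "sphere", center = c(0, 1.1, 0),
                                radius = 0.2)))
  cams <- default_cameras()
  rv <- render_views(sph, cams$anterior, cams$posterior,
                     platform_height_m = 0, seed = 1)
  sc <- rv$anterior
  hit <- which(true_body_mask(sc), arr.ind = TRUE)
  u <- hit[, 2] - 1; v <- hit[, 1] - 1
  cam <- sc$camera
  # analytic z-depth of the ray through each pixel centre: solve
  # |o + z * d - c|^2 = r^2 in camera coordinates with d = ((u-cx)/fx,
  # (v-cy)/fy, 1); sphere centre in camera frame
  cc <- cam$pose[1:3, 1:3] %*% c(0, 1.1, 0) + cam$pose[1:3, 4]
  dx <- (u - cam$cx) / cam$fx; dy <- (v - cam$cy) / cam$fy
  A <- dx^2 + dy^2 + 1
  B <- -2 * (dx * cc[1] + dy * cc[2] + cc[3])
  C <- sum(cc^2) - 0.2^2
  z <- (-B - sqrt(B^2 - 4 * A * C)) / (2 * A)
  expect_lt(max(abs(sc$depth[hit] - z * 1000)), 1)
})

test_that("rendering is deterministic in (phantom, cameras, seed)", {
  fx <- scene_fixture()
  cams <- default_cameras(noise_sigma_mm = 2, dropout_rate = 0.05)
  a <- render_views(fx$phantom, cams$anterior, cams$posterior, seed = 7)
  b <- render_views(fx$phantom, cams$anterior, cams$posterior, seed = 7)
  expect_identical(a$anterior$depth, b$anterior$depth)
  expect_identical(a$posterior$depth, b$posterior$depth)
  expect_identical(a$anterior$ir, b$anterior$ir)
  c <- render_views(fx$phantom, cams$anterior, cams$posterior, seed = 8)
  expect_false(identical(a$anterior$depth, c$anterior$depth))
})

test_that("dropout zeroes body pixels at the configured binomial rate", {
  fx <- scene_fixture()
  cams <- default_cameras(noise_sigma_mm = 0, dropout_rate = 0.05)
  rv <- render_views(fx$phantom, cams$anterior, cams$posterior, seed = 3)
  sc <- rv$anterior
  body <- true_body_mask(sc)
  n <- sum(body)
  zeroed <- sum(sc$depth[body] == 0)
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(zeroed, bounds[1])
  expect_lte(zeroed, bounds[2])
})

test_that("platform is bright in IR but returns no depth", {
  fx <- scene_fixture()
  sc <- fx$views$anterior
  plat <- sc$labels == sc$platform_label
  expect_gt(sum(plat), 0)
  expect_true(all(sc$depth[plat] == 0))
  expect_true(all(sc$ir[plat] > sc$ir[sc$labels == 0][1]))
})

test_that("a phantom outside both frusta raises an empty-render error", {
  ph <- make_phantom(list(list(type = "sphere", center = c(0, 2.1, 0),
                               radius = 0.02)))
  cam_up <- camera_model(pose = look_at_pose(c(0, 0.05, 1.9), c(0, 0.05, 0)))
  expect_error(
    render_views(ph, cam_up, cam_up, platform_height_m = 0, seed = 1),
    class = "empty_render")
})

test_that("scene files round-trip bit-exactly with full-precision sidecar", {
  ph <- make_phantom(list(list(type = "sphere", center = c(0, 1.1, 0),
                               radius = 0.25)))
  cams <- default_cameras(noise_sigma_mm = 1.5, dropout_rate = 0.05)
  rv <- render_views(ph, cams$anterior, cams$posterior, seed = 3)
  pre <- file.path(withr::local_tempdir(), "t1_anterior")
  write_scene(rv$anterior, pre)
  back <- read_scene(pre)
  expect_identical(back$depth, rv$anterior$depth)
  expect_identical(back$ir, rv$anterior$ir)
  expect_identical(back$camera$fx, rv$anterior$camera$fx)
  expect_identical(back$camera$pose, rv$anterior$camera$pose)
  expect_identical(back$camera$noise_sigma_mm,
                   rv$anterior$camera$noise_sigma_mm)
})

test_that("depth beyond the 16-bit millimetre range refuses to serialize", {
  fx <- scene_fixture()
  sc <- fx$views$anterior
  sc$depth[1, 1] <- 70000L   # 70 m
  expect_error(write_scene(sc, file.path(withr::local_tempdir(), "bad")),
               class = "range_error")
})
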