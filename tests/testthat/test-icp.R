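# asymmetric test cloud: registration is well-posed (unlike a sphere)
blob_cloud <- function(n = 4000, seed = 42) {
  set.seed(seed)
  p <- cbind(rnorm(n, sd = 0.3), rnorm(n, sd = 0.8), rnorm(n, sd = 0.15))
  p <- p + 0.2 * sin(5 * p[, 2])
  point_cloud(p)
}

rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
}

test_that("self-registration returns the identity", {
  cl <- blob_cloud(3000)
  res <- align_views(cl, cl, subsample_voxel = 0.02)
  expect_lt(bodyscan:::rotation_angle_deg(res$transform$rotation) * pi / 180,
            1e-6)
  expect_lt(sqrt(sum(res$transform$translation^2)), 1e-6)
  expect_equal(nrow(res$merged$points), 2 * nrow(cl$points))
})

test_that("a constructed 5 degree / 2 cm motion is recovered", {
  cl <- blob_cloud()
  R5 <- rot_y(5)
  tv <- c(0.02, 0, 0.005)
  post <- point_cloud(t(R5 %*% t(cl$points)) + rep(tv, each = nrow(cl$points)))
  res <- align_views(cl, post, subsample_voxel = 0.02)
  Rrec <- res$transform$rotation
  # recovered transform must invert the constructed motion
  expect_lt(bodyscan:::rotation_angle_deg(Rrec %*% R5), 0.05)
  expect_lt(sqrt(sum((Rrec %*% tv + res$transform$translation)^2)), 1e-3)
})

test_that("disjoint distant clusters fail registration", {
  set.seed(1)
  a <- point_cloud(matrix(rnorm(300, sd = 0.05), ncol = 3))
  b <- point_cloud(matrix(rnorm(300, sd = 0.05), ncol = 3) + 5)
  expect_error(align_views(a, b), class = "registration_failure")
})

test_that("rigid transforms validate orthonormality", {
  expect_error(rigid_transform(matrix(1, 3, 3)), class = "invalid_transform")
  skew <- rot_y(10); skew[1, 1] <- skew[1, 1] + 1e-6
  expect_error(rigid_transform(skew), class = "invalid_transform")
  tf <- rigid_transform(rot_y(30), c(1, 2, 3))
  p <- matrix(rnorm(30), 10, 3)
  q <- bodyscan:::apply_transform(p, tf)
  d_orig <- dist(p); d_new <- dist(q)
  expect_equal(as.numeric(d_new), as.numeric(d_orig), tolerance = 1e-12)
})

test_that("opposed-view registration with a calibration prior stays put on
           aligned clouds", {
  fx <- scene_fixture()
  pv <- function(sc, cam) {
    m <- clean_mask(exclude_platform(segment_body(sc$ir), sc$depth))
    backproject(apply_mask(sc$depth, m), cam)
  }
  ca <- pv(fx$views$anterior, fx$cams$anterior)
  cp <- pv(fx$views$posterior, fx$cams$posterior)
  res <- align_views(ca, cp, prior_sigma_t = 0.005, prior_sigma_deg = 0.5)
  expect_lt(sqrt(sum(res$transform$translation^2)), 0.01)
  expect_lt(bodyscan:::rotation_angle_deg(res$transform$rotation), 1)
})
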