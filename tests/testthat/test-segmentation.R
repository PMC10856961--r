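test_that("segmentation + platform removal recovers the true silhouette exactly
           on noiseless frames", {
  fx <- scene_fixture()
  for (view in c("anterior", "posterior")) {
    sc <- fx$views[[view]]
    mask <- segment_body(sc$ir)
    mask <- exclude_platform(mask, sc$depth)
    truth <- true_body_mask(sc)
    expect_identical(unclass(bodyscan:::unclass_mask(mask)), unclass(truth))
  }
})

test_that("degenerate IR frames are handled per contract", {
  expect_error(segment_body(matrix(0, 20, 20)), class = "no_body_found")
  # one uniform bright rectangle -> mask is that rectangle
  ir <- matrix(5, 60, 60)
  ir[10:40, 20:45] <- 200
  m <- segment_body(ir)
  expected <- matrix(FALSE, 60, 60)
  expected[10:40, 20:45] <- TRUE
  expect_identical(unclass(bodyscan:::unclass_mask(m)), expected)
  # explicit seed outside the foreground
  expect_error(segment_body(ir, seed_point = c(5, 5)), class = "bad_seed")
})

test_that("platform-band rules remove platform, keep feet", {
  fx <- scene_fixture()
  sc <- fx$views$anterior
  mask <- segment_body(sc$ir)
  out <- exclude_platform(mask, sc$depth)
  plat <- sc$labels == sc$platform_label
  feet <- true_body_mask(sc) & row(sc$depth) > 0.8 * nrow(sc$depth)
  expect_equal(sum(out & plat), 0)
  expect_true(all(out[feet]))
})

test_that("exclude_platform leaves masks without bottom regions unchanged and
           empties platform-only frames with a warning", {
  m <- matrix(FALSE, 40, 40)
  m[5:15, 10:20] <- TRUE
  depth <- matrix(0L, 40, 40)
  depth[m] <- 1500L
  bm <- body_mask(m)
  expect_identical(exclude_platform(bm, depth), bm)
  # platform only: bright band at the bottom with no depth return
  p <- matrix(FALSE, 40, 40)
  p[35:40, ] <- TRUE
  expect_warning(out <- exclude_platform(body_mask(p), matrix(0L, 40, 40)),
                 class = "platform_only")
  expect_equal(sum(out), 0)
})

test_that("clean_mask removes salt noise with little area change", {
  fx <- scene_fixture()
  sc <- fx$views$anterior
  mask <- exclude_platform(segment_body(sc$ir), sc$depth)
  noisy <- bodyscan:::unclass_mask(mask)
  set.seed(5)
  salt <- sample(which(!noisy), 300)
  noisy[salt] <- TRUE
  cleaned <- clean_mask(body_mask(noisy), open_radius_px = 1,
                        close_radius_px = 2)
  base <- clean_mask(mask, open_radius_px = 1, close_radius_px = 2)
  expect_lt(abs(sum(cleaned) - sum(base)) / sum(base), 0.02)
})

test_that("clean_mask honours identity, tie-break and emptiness contracts", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  bm <- body_mask(m)
  expect_identical(
    unclass(bodyscan:::unclass_mask(
      clean_mask(bm, open_radius_px = 0, close_radius_px = 0,
                 min_component_px = 0))),
    m)
  # two equal-size components: keep the one with the smaller row-major
  # first-pixel index
  m2 <- matrix(FALSE, 30, 30)
  m2[20:22, 3:5] <- TRUE    # first pixel later in row-major order
  m2[3:5, 20:22] <- TRUE    # rows come first -> this wins
  out <- clean_mask(body_mask(m2), open_radius_px = 0, close_radius_px = 0,
                    min_component_px = 0)
  expect_true(all(out[3:5, 20:22]))
  expect_equal(sum(out), 9)
  # cleaning that empties the mask errors
  tiny <- matrix(FALSE, 30, 30)
  tiny[15, 15] <- TRUE
  expect_error(clean_mask(body_mask(tiny), min_component_px = 10),
               class = "empty_mask")
})

test_that("mask cleaning is idempotent", {
  fx <- scene_fixture()
  sc <- fx$views$anterior
  m1 <- clean_mask(exclude_platform(segment_body(sc$ir), sc$depth))
  m2 <- clean_mask(m1)
  expect_identical(unclass(bodyscan:::unclass_mask(m1)),
                   unclass(bodyscan:::unclass_mask(m2)))
})

test_that("apply_mask fuses depth and mask per contract", {
  depth <- matrix(1500L, 10, 10)
  depth[1, 1] <- 0L
  depth[2, 2] <- 100L      # below near clip
  full <- body_mask(matrix(TRUE, 10, 10))
  md <- apply_mask(depth, full)
  expect_equal(md[1, 1], 0L)
  expect_equal(md[2, 2], 0L)
  expect_equal(md[5, 5], 1500L)
  none <- body_mask(matrix(FALSE, 10, 10))
  expect_true(all(apply_mask(depth, none) == 0L))
  expect_error(apply_mask(depth, body_mask(matrix(TRUE, 5, 5))),
               class = "shape_error")
  # on synthetic frames the nonzero set is the intersection of true hits
  # and the mask
  fx <- scene_fixture()
  sc <- fx$views$anterior
  mask <- clean_mask(exclude_platform(segment_body(sc$ir), sc$depth))
  md2 <- apply_mask(sc$depth, mask,
                    near_mm = sc$camera$near * 1000,
                    far_mm = sc$camera$far * 1000)
  expect_identical(which(md2 > 0),
                   which(true_body_mask(sc) & bodyscan:::unclass_mask(mask)))
})
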