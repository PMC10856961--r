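make_design <- function(n = 100, seed = 61) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  data.frame(y = 2 + 1.5 * x1 + 0.4 * x2 + rnorm(n, sd = 0.5),
             x1 = x1, x2 = x2, x3 = x3)
}

test_that("exhaustive enumeration covers every non-empty subset", {
  d <- make_design()
  out <- best_subsets(d, "y", c("x1", "x2", "x3"))
  expect_equal(nrow(out), 7)   # 2^3 - 1
  expect_setequal(
    out$predictors,
    c("x1", "x2", "x3", "x1,x2", "x1,x3", "x2,x3", "x1,x2,x3"))
})

test_that("an exact linear response ranks its predictor first with R2 = 1", {
  set.seed(9)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- 3 * d$x1 - 1
  out <- best_subsets(d, "y", c("x1", "x2"))
  expect_equal(out$predictors[1], "x1")
  expect_equal(out$r2[1], 1, tolerance = 1e-12)
})

test_that("full-model Mallows Cp equals p + 1 exactly and the noise-only
           predictor loses", {
  d <- make_design()
  d$y <- 2 + 1.5 * d$x1 + rnorm(nrow(d), sd = 0.4)   # x2, x3 pure noise
  out <- best_subsets(d, "y", c("x1", "x2", "x3"))
  full <- out[out$predictors == "x1,x2,x3", ]
  expect_equal(full$mallows_cp, 4, tolerance = 1e-9)   # p + 1 with p = 3
  two <- best_subsets(d, "y", c("x1", "x2"))
  expect_equal(two$mallows_cp[two$predictors == "x1,x2"], 3,
               tolerance = 1e-9)
  best1 <- two[two$p == 1, ]
  expect_equal(best1$predictors[which.max(best1$r2)], "x1")
})

test_that("subset statistics match the normal-equations oracle", {
  d <- make_design(n = 60, seed = 77)
  out <- best_subsets(d, "y", c("x1", "x2", "x3"))
  n <- nrow(d)
  full_o <- ols_oracle(d[, c("x1", "x2", "x3")], d$y)
  mse_full <- full_o$rss / (n - 4)
  for (i in seq_len(nrow(out))) {
    sel <- strsplit(out$predictors[i], ",")[[1]]
    o <- ols_oracle(d[, sel, drop = FALSE], d$y)
    expect_equal(out$r2[i], o$r2, tolerance = 1e-9)
    p <- length(sel)
    expect_equal(out$adjusted_r2[i],
                 1 - (1 - o$r2) * (n - 1) / (n - p - 1), tolerance = 1e-9)
    expect_equal(out$mallows_cp[i], o$rss / mse_full - n + 2 * (p + 1),
                 tolerance = 1e-9)
    expect_equal(sort(unname(out$coefficients[[i]])), sort(o$coef),
                 tolerance = 1e-9)
    expect_lte(out$adjusted_r2[i], out$r2[i])
  }
})

test_that("adjusted-R2 ranking never puts a worse superset above its subset", {
  d <- make_design(n = 40, seed = 33)
  out <- best_subsets(d, "y", c("x1", "x2", "x3"), criterion = "adjusted_r2")
  rank_of <- function(p) which(out$predictors == p)
  subsets_of <- function(p) {
    sel <- strsplit(p, ",")[[1]]
    unlist(lapply(seq_len(length(sel) - 1), function(k)
      apply(utils::combn(sel, k), 2, paste, collapse = ",")))
  }
  for (p in out$predictors[out$p > 1]) {
    for (s in subsets_of(p)) {
      if (out$adjusted_r2[rank_of(p)] < out$adjusted_r2[rank_of(s)])
        expect_gt(rank_of(p), rank_of(s))
    }
  }
})

test_that("degenerate designs are rejected or skipped", {
  d <- make_design(n = 4)
  expect_error(best_subsets(d, "y", c("x1", "x2", "x3")),
               class = "input_error")
  d2 <- make_design(n = 30)
  d2$x3 <- d2$x1            # collinear full model
  expect_error(best_subsets(d2, "y", c("x1", "x3")), class = "input_error")
})
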