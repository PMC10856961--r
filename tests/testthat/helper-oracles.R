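# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ANOVA mean squares come from stats::aov, OLS
# from explicit normal equations, volumes from closed forms.

# two-way ANOVA mean squares via aov (long format), for the ICC oracle
aov_mean_squares <- function(ratings) {
  d <- data.frame(
    y = as.vector(ratings),
    subj = factor(rep(seq_len(nrow(ratings)), ncol(ratings))),
    rater = factor(rep(seq_len(ncol(ratings)), each = nrow(ratings)))
  )
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  list(msr = tab["subj", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

icc21_oracle <- function(ratings) {
  ms <- aov_mean_squares(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

icc31_oracle <- function(ratings) {
  ms <- aov_mean_squares(ratings)
  k <- ncol(ratings)
  (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
}

# OLS through explicit normal equations (no lm)
ols_oracle <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  fitted <- Xd %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(coef = as.numeric(beta), rss = rss, r2 = 1 - rss / tss)
}

# replicate-selection oracle: brute-force over all pairs with the
# documented tie-breaks
select_replicates_oracle <- function(values) {
  pairs <- utils::combn(length(values), 2, simplify = FALSE)
  diffs <- vapply(pairs, function(p) abs(values[p[1]] - values[p[2]]),
                  numeric(1))
  cand <- pairs[diffs == min(diffs)]
  if (length(cand) > 1) {
    dmed <- vapply(cand, function(p) abs(mean(values[p]) - median(values)),
                   numeric(1))
    cand <- cand[dmed == min(dmed)]
  }
  mean(values[cand[[1]]])
}

# unit icosphere subdivided `level` times, radius r
icosphere <- function(r = 0.1, level = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
    2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
    4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
    5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2
  ), ncol = 3, byrow = TRUE)
  for (l in seq_len(level)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  # wind every face outward (valid for a convex solid centred at origin)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
           (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
           (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    if (sum(n * (a + b + c)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  v <- v * r
  dimnames(v) <- NULL
  body_mesh(v, f)
}

# consistently wound unit cube (12 triangles, outward normals)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 1.0
  dimnames(v) <- NULL
  f <- matrix(c(1, 2, 4, 1, 4, 3, 5, 8, 6, 5, 7, 8, 1, 6, 2, 1, 5, 6,
                3, 4, 8, 3, 8, 7, 1, 3, 7, 1, 7, 5, 2, 6, 8, 2, 8, 4),
              ncol = 3, byrow = TRUE)
  body_mesh(v, f)
}

# small shared scene fixture, rendered once per test run
scene_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hum <- humanoid_phantom(voxel_mm = 3)
      cams <- default_cameras()
      rv <- render_views(hum, cams$anterior, cams$posterior, seed = 1)
      cache <<- list(phantom = hum, cams = cams, views = rv)
    }
    cache
  }
})
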