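#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#'   (tolerance 1e-9).
#' @param translation Length-3 numeric vector (metres).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_bodyscan("invalid_transform",
                  "rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation %.4f m\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

apply_transform <- function(points, tf) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, `+`)
}

compose_transform <- function(a, b) {  # a after b
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

rotation_angle_deg <- function(R) {
  cth <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, cth))) * 180 / pi
}

#' Align anterior and posterior point clouds with ICP
#'
#' Trimmed iterative closest points: at each iteration the nearest
#' anterior neighbour of every (transformed) posterior point is found,
#' the worst `trim` fraction of matches and matches farther than
#' `max_correspondence` are rejected, anti-facing matches are rejected by
#' a normal-compatibility gate (when sensor viewpoints are available),
#' and the rigid motion is updated. Iteration stops when the RMS
#' residual changes by less than `tol` or after `max_iter` iterations.
#'
#' The default error metric is point-to-plane (residuals along the
#' target surface normals, solved by small-angle linearization). For two
#' opposed perspective views this choice matters: each camera sees
#' slightly less than half the body, so a physical never-observed
#' lateral band separates the two silhouette rims. Point-to-point ICP
#' closes that gap and drags the shells into each other, biasing the
#' registration; the gap is tangential to the rim surface planes, so
#' point-to-plane leaves it open while remaining sensitive to genuine
#' misalignment. `variant = "point_to_point"` (closed-form Kabsch
#' updates) is available for fully overlapping clouds.
#'
#' Clouds produced by [backproject()] are already expressed in the world
#' frame through the known camera extrinsics, so the default initial
#' transform is the identity; ICP refines the residual misalignment.
#'
#' @param anterior,posterior `point_cloud` objects.
#' @param init Initial `rigid_transform` applied to the posterior cloud.
#' @param max_iter,tol Iteration controls.
#' @param trim Fraction of worst correspondences rejected (default 0.1).
#' @param max_correspondence Correspondences farther than this (metres)
#'   are rejected outright (default 0.08). Two opposed half-shells
#'   overlap only along the silhouette rim; without this cutoff the
#'   far-apart front/back matches dominate and ICP collapses the shells.
#' @param overlap_threshold Registration fails if the median
#'   nearest-neighbour distance after `init` exceeds this (metres).
#' @param subsample_voxel Voxel size used to subsample both clouds for
#'   correspondence search (metres); the final transform is applied to
#'   the full posterior cloud.
#' @param variant `"point_to_plane"` (default) or `"point_to_point"`;
#'   see Details.
#' @param prior_sigma_t,prior_sigma_deg Standard deviations (metres,
#'   degrees) of a rig-calibration prior on the transform, centred at
#'   `init`. Default `Inf` (pure ICP). For opposed views this prior is
#'   essential: a convex body's two half-shells contain no genuinely
#'   shared surface, and they fit together *better* when interpenetrating
#'   — every data-driven criterion (trimmed, truncated, inlier count)
#'   prefers the collapse, so the stand-off axis is only determined by
#'   the extrinsic calibration. The pipeline therefore registers with a
#'   tight prior (MAP estimate) rather than treating calibration as a
#'   mere initial guess.
#' @return List with `transform` (the refined posterior-to-anterior
#'   `rigid_transform`), `merged` (`point_cloud`: anterior plus
#'   transformed posterior), `rms` (final trimmed RMS distance, metres)
#'   and `iterations`.
#' @export
align_views <- function(anterior, posterior, init = rigid_transform(),
                        max_iter = 50, tol = 1e-6, trim = 0.1,
                        max_correspondence = 0.08,
                        overlap_threshold = 0.25, subsample_voxel = 0.015,
                        variant = c("point_to_plane", "point_to_point"),
                        prior_sigma_t = Inf, prior_sigma_deg = Inf) {
  variant <- match.arg(variant)
  stopifnot(inherits(anterior, "point_cloud"), inherits(posterior, "point_cloud"))
  tgt_cl <- downsample_cloud(anterior, subsample_voxel)
  src_cl <- downsample_cloud(posterior, subsample_voxel)
  tgt <- tgt_cl$points
  src0 <- src_cl$points
  enough <- nrow(tgt) > 30 && nrow(src0) > 30
  tgt_n <- if (variant == "point_to_plane" && enough)
    estimate_normals(tgt_cl, k = 15)$normals else NULL
  # normal-compatibility gate: anti-facing front/back matches are never
  # genuine correspondences between opposed half-shells
  gate <- !is.null(tgt_cl$viewpoints) && !is.null(src_cl$viewpoints) && enough
  if (gate) {
    if (is.null(tgt_n)) tgt_gn <- estimate_normals(tgt_cl, k = 15)$normals
    else tgt_gn <- tgt_n
    src_n0 <- estimate_normals(src_cl, k = 15)$normals
  }
  if (variant == "point_to_plane" && is.null(tgt_n))
    variant <- "point_to_point"    # too few points for stable normals
  tf <- init
  src <- apply_transform(src0, tf)
  nn <- knn_points(src, tgt, 1L)
  if (stats::median(nn$dist[, 1]) > overlap_threshold)
    stop_bodyscan("registration_failure",
                  "clouds do not overlap after the initial transform")
  # Robust global objective for step acceptance: truncated squared
  # nearest-neighbour distances. The opposed shells contain a physically
  # unobserved rim band; closing it lowers naive correspondence error, so
  # a step is accepted only if this objective improves. Pairs beyond the
  # cap contribute a constant (a smooth robust loss still slopes there,
  # and the many far cross-shell pairs would out-vote the anchors), so
  # only genuinely double-observed surface shapes the optimum. The cap
  # anneals with the current alignment quality.
  prior_cost <- function(tfc, cap) {
    if (!is.finite(prior_sigma_t) && !is.finite(prior_sigma_deg)) return(0)
    dt <- sqrt(sum((tfc$translation - init$translation)^2))
    dth <- rotation_angle_deg(t(init$rotation) %*% tfc$rotation)
    cap^2 * ((dt / prior_sigma_t)^2 + (dth / prior_sigma_deg)^2)
  }
  eval_obj <- function(tfc, cap) {
    d <- knn_points(apply_transform(src0, tfc), tgt, 1L)$dist[, 1]
    mean(pmin(d^2, cap^2)) + prior_cost(tfc, cap)
  }
  iters <- 0L
  rms <- sqrt(mean(pmin(nn$dist[, 1], max_correspondence)^2))
  for (it in seq_len(max_iter)) {
    iters <- it
    nn <- knn_points(src, tgt, 1L)
    d <- nn$dist[, 1]
    # coarse-to-fine: early iterations admit wide matches to pull in any
    # initial misalignment; late iterations keep only near matches
    cutoff <- max(subsample_voxel, max_correspondence * 0.7^(it - 1))
    keep <- d <= min(stats::quantile(d, 1 - trim), cutoff)
    if (gate) {
      src_n <- src_n0 %*% t(tf$rotation)
      compat <- rowSums(src_n * tgt_gn[nn$idx[, 1], , drop = FALSE]) > 0.5
      keep <- keep & compat
    }
    if (sum(keep) < 6) break   # no usable overlap band; keep current tf
    b <- tgt[nn$idx[keep, 1], , drop = FALSE]
    cap <- max(subsample_voxel, 1.5 * stats::median(d[keep]))
    obj <- eval_obj(tf, cap)
    accepted <- FALSE
    lambda <- 0
    for (try in 1:3) {
      cand <- if (variant == "point_to_point") {
        kabsch(src0[keep, , drop = FALSE], b)
      } else {
        nb <- tgt_n[nn$idx[keep, 1], , drop = FALSE]
        compose_transform(
          point_to_plane_step(src[keep, , drop = FALSE], b, nb,
                              lambda = lambda), tf)
      }
      cand_obj <- eval_obj(cand, cap)
      if (cand_obj < obj - 1e-15) {
        tf <- cand
        accepted <- TRUE
        break
      }
      if (variant == "point_to_point") break   # closed form: nothing to damp
      lambda <- if (lambda == 0) 1e-2 else lambda * 100
    }
    if (!accepted) break
    src <- apply_transform(src0, tf)
    new_rms <- sqrt(mean(pmin(knn_points(src, tgt, 1L)$dist[, 1],
                              max_correspondence)^2))
    if (abs(rms - new_rms) < tol) { rms <- new_rms; break }
    rms <- new_rms
  }
  vp <- if (!is.null(anterior$viewpoints) && !is.null(posterior$viewpoints))
    rbind(anterior$viewpoints, apply_transform(posterior$viewpoints, tf))
  else NULL
  merged <- point_cloud(
    rbind(anterior$points, apply_transform(posterior$points, tf)),
    view = "merged", viewpoints = vp
  )
  list(transform = tf, merged = merged, rms = rms, iterations = iters)
}

# one linearized point-to-plane update: minimize sum(n . (p + w x p + t - q))^2
# with optional Levenberg damping of the 6x6 normal equations
point_to_plane_step <- function(p, q, n, lambda = 0) {
  cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
               p[, 3] * n[, 1] - p[, 1] * n[, 3],
               p[, 1] * n[, 2] - p[, 2] * n[, 1])
  A <- cbind(cxn, n)
  b <- -rowSums((p - q) * n)
  AtA <- crossprod(A)
  AtA <- AtA + lambda * mean(diag(AtA)) * diag(6)
  delta <- tryCatch(solve(AtA, crossprod(A, b)),
                    error = function(e) matrix(0, 6, 1))
  w <- delta[1:3]
  rigid_transform(rodrigues(w), delta[4:6])
}

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# closed-form least-squares rigid motion mapping a onto b
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}
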