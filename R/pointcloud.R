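#' 3D point cloud
#'
#' @param points N x 3 numeric matrix of world-frame coordinates (metres).
#' @param view Optional view label.
#' @param normals Optional N x 3 unit normal matrix.
#' @param viewpoints Optional N x 3 matrix of sensor positions from which
#'   each point was observed; clouds from [backproject()] carry these and
#'   they drive visibility-based normal orientation.
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(points, view = NA_character_, normals = NULL,
                        viewpoints = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (nrow(points) < 1)
    stop_bodyscan("empty_cloud", "point cloud needs at least one point")
  if (!all(is.finite(points)))
    stop_bodyscan("invalid_cloud", "non-finite coordinates in point cloud")
  if (!is.null(normals))
    stopifnot(is.matrix(normals), all(dim(normals) == dim(points)))
  if (!is.null(viewpoints))
    stopifnot(is.matrix(viewpoints), all(dim(viewpoints) == dim(points)))
  structure(list(points = points, normals = normals, view = view,
                 viewpoints = viewpoints),
            class = "point_cloud")
}

#' Back-project a masked depth image to a world-frame point cloud
#'
#' Each valid pixel `(u, v)` with depth `z` (mm) maps to camera
#' coordinates `x = (u - cx) z / fx`, `y = (v - cy) z / fy`, `z` (metres,
#' 0-based pixel coordinates), then to the world frame through the
#' inverse of the camera pose. The point count equals the valid-pixel
#' count.
#'
#' @param md A `masked_depth` (or any depth matrix in mm, 0 = invalid).
#' @param cam The `camera_model` that produced it.
#' @return A `point_cloud` in world coordinates.
#' @export
backproject <- function(md, cam) {
  stopifnot(is.matrix(md), inherits(cam, "camera_model"))
  idx <- which(md > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop_bodyscan("empty_cloud", "masked depth has no valid pixels")
  z <- md[idx] / 1000
  u <- idx[, 2] - 1                    # 0-based column -> u
  v <- idx[, 1] - 1                    # 0-based row -> v
  pc <- cbind((u - cam$cx) * z / cam$fx, (v - cam$cy) * z / cam$fy, z)
  R <- cam$pose[1:3, 1:3]
  t_ <- cam$pose[1:3, 4]
  pw <- sweep(pc, 2, t_) %*% R          # t(R) %*% (p_c - t), row-wise
  ctr <- camera_center(cam)
  point_cloud(pw, view = attr(md, "view") %||% NA_character_,
              viewpoints = matrix(ctr, nrow(pw), 3, byrow = TRUE))
}

#' Voxel-grid downsampling
#'
#' Averages points (and normals) within each cubic voxel; used to even
#' out the anisotropic sampling density of projective depth data before
#' normal estimation and reconstruction.
#'
#' @param cloud A `point_cloud`.
#' @param voxel Voxel edge length in metres.
#' @return A downsampled `point_cloud`.
#' @export
downsample_cloud <- function(cloud, voxel) {
  p <- cloud$points
  key <- interaction(floor(p[, 1] / voxel), floor(p[, 2] / voxel),
                     floor(p[, 3] / voxel), drop = TRUE)
  cnt <- as.vector(table(key)[levels(key)])
  q <- rowsum(p, key) / cnt
  nrm <- NULL
  if (!is.null(cloud$normals)) {
    nrm <- rowsum(cloud$normals, key) / cnt
    nn <- sqrt(rowSums(nrm^2))
    nrm <- nrm / pmax(nn, 1e-12)
  }
  vp <- if (!is.null(cloud$viewpoints))
    unname(as.matrix(rowsum(cloud$viewpoints, key) / cnt)) else NULL
  point_cloud(unname(as.matrix(q)), view = cloud$view, normals = nrm,
              viewpoints = vp)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", nrow(x$points),
              if (!is.null(x$normals)) " (with normals)" else "",
              if (!is.na(x$view)) paste0(", view ", x$view) else ""))
  invisible(x)
}
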