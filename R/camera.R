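#' Pinhole depth-camera model
#'
#' Intrinsics, image size, rigid pose and noise model of one IR/depth
#' camera. The pose is the camera-from-world rigid transform: a point
#' `p_w` in world coordinates maps to camera coordinates
#' `p_c = R p_w + t`, with the camera looking along `+z`, `x` to the
#' image right and `y` down (image rows grow downwards).
#'
#' Defaults are Kinect v2-class parameters (512 x 424 px, focal length
#' 365 px); the acquisition geometry the package emulates places two such
#' cameras about 1.9 m in front of and behind a standing subject.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels (inside the image).
#' @param width,height Image size in pixels.
#' @param pose 4x4 camera-from-world rigid transform (see [look_at_pose()]).
#' @param near,far Depth clip range in metres.
#' @param noise_sigma_mm Gaussian depth noise standard deviation (mm, >= 0).
#' @param dropout_rate Probability a valid depth pixel is zeroed, in \[0, 1).
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' cam$fx
#' @export
camera_model <- function(fx = 365, fy = 365, cx = 256, cy = 212,
                         width = 512L, height = 424L,
                         pose = diag(4), near = 0.5, far = 4.5,
                         noise_sigma_mm = 0, dropout_rate = 0) {
  stopifnot(is_scalar_number(fx), is_scalar_number(fy), fx > 0, fy > 0)
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width > 0, height > 0)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop_bodyscan("invalid_camera", "principal point must lie inside the image")
  stopifnot(is.matrix(pose), all(dim(pose) == c(4, 4)))
  R <- pose[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop_bodyscan("invalid_camera", "pose rotation must be a proper rotation")
  stopifnot(near > 0, far > near, noise_sigma_mm >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy, width = width, height = height,
         pose = pose, near = near, far = far,
         noise_sigma_mm = noise_sigma_mm, dropout_rate = dropout_rate),
    class = "camera_model"
  )
}

#' Camera-from-world pose looking from `eye` towards `target`
#'
#' Builds the 4x4 camera-from-world transform of a camera placed at `eye`
#' with its optical axis through `target`, image x to the right and image
#' y down (world `up` defines "up").
#'
#' @param eye,target,up Numeric length-3 world vectors.
#' @return 4x4 rigid transform matrix.
#' @export
look_at_pose <- function(eye, target, up = c(0, 1, 0)) {
  f <- target - eye
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * up[3] - f[3] * up[2],
         f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12)
    stop_bodyscan("invalid_camera", "view direction parallel to up vector")
  r <- r / nr
  d <- c(f[2] * r[3] - f[3] * r[2],   # image-down = f x r
         f[3] * r[1] - f[1] * r[3],
         f[1] * r[2] - f[2] * r[1])
  Rwc <- cbind(r, d, f)               # world directions of camera axes
  R <- t(Rwc)
  t_ <- -R %*% eye
  out <- rbind(cbind(R, t_), c(0, 0, 0, 1))
  dimnames(out) <- NULL
  out
}

#' Default anterior/posterior camera pair
#'
#' Two opposed cameras, each `distance` metres from the body axis at
#' height `height`, facing each other horizontally through the body. The
#' world frame is right-handed with +y up and the origin at the centre of
#' the standing platform.
#'
#' @param distance Stand-off from the body axis in metres (default 1.9).
#' @param height Camera height above the floor in metres.
#' @param noise_sigma_mm,dropout_rate Depth noise model, passed to
#'   [camera_model()].
#' @return Named list with elements `anterior` and `posterior`.
#' @export
default_cameras <- function(distance = 1.9, height = 1.1,
                            noise_sigma_mm = 0, dropout_rate = 0) {
  list(
    anterior = camera_model(
      pose = look_at_pose(c(0, height, distance), c(0, height, 0)),
      noise_sigma_mm = noise_sigma_mm, dropout_rate = dropout_rate),
    posterior = camera_model(
      pose = look_at_pose(c(0, height, -distance), c(0, height, 0)),
      noise_sigma_mm = noise_sigma_mm, dropout_rate = dropout_rate)
  )
}

camera_center <- function(cam) {
  R <- cam$pose[1:3, 1:3]
  as.numeric(-t(R) %*% cam$pose[1:3, 4])
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, fx=%.1f fy=%.1f, c=(%.1f, %.1f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  centre (%.3f, %.3f, %.3f) m, noise %.1f mm, dropout %.3f\n",
              camera_center(x)[1], camera_center(x)[2], camera_center(x)[3],
              x$noise_sigma_mm, x$dropout_rate))
  invisible(x)
}
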