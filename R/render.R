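#' Render anterior/posterior IR + depth views of a phantom
#'
#' Ray-casts the phantom (lifted onto a reflective standing platform) into
#' each camera, producing per view an 8-bit IR intensity frame and a
#' 16-bit depth frame in millimetres (0 = no return). Depth stores
#' camera-z, the convention under which pinhole back-projection
#' `x = (u - cx) z / fx` is exact. IR uses a two-level reflectance model:
#' dark background, bright body, brighter platform. The highly
#' reflective platform paint saturates the IR sensor, so platform pixels
#' are bright in IR but carry no depth return: depth frames hold phantom
#' geometry only. Gaussian depth noise (per-camera `noise_sigma_mm`) and
#' random dropout (`dropout_rate`) are applied from the single `seed`,
#' so rendering is a pure function of (phantom, cameras, platform,
#' seed).
#'
#' @param phantom A [make_phantom()] phantom (feet at y = 0; it is raised
#'   by `platform_height_m` onto the platform).
#' @param front,back `camera_model` objects for the anterior and posterior
#'   views (see [default_cameras()]).
#' @param platform_height_m Height of the standing platform in metres.
#' @param seed Integer seed driving noise and dropout.
#' @return List with elements `anterior` and `posterior`, each a
#'   `scene_render`: `ir` (integer matrix), `depth` (integer matrix, mm),
#'   `labels` (0 background, part index, or `platform_label`), `view`,
#'   `camera`, `seed`. `labels` is the renderer's ground-truth oracle:
#'   `labels > 0 & labels < platform_label` marks true body-hit pixels.
#' @examples
#' ph <- make_phantom(list(list(type = "sphere", center = c(0, 1.1, 0),
#'                              radius = 0.25)))
#' cams <- default_cameras()
#' rv <- render_views(ph, cams$anterior, cams$posterior, seed = 1)
#' sum(rv$anterior$labels > 0)
#' @export
render_views <- function(phantom, front, back, platform_height_m = 0.3,
                         seed = 1L) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(front, "camera_model"), inherits(back, "camera_model"),
            platform_height_m >= 0)
  prims <- lift_prims(phantom$prims, platform_height_m)
  n_body <- nrow(prims)
  if (platform_height_m > 0) {
    platform <- numeric(10)
    platform[1:7] <- c(5, -0.4, 0, -0.35, 0.4, platform_height_m, 0.35)
    prims <- rbind(prims, platform)
  }
  platform_label <- n_body + 1L
  with_local_seed(seed, {
    anterior <- render_one(prims, n_body, platform_label, front, "anterior", seed)
    posterior <- render_one(prims, n_body, platform_label, back, "posterior", seed)
  })
  if (sum(anterior$labels > 0 & anterior$labels < platform_label) == 0 &&
      sum(posterior$labels > 0 & posterior$labels < platform_label) == 0)
    stop_bodyscan("empty_render", "phantom outside both camera frusta")
  list(anterior = anterior, posterior = posterior)
}

lift_prims <- function(prims, dy) {
  out <- prims
  for (i in seq_len(nrow(prims))) {
    type <- prims[i, 1]
    if (type %in% c(1, 2)) out[i, 3] <- out[i, 3] + dy
    else { out[i, 3] <- out[i, 3] + dy; out[i, 6] <- out[i, 6] + dy }
  }
  out
}

IR_BACKGROUND <- 8L
IR_BODY <- 220L
IR_PLATFORM <- 245L

render_one <- function(prims, n_body, platform_label, cam, view, seed) {
  w <- cam$width; h <- cam$height
  u <- rep(0:(w - 1), each = h)         # column-major frames: row index fast
  v <- rep(0:(h - 1), times = w)
  d_cam <- cbind((u - cam$cx) / cam$fx, (v - cam$cy) / cam$fy, 1)
  R <- cam$pose[1:3, 1:3]
  dirs <- d_cam %*% R                   # rows: t(R) %*% d_cam
  o <- camera_center(cam)
  hit <- cpp_ray_cast(o, dirs, prims)
  # ray parameter t equals camera-z because the camera-frame direction has
  # unit z component
  z_m <- hit$t
  lab <- hit$hit
  valid <- lab > 0 & z_m >= cam$near & z_m <= cam$far
  lab[!valid] <- 0L
  # the reflective platform saturates the IR sensor: bright in IR, no
  # depth return (depth images carry body geometry only)
  valid <- valid & lab != platform_label
  depth_mm <- ifelse(valid, z_m * 1000, 0)
  if (cam$noise_sigma_mm > 0) {
    nv <- sum(valid)
    depth_mm[valid] <- depth_mm[valid] + stats::rnorm(nv, 0, cam$noise_sigma_mm)
  }
  if (cam$dropout_rate > 0) {
    drop <- valid & stats::runif(length(valid)) < cam$dropout_rate
    depth_mm[drop] <- 0
  }
  depth_mm <- pmin(pmax(round(depth_mm), 0), 65535)
  ir <- rep(IR_BACKGROUND, length(lab))
  ir[lab > 0 & lab < platform_label] <- IR_BODY
  ir[lab == platform_label] <- IR_PLATFORM
  structure(
    list(ir = matrix(as.integer(ir), h, w),
         depth = matrix(as.integer(depth_mm), h, w),
         labels = matrix(as.integer(lab), h, w),
         platform_label = platform_label,
         view = view, camera = cam, seed = seed),
    class = "scene_render"
  )
}

#' True body-hit mask of a synthetic render
#'
#' The renderer's ground-truth silhouette: pixels whose ray intersected a
#' body primitive (platform and background excluded). Used as the oracle
#' for segmentation tests.
#'
#' @param render A `scene_render`.
#' @return Logical matrix.
#' @export
true_body_mask <- function(render) {
  render$labels > 0 & render$labels < render$platform_label
}

#' @export
print.scene_render <- function(x, ...) {
  cat(sprintf("<scene_render> %s view, %dx%d px, %d body px, %d platform px\n",
              x$view, ncol(x$ir), nrow(x$ir), sum(true_body_mask(x)),
              sum(x$labels == x$platform_label)))
  invisible(x)
}
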