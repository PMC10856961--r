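#' Solid-primitive body phantoms with known volume
#'
#' A phantom is a union of solid primitives (sphere, ellipsoid, capsule,
#' cylinder, box) standing in the world frame (+y up, feet at y = 0). Its
#' ground-truth volume in litres is computed analytically when the parts
#' are provably disjoint (pairwise-disjoint bounding spheres) and by dense
#' voxelization otherwise, so that every phantom carries a reference
#' volume the reconstruction pipeline can be scored against.
#'
#' @param parts A list of primitive specs. Each spec is a named list with a
#'   `type` field and type-specific fields, all dimensions in metres:
#'   \describe{
#'     \item{sphere}{`center` (length 3), `radius`}
#'     \item{ellipsoid}{`center`, `semiaxes` (length 3, axis-aligned)}
#'     \item{capsule}{`p0`, `p1` (axis endpoints), `radius`}
#'     \item{cylinder}{`p0`, `p1`, `radius` (flat caps)}
#'     \item{box}{`min`, `max` (corners)}
#'   }
#' @param label Free-text phantom label.
#' @param voxel_mm Voxel edge length (mm) used when parts overlap and the
#'   volume must be voxelized (default 2 mm).
#' @return An object of class `phantom` with fields `parts`, `prims`
#'   (primitive matrix used by the renderer), `reference_volume_liters`
#'   and `label`.
#' @examples
#' ph <- make_phantom(list(list(type = "sphere", center = c(0, 1, 0),
#'                              radius = 0.1)))
#' ph$reference_volume_liters  # 4/3 pi 0.1^3 * 1000
#' @export
make_phantom <- function(parts, label = "phantom", voxel_mm = 2) {
  if (!is.list(parts) || length(parts) == 0)
    stop_bodyscan("invalid_spec", "phantom spec must list at least one primitive")
  prims <- do.call(rbind, lapply(parts, primitive_row))
  vols <- vapply(parts, primitive_volume_l, numeric(1))
  ref <- if (length(parts) == 1L || parts_disjoint(parts)) {
    sum(vols)
  } else {
    phantom_voxel_volume_l(prims, voxel_mm = voxel_mm)
  }
  ph <- structure(
    list(parts = parts, prims = prims,
         reference_volume_liters = ref, label = label),
    class = "phantom"
  )
  bb <- phantom_bbox(ph)
  if (bb$hi[2] - min(0, bb$lo[2]) > 2.2 ||
      bb$hi[1] - bb$lo[1] > 1.5 || bb$hi[3] - bb$lo[3] > 1.5)
    stop_bodyscan("invalid_spec",
                  "phantom exceeds the 2.2 m x 1.5 m scene bounding box")
  ph
}

primitive_row <- function(p) {
  row <- numeric(10)
  pos <- function(x, what) {
    if (!all(is.finite(x)) || any(x <= 0))
      stop_bodyscan("invalid_spec", paste0("non-positive ", what, " in primitive"))
    x
  }
  switch(p$type,
    sphere = { row[1:5] <- c(1, p$center, pos(p$radius, "radius")) },
    ellipsoid = { row[1:7] <- c(2, p$center, pos(p$semiaxes, "semi-axis")) },
    capsule = { row[1:8] <- c(3, p$p0, p$p1, pos(p$radius, "radius")) },
    cylinder = {
      pos(sqrt(sum((p$p1 - p$p0)^2)), "length")
      row[1:8] <- c(4, p$p0, p$p1, pos(p$radius, "radius"))
    },
    box = {
      pos(p$max - p$min, "box extent")
      row[1:7] <- c(5, p$min, p$max)
    },
    stop_bodyscan("invalid_spec", paste0("unknown primitive type: ", p$type))
  )
  row
}

primitive_volume_l <- function(p) {
  1000 * switch(p$type,
    sphere = 4 / 3 * pi * p$radius^3,
    ellipsoid = 4 / 3 * pi * prod(p$semiaxes),
    capsule = {
      L <- sqrt(sum((p$p1 - p$p0)^2))
      pi * p$radius^2 * L + 4 / 3 * pi * p$radius^3
    },
    cylinder = pi * p$radius^2 * sqrt(sum((p$p1 - p$p0)^2)),
    box = prod(p$max - p$min)
  )
}

primitive_bounding_sphere <- function(p) {
  switch(p$type,
    sphere = list(c = p$center, r = p$radius),
    ellipsoid = list(c = p$center, r = max(p$semiaxes)),
    capsule = list(c = (p$p0 + p$p1) / 2,
                   r = sqrt(sum((p$p1 - p$p0)^2)) / 2 + p$radius),
    cylinder = list(c = (p$p0 + p$p1) / 2,
                    r = sqrt(sum((p$p1 - p$p0)^2) / 4 + p$radius^2)),
    box = list(c = (p$min + p$max) / 2, r = sqrt(sum((p$max - p$min)^2)) / 2)
  )
}

# conservative: TRUE only when all pairwise bounding spheres are disjoint
parts_disjoint <- function(parts) {
  bs <- lapply(parts, primitive_bounding_sphere)
  n <- length(bs)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt(sum((bs[[i]]$c - bs[[j]]$c)^2))
      if (d <= bs[[i]]$r + bs[[j]]$r) return(FALSE)
    }
  }
  TRUE
}

phantom_bbox <- function(ph, pad = 0) {
  bs <- lapply(ph$parts, primitive_bounding_sphere)
  lo <- Reduce(pmin, lapply(bs, function(b) b$c - b$r))
  hi <- Reduce(pmax, lapply(bs, function(b) b$c + b$r))
  list(lo = lo - pad, hi = hi + pad)
}

# dense voxel-count volume of the union of primitives, in litres
phantom_voxel_volume_l <- function(prims, voxel_mm = 2) {
  ph <- list(parts = NULL, prims = prims)
  bs <- apply(prims, 1, function(row) prim_row_bounds(row), simplify = FALSE)
  lo <- Reduce(pmin, lapply(bs, `[[`, "lo"))
  hi <- Reduce(pmax, lapply(bs, `[[`, "hi"))
  h <- voxel_mm / 1000
  1000 * cpp_voxel_volume(prims, lo - 2 * h, hi + 2 * h, h)
}

prim_row_bounds <- function(row) {
  type <- row[1]
  if (type == 1) list(lo = row[2:4] - row[5], hi = row[2:4] + row[5])
  else if (type == 2) list(lo = row[2:4] - row[5:7], hi = row[2:4] + row[5:7])
  else if (type %in% c(3, 4)) {
    r <- row[8]
    list(lo = pmin(row[2:4], row[5:7]) - r, hi = pmax(row[2:4], row[5:7]) + r)
  } else list(lo = row[2:4], hi = row[5:7])
}

#' Standing-adult humanoid phantom preset
#'
#' Head sphere, neck capsule, torso ellipsoid, two arm capsules and two
#' leg capsules, standing with the soles at y = 0. `height` sets the
#' stature; `bulk` scales all cross-sectional radii (not the stature), so
#' volume grows roughly with `bulk^2`. Defaults give a total volume of
#' about 72 L, inside the 50-90 L adult range.
#'
#' @param height Stature in metres (default 1.70).
#' @param bulk Radial scale factor (default 1).
#' @param voxel_mm Voxelization resolution for the (overlapping) parts.
#' @return A `phantom`.
#' @export
humanoid_phantom <- function(height = 1.70, bulk = 1, voxel_mm = 2) {
  stopifnot(height > 0.5, height < 2.1, bulk > 0.5, bulk < 1.6)
  s <- height / 1.70                      # stature scale
  b <- bulk
  head_r <- 0.11 * s * b
  parts <- list(
    list(type = "sphere", center = c(0, height - head_r, 0), radius = head_r),
    list(type = "capsule", p0 = c(0, 0.82 * height, 0),
         p1 = c(0, 0.92 * height, 0), radius = 0.05 * s * b),
    list(type = "ellipsoid", center = c(0, 0.705 * height, 0),
         semiaxes = c(0.17 * s * b, 0.1765 * height, 0.11 * s * b)),
    list(type = "capsule", p0 = c(-0.19 * s, 0.82 * height, 0),
         p1 = c(0.19 * s, 0.82 * height, 0), radius = 0.055 * s * b),
    list(type = "capsule", p0 = c(0.20 * s, 0.82 * height, 0),
         p1 = c(0.235 * s, 0.47 * height, 0), radius = 0.045 * s * b),
    list(type = "capsule", p0 = c(-0.20 * s, 0.82 * height, 0),
         p1 = c(-0.235 * s, 0.47 * height, 0), radius = 0.045 * s * b),
    list(type = "capsule", p0 = c(0.09 * s, 0.075 * s * b, 0),
         p1 = c(0.09 * s, 0.54 * height, 0), radius = 0.075 * s * b),
    list(type = "capsule", p0 = c(-0.09 * s, 0.075 * s * b, 0),
         p1 = c(-0.09 * s, 0.54 * height, 0), radius = 0.075 * s * b)
  )
  make_phantom(parts, label = sprintf("humanoid h=%.2f bulk=%.2f", height, b),
               voxel_mm = voxel_mm)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> '%s': %d parts, reference volume %.3f L\n",
              x$label, length(x$parts), x$reference_volume_liters))
  invisible(x)
}
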