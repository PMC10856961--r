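#' Segment the body silhouette from an IR frame
#'
#' Thresholding plus region growth: a threshold (Otsu's method on the IR
#' histogram by default, or a fixed value) defines candidate foreground;
#' region growth from a seed point — with an intensity tolerance expressed
#' as a fraction of the threshold — keeps the single 8-connected component
#' containing the seed. The default seed is the centroid of the brightest
#' candidate blob that is not contiguous with the bottom image rows (the
#' platform band rule: the reflective standing platform appears as a
#' bright band at the bottom of the frame and must not seed the body).
#'
#' @param ir Integer/numeric intensity matrix (rows x cols, non-negative).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param seed_point Optional `c(row, col)` (1-based) inside the
#'   foreground; default chooses automatically as described.
#' @param tol_frac Region-growth intensity tolerance as a fraction of the
#'   threshold (default 0.25): pixels at or above
#'   `threshold * (1 - tol_frac)` are grown into.
#' @return A `body_mask`: logical matrix with attributes `view` and
#'   `threshold`.
#' @export
segment_body <- function(ir, threshold = "otsu", seed_point = NULL,
                         tol_frac = 0.25) {
  ir <- frame_matrix(ir)
  view <- attr(ir, "view") %||% NA_character_
  thr <- if (identical(threshold, "otsu")) otsu_threshold(ir) else threshold
  strict <- ir >= thr
  if (!any(strict))
    stop_bodyscan("no_body_found", "no pixel above the segmentation threshold")
  candidate <- ir >= thr * (1 - tol_frac)
  lab <- cpp_label8(candidate)
  if (is.null(seed_point)) {
    seed_point <- auto_seed(ir, strict, lab)
  } else {
    seed_point <- as.integer(round(seed_point))
  }
  sl <- lab[seed_point[1], seed_point[2]]
  if (sl == 0L)
    stop_bodyscan("bad_seed", "seed point lies outside the candidate foreground")
  body_mask(lab == sl, view = view, threshold = thr)
}

# centroid of the brightest candidate blob not touching the bottom rows;
# falls back to the overall brightest blob when all touch the bottom
auto_seed <- function(ir, strict, lab) {
  labs <- sort(unique(lab[strict]))
  labs <- setdiff(labs, 0L)
  nr <- nrow(lab)
  bottom <- unique(lab[c(nr - 1L, nr), ])
  eligible <- setdiff(labs, bottom)
  if (length(eligible) == 0) eligible <- labs
  mean_int <- vapply(eligible, function(l) mean(ir[lab == l]), numeric(1))
  sizes <- vapply(eligible, function(l) sum(lab == l), numeric(1))
  best <- eligible[order(-mean_int, -sizes)][1]
  idx <- which(lab == best, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  if (lab[ctr[1], ctr[2]] != best) {
    # concave blob: nearest blob pixel to the centroid
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    ctr <- idx[which.min(d2), ]
  }
  as.integer(ctr)
}

otsu_threshold <- function(ir) {
  rng <- range(ir)
  if (rng[1] == rng[2])
    stop_bodyscan("no_body_found", "uniform IR frame: no threshold separates it")
  img <- EBImage::Image((ir - rng[1]) / (rng[2] - rng[1]))
  thr01 <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  rng[1] + thr01 * (rng[2] - rng[1])
}

#' Body-mask raster
#'
#' @param mask Logical matrix.
#' @param view View label (`"anterior"`, `"posterior"` or `NA`).
#' @param threshold Threshold used to produce the mask, if any.
#' @return Logical matrix of class `body_mask`.
#' @export
body_mask <- function(mask, view = NA_character_, threshold = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(mask, view = view, threshold = threshold, class = "body_mask")
}

frame_matrix <- function(x) {
  stopifnot(is.matrix(x), length(x) > 0)
  if (any(x < 0)) stop_bodyscan("invalid_frame", "negative intensities")
  x
}

#' Remove the standing-platform band from a body mask
#'
#' The reflective platform that separates the feet from the floor shows
#' up in the IR frame as a bright region contiguous with the bottom image
#' rows, but — its paint saturating the sensor — returns no depth. Two
#' rules remove it while keeping the feet. First, bright mask pixels in
#' the lower part of the frame (`platform_rows`, by default the bottom
#' half) with no depth return are dropped. Second, any remaining
#' 8-connected component that touches the bottom image rows and whose
#' median depth differs from the leg depth (median depth over the lowest
#' fifth of the remaining mask) by more than `offset_mm` is dropped.
#' Feet — which touch the legs, not the image border, and carry valid
#' depth — are retained. With no bottom-contiguous bright region the mask
#' is returned unchanged.
#'
#' @param mask A `body_mask`.
#' @param depth Depth matrix (mm) paired with the mask.
#' @param platform_rows Optional integer rows that may contain the
#'   platform band; defaults to the bottom half of the frame.
#' @param offset_mm Depth-offset rule threshold in millimetres.
#' @return A `body_mask` without platform pixels (empty, with a warning,
#'   if the frame contained only platform).
#' @export
exclude_platform <- function(mask, depth, platform_rows = NULL,
                             offset_mm = 120) {
  stopifnot(inherits(mask, "body_mask"), is.matrix(depth),
            all(dim(mask) == dim(depth)))
  m <- unclass_mask(mask)
  if (!any(m)) return(mask)
  nr <- nrow(m)
  rows_zone <- platform_rows %||% seq.int(ceiling(nr / 2), nr)
  plane_px <- m & depth <= 0 & (row(m) %in% rows_zone)
  m2 <- m & !plane_px
  lab <- cpp_label8(m2)
  changed <- any(plane_px)
  if (max(lab) > 0L) {
    bottom_labs <- setdiff(unique(lab[c(nr - 1L, nr), ]), 0L)
    if (length(bottom_labs) > 0) {
      keep <- setdiff(seq_len(max(lab)), bottom_labs)
      body_px <- matrix(lab %in% keep, nr, ncol(m)) & depth > 0
      leg_depth <- leg_reference_depth(body_px, depth)
      for (l in bottom_labs) {
        sel <- lab == l & depth > 0
        if (!any(sel) || is.na(leg_depth) ||
            abs(stats::median(depth[sel]) - leg_depth) > offset_mm) {
          m2[lab == l] <- FALSE
          changed <- TRUE
        }
      }
    }
  }
  if (!any(m2)) {
    warn_bodyscan("platform_only",
                  "mask contains only platform pixels; nothing remains")
    return(body_mask(m2, view = attr(mask, "view"),
                     threshold = attr(mask, "threshold")))
  }
  if (!changed) return(mask)
  body_mask(m2, view = attr(mask, "view"), threshold = attr(mask, "threshold"))
}

leg_reference_depth <- function(body_px, depth) {
  rows <- which(rowSums(body_px) > 0)
  if (length(rows) == 0) return(NA_real_)
  lo <- stats::quantile(rows, 0.8)       # lowest fifth of the body rows
  sel <- body_px & row(body_px) >= lo
  if (!any(sel)) return(NA_real_)
  stats::median(depth[sel])
}

#' Morphological cleanup of a body mask
#'
#' Opening then closing with disc structuring elements, removal of
#' components below `min_component_px`, and reduction to a single
#' component: the largest one is kept (ties broken by the smallest
#' row-major first-pixel index). Cleaning is idempotent.
#'
#' @param mask A `body_mask`.
#' @param open_radius_px,close_radius_px Disc radii in pixels (0 skips the
#'   operation).
#' @param min_component_px Minimum component size in pixels.
#' @return A cleaned `body_mask` with exactly one component.
#' @export
clean_mask <- function(mask, open_radius_px = 1, close_radius_px = 2,
                       min_component_px = 64) {
  stopifnot(inherits(mask, "body_mask"),
            open_radius_px >= 0, close_radius_px >= 0)
  m <- unclass_mask(mask)
  if (open_radius_px > 0)
    m <- ebimage_morph(m, EBImage::opening, open_radius_px)
  if (close_radius_px > 0)
    m <- ebimage_morph(m, EBImage::closing, close_radius_px)
  lab <- cpp_label8(m)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    ok <- which(sizes >= min_component_px)
    if (length(ok) > 0) {
      # cpp_label8 assigns labels in row-major order of first pixels, so
      # the smallest label among equal-sized components is the tie-break
      best <- ok[order(-sizes[ok], ok)][1]
      m <- lab == best
    } else {
      m <- m & FALSE
    }
  }
  if (!any(m))
    stop_bodyscan("empty_mask", "mask is empty after cleaning")
  body_mask(m, view = attr(mask, "view"), threshold = attr(mask, "threshold"))
}

ebimage_morph <- function(m, fun, radius) {
  size <- 2L * as.integer(radius) + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  out <- fun(EBImage::Image(m * 1), kern)
  EBImage::imageData(out) > 0.5
}

unclass_mask <- function(mask) {
  m <- unclass(mask)
  attr(m, "view") <- NULL
  attr(m, "threshold") <- NULL
  m
}

#' Fuse a depth frame with a body mask
#'
#' Pixels outside the mask, invalid pixels (depth 0) and pixels outside
#' the `[near, far]` clip range are zeroed; the result is the masked depth
#' image the back-projection consumes.
#'
#' @param depth Depth matrix (mm).
#' @param mask A `body_mask` with matching dimensions.
#' @param near_mm,far_mm Clip range in millimetres.
#' @return A `masked_depth`: integer matrix with attribute `view`.
#' @export
apply_mask <- function(depth, mask, near_mm = 500, far_mm = 4500) {
  if (!all(dim(depth) == dim(mask)))
    stop_bodyscan("shape_error", "depth and mask dimensions differ")
  out <- depth
  out[!mask | depth <= 0 | depth < near_mm | depth > far_mm] <- 0L
  stopifnot(all(out[!mask] == 0))
  structure(out, view = attr(mask, "view"), class = "masked_depth")
}
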