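#' Write and read scene files
#'
#' A rendered view is stored as three sidecar files sharing a prefix:
#' `<prefix>_depth.png` (16-bit grayscale PNG, millimetres, 0 = invalid),
#' `<prefix>_ir.png` (8-bit grayscale PNG) and `<prefix>_camera.yaml`
#' (intrinsics, pose, noise model, view, seed; numbers serialized at full
#' double precision). Round-trips are bit-exact for both rasters and
#' exact to full float precision for the sidecar.
#'
#' @param render A `scene_render` from [render_views()].
#' @param prefix File path prefix (directories are created).
#' @return `write_scene` invisibly returns the three paths; `read_scene`
#'   returns a `scene_render` (without the ground-truth `labels`, which
#'   exist only in memory).
#' @export
write_scene <- function(render, prefix) {
  stopifnot(inherits(render, "scene_render"))
  if (any(render$depth > 65535) || any(render$depth < 0))
    stop_bodyscan("range_error", "depth exceeds the 16-bit millimetre range")
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- scene_paths(prefix)
  write_png16(render$depth, paths$depth)
  png::writePNG(render$ir / 255, paths$ir)
  cam <- render$camera
  side <- list(
    view = render$view, seed = render$seed,
    fx = fmt_dbl(cam$fx), fy = fmt_dbl(cam$fy),
    cx = fmt_dbl(cam$cx), cy = fmt_dbl(cam$cy),
    width = cam$width, height = cam$height,
    near = fmt_dbl(cam$near), far = fmt_dbl(cam$far),
    noise_sigma_mm = fmt_dbl(cam$noise_sigma_mm),
    dropout_rate = fmt_dbl(cam$dropout_rate),
    pose = lapply(seq_len(4), function(i) vapply(cam$pose[i, ], fmt_dbl, ""))
  )
  writeLines(yaml::as.yaml(side), paths$camera)
  invisible(paths)
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  paths <- scene_paths(prefix)
  for (p in paths)
    if (!file.exists(p))
      stop_bodyscan("missing_file", paste0("scene file not found: ", p))
  depth <- round(png::readPNG(paths$depth) * 65535)
  storage.mode(depth) <- "integer"
  ir <- round(png::readPNG(paths$ir) * 255)
  storage.mode(ir) <- "integer"
  side <- yaml::read_yaml(paths$camera)
  pose <- do.call(rbind, lapply(side$pose, as.numeric))
  cam <- camera_model(
    fx = as.numeric(side$fx), fy = as.numeric(side$fy),
    cx = as.numeric(side$cx), cy = as.numeric(side$cy),
    width = side$width, height = side$height, pose = pose,
    near = as.numeric(side$near), far = as.numeric(side$far),
    noise_sigma_mm = as.numeric(side$noise_sigma_mm),
    dropout_rate = as.numeric(side$dropout_rate)
  )
  structure(
    list(ir = ir, depth = depth, labels = NULL, platform_label = NA_integer_,
         view = side$view, camera = cam, seed = side$seed),
    class = "scene_render"
  )
}

scene_paths <- function(prefix) {
  list(depth = paste0(prefix, "_depth.png"),
       ir = paste0(prefix, "_ir.png"),
       camera = paste0(prefix, "_camera.yaml"))
}

fmt_dbl <- function(x) sprintf("%.17g", x)

# Minimal 16-bit grayscale PNG encoder. R's memCompress("gzip") emits a
# zlib stream, which is exactly what the IDAT chunk requires; CRC32 is
# computed in C++. No installed package writes 16-bit PNG.
write_png16 <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 65535))
  h <- nrow(img); w <- ncol(img)
  v <- t(img)                            # scanlines are image rows
  sc <- matrix(as.raw(0), nrow = 1 + 2 * w, ncol = h)
  idx <- seq_len(w)
  sc[2 * idx, ] <- matrix(as.raw(v %/% 256), nrow = w)
  sc[2 * idx + 1, ] <- matrix(as.raw(v %% 256), nrow = w)
  u32 <- function(x) {
    x <- as.numeric(x)
    if (x < 0) x <- x + 4294967296
    as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    td <- c(charToRaw(type), data)
    c(u32(length(data)), td, u32(cpp_crc32(td)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16, 0, 0, 0, 0)))  # 16-bit grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr),
           chunk("IDAT", memCompress(as.vector(sc), "gzip")),
           chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
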