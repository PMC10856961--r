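#' Triangle body mesh
#'
#' @param vertices V x 3 numeric matrix (metres).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `body_mesh` with a lazily evaluated
#'   `watertight` flag (see [is_watertight()]).
#' @export
body_mesh <- function(vertices, faces) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop_bodyscan("invalid_mesh", "face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "body_mesh")
}

#' Watertightness and orientation check
#'
#' A mesh is watertight and consistently oriented when every undirected
#' edge borders exactly two faces and the two incident faces traverse it
#' in opposite directions.
#'
#' @param mesh A `body_mesh`.
#' @return List with logical elements `watertight` (every edge borders
#'   exactly 2 faces) and `oriented` (each directed edge used once).
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(list(watertight = FALSE, oriented = FALSE))
  nv <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  dkey <- as.numeric(from) * (nv + 1) + to
  ukey <- pmin(from, to) * as.numeric(nv + 1) + pmax(from, to)
  utab <- table(ukey)
  list(
    watertight = all(utab == 2L),
    oriented = !anyDuplicated(dkey) && all(utab <= 2L)
  )
}

boundary_edges <- function(faces) {
  f <- faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  ukey <- pmin(from, to) * (max(f) + 1) + pmax(from, to)
  once <- ukey %in% names(which(table(ukey) == 1L))
  cbind(from[once], to[once])
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Enclosed volume of a watertight mesh, in litres
#'
#' The signed-tetrahedron (divergence theorem) volume
#' `|sum det(v0, v1, v2) / 6|`, valid only for watertight, consistently
#' oriented meshes; others raise a `volume_undefined` error.
#'
#' @param mesh A `body_mesh`.
#' @return Volume in litres.
#' @examples
#' # unit cube: 12 consistently oriented triangles -> 1000 L
#' @export
mesh_volume <- function(mesh) {
  wt <- is_watertight(mesh)
  if (!wt$watertight || !wt$oriented)
    stop_bodyscan("volume_undefined",
                  "mesh is not watertight and consistently oriented")
  abs(signed_volume_m3(mesh)) * 1000
}

signed_volume_m3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  sum(p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
      p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
      p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])) / 6
}

mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(
    rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)]),
    directed = FALSE
  )
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  igraph::components(g)$membership
}

#' Filter, repair and smooth a mesh
#'
#' Removes connected components whose surface area is below
#' `min_component_frac` of the total, fills boundary loops (fan
#' triangulation about the loop centroid) to restore watertightness, and
#' applies `smooth_iters` iterations of Taubin lambda/mu smoothing
#' (volume-preserving to well under 1 percent). Raises `non_watertight`
#' if the repaired mesh still has open edges.
#'
#' @param mesh A `body_mesh`.
#' @param min_component_frac Components below this fraction of total area
#'   are dropped (default 0.01).
#' @param smooth_iters Taubin smoothing iterations (default 5; 0 = none).
#' @return A cleaned `body_mesh`.
#' @export
clean_mesh <- function(mesh, min_component_frac = 0.01, smooth_iters = 5) {
  if (nrow(mesh$faces) == 0)
    stop_bodyscan("invalid_mesh", "empty mesh")
  areas <- face_areas(mesh)
  memb <- mesh_components(mesh)
  fcomp <- memb[mesh$faces[, 1]]
  carea <- tapply(areas, fcomp, sum)
  keep_comp <- as.integer(names(carea)[carea >= min_component_frac * sum(areas)])
  f <- mesh$faces[fcomp %in% keep_comp, , drop = FALSE]
  f <- f[face_areas(body_mesh(mesh$vertices, f)) > 0, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  v <- mesh$vertices[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  filled <- fill_holes(v, f)
  v <- filled$vertices; f <- filled$faces
  if (smooth_iters > 0) v <- taubin_smooth(v, f, smooth_iters)
  out <- body_mesh(v, f)
  wt <- is_watertight(out)
  if (!wt$watertight)
    stop_bodyscan("non_watertight", "mesh could not be made watertight")
  out
}

# fan-fill every boundary loop about its centroid; new triangles reverse
# the boundary edge direction so orientation stays consistent
fill_holes <- function(v, f) {
  repeat {
    be <- boundary_edges(f)
    if (nrow(be) == 0) break
    # recover directed boundary edges: (a, b) such that a->b used by a face
    from <- c(f[, 1], f[, 2], f[, 3])
    to <- c(f[, 2], f[, 3], f[, 1])
    nv1 <- nrow(v) + 1
    ukey <- pmin(from, to) * nv1 + pmax(from, to)
    cnt <- table(ukey)
    bsel <- ukey %in% names(which(cnt == 1L))
    ba <- from[bsel]; bb <- to[bsel]
    # group directed boundary edges into loops by following b -> next edge
    nxt <- match(bb, ba)
    done <- rep(FALSE, length(ba))
    for (s in seq_along(ba)) {
      if (done[s]) next
      loop <- integer(0)
      i <- s
      while (!is.na(i) && !done[i]) {
        done[i] <- TRUE
        loop <- c(loop, i)
        i <- nxt[i]
      }
      verts <- unique(ba[loop])
      ctr <- colMeans(v[verts, , drop = FALSE])
      v <- rbind(v, ctr)
      ci <- nrow(v)
      newf <- cbind(bb[loop], ba[loop], ci)
      f <- rbind(f, newf)
    }
  }
  list(vertices = v, faces = f)
}

taubin_smooth <- function(v, f, iters, lambda = 0.5, mu = -0.53) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  W <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  deg <- Matrix::rowSums(W)
  deg[deg == 0] <- 1
  W <- W / deg
  for (it in seq_len(iters)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  v
}

#' @export
print.body_mesh <- function(x, ...) {
  wt <- is_watertight(x)
  cat(sprintf("<body_mesh> %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), wt$watertight && wt$oriented))
  invisible(x)
}

#' PLY input/output for meshes and point clouds
#'
#' Writes `binary_little_endian` (default) or `ascii` PLY with float32
#' coordinates; reads either format back. Point clouds store optional
#' normals as `nx/ny/nz` properties.
#'
#' @param x A `body_mesh` or `point_cloud`.
#' @param path Output file.
#' @param format `"binary"` or `"ascii"`.
#' @return `write_ply` invisibly returns `path`; `read_ply` returns a
#'   `body_mesh` (if the file has faces) or `point_cloud`.
#' @export
write_ply <- function(x, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (inherits(x, "body_mesh")) {
    verts <- x$vertices; norms <- NULL; faces <- x$faces
  } else if (inherits(x, "point_cloud")) {
    verts <- x$points; norms <- x$normals; faces <- NULL
  } else stop_bodyscan("invalid_input", "write_ply needs a mesh or point cloud")
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (format == "binary") "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(verts)),
           "property float x", "property float y", "property float z")
  if (!is.null(norms))
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  vdat <- if (is.null(norms)) verts else cbind(verts, norms)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "binary") {
    writeBin(as.numeric(t(vdat)), con, size = 4, endian = "little")
    if (!is.null(faces)) {
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(faces[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    writeLines(apply(vdat, 1, function(r) paste(sprintf("%.9g", r),
                                                collapse = " ")), con)
    if (!is.null(faces))
      writeLines(paste(3, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
                 con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+).*", "\\1", grep("^format", hdr, value = TRUE))
  nvert <- as.integer(sub("element vertex ", "",
                          grep("^element vertex", hdr, value = TRUE)))
  nface_line <- grep("^element face", hdr, value = TRUE)
  nface <- if (length(nface_line)) as.integer(sub("element face ", "",
                                                  nface_line)) else 0L
  vprops <- sub("property float ", "",
                grep("^property float", hdr, value = TRUE))
  np <- length(vprops)
  if (fmt == "binary_little_endian") {
    vdat <- matrix(readBin(con, "numeric", nvert * np, size = 4,
                           endian = "little"), ncol = np, byrow = TRUE)
    faces <- NULL
    if (nface > 0) {
      faces <- matrix(0L, nface, 3)
      for (i in seq_len(nface)) {
        k <- as.integer(readBin(con, "raw", 1))
        idx <- readBin(con, "integer", k, size = 4, endian = "little")
        faces[i, ] <- idx[1:3] + 1L
      }
    }
  } else {
    txt <- readLines(con)
    vdat <- matrix(as.numeric(unlist(strsplit(txt[seq_len(nvert)], " "))),
                   ncol = np, byrow = TRUE)
    faces <- NULL
    if (nface > 0) {
      fdat <- matrix(as.integer(unlist(
        strsplit(txt[nvert + seq_len(nface)], " "))), ncol = 4, byrow = TRUE)
      faces <- fdat[, 2:4, drop = FALSE] + 1L
    }
  }
  verts <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
  if (!is.null(faces)) return(body_mesh(verts, faces))
  norms <- NULL
  if (all(c("nx", "ny", "nz") %in% vprops))
    norms <- vdat[, match(c("nx", "ny", "nz"), vprops), drop = FALSE]
  point_cloud(verts, normals = norms)
}
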