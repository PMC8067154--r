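#' Triangle surface mesh of the skull
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z in
#'   mm.
#' @param faces Integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param tags Character vector, one per face: `"original"` or
#'   `"reconstructed"`.
#' @return A `skull_mesh`.
#' @export
skull_mesh <- function(vertices, faces, tags = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1) || any(faces > nrow(vertices)))
    abort("face index out of range")
  if (is.null(tags)) tags <- rep("original", nrow(faces))
  stopifnot(length(tags) == nrow(faces))
  structure(list(vertices = vertices, faces = faces, tags = tags),
            class = "skull_mesh")
}

#' @export
print.skull_mesh <- function(x, ...) {
  cat(sprintf("<skull_mesh> %d vertices, %d faces (%d reconstructed)%s\n",
              nrow(x$vertices), nrow(x$faces),
              sum(x$tags == "reconstructed"),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

# index map between two rings: point m of the lower ring is matched to
# point floor(m * n2 / n1) of the upper ring (0-based)
stitch_map <- function(n1, n2) floor((0:(n1 - 1)) * n2 / n1)

#' Stitch two adjacent slice contours into a triangle band
#'
#' For the m-th point (0-based) of the lower contour with
#' `n = floor(m * N2 / N1)`, two triangles are emitted: (m, m+1, n) and
#' (m+1, n, n+1), indices modulo the respective ring sizes. This gives
#' `2 * N1` faces before cleanup; triangles degenerated by the floor
#' map (repeated vertex) are dropped. With equal point counts the band
#' is the standard closed prismatic strip; with unequal counts it is
#' edge-manifold but its upper rim is ragged, so pipelines resample
#' contours to a common count before stitching.
#'
#' @param c1,c2 Closed [slice_contour]s (lower, upper).
#' @param z1,z2 Slice heights, mm.
#' @return A `skull_mesh` band (no caps).
#' @export
stitch_layers <- function(c1, c2, z1, z2) {
  p1 <- contour_xy(c1); p2 <- contour_xy(c2)
  if (nrow(p1) == 0 || nrow(p2) == 0) abort("empty contour")
  n1 <- nrow(p1); n2 <- nrow(p2)
  verts <- rbind(cbind(p1, z1), cbind(p2, z2))
  fcs <- band_faces(n1, n2, 0L, n1)
  tags <- band_tags(fcs$faces, c(contour_prov(c1), contour_prov(c2)))
  skull_mesh(verts, fcs$faces, tags)
}

contour_xy <- function(ct) {
  if (is.matrix(ct)) ct else {
    if (anyNA(ct$x_mm)) abort("contour has an unfilled gap")
    cbind(ct$x_mm, ct$y_mm)
  }
}

contour_prov <- function(ct) {
  if (is.matrix(ct)) rep("original", nrow(ct)) else ct$provenance
}

# faces of one band; off1/off2 are 0-based vertex offsets of the rings
band_faces <- function(n1, n2, off1, off2) {
  m <- 0:(n1 - 1)
  n <- stitch_map(n1, n2)
  m1 <- (m + 1) %% n1
  np1 <- (n + 1) %% n2
  f1 <- cbind(off1 + m, off1 + m1, off2 + n)
  # same vertex set as the mapping rule's (m+1, n, n+1) but wound so the
  # normal agrees with f1 (outward for CCW rings)
  f2 <- cbind(off1 + m1, off2 + np1, off2 + n)
  faces <- rbind(f1, f2) + 1L
  # drop triangles collapsed by the floor map
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  list(faces = faces[!deg, , drop = FALSE], dropped = sum(deg))
}

band_tags <- function(faces, vert_prov) {
  rec <- matrix(vert_prov[faces] == "reconstructed", nrow = nrow(faces))
  ifelse(rowSums(rec) > 0, "reconstructed", "original")
}

#' Build a watertight skull mesh from a contour stack
#'
#' Stacks the closed contours at heights `z_i = (i-1) * slice_thickness`
#' (or explicit `z`), rotates each ring so index 0 is its most anterior
#' point (preventing band twist), stitches consecutive rings and closes
#' both ends with centroid fans.
#'
#' @param contours List of closed [slice_contour]s, inferior first.
#' @param slice_thickness Slice spacing, mm (ignored when `z` given).
#' @param z Optional explicit slice heights, mm.
#' @return A watertight `skull_mesh`.
#' @export
build_mesh <- function(contours, slice_thickness = 1.25, z = NULL) {
  L <- length(contours)
  if (L < 1) abort("need at least one contour")
  if (is.null(z)) z <- (seq_len(L) - 1) * slice_thickness
  stopifnot(length(z) == L)
  rings <- lapply(contours, function(ct) {
    xy <- contour_xy(ct)
    prov <- contour_prov(ct)
    i0 <- which.max(xy[, 2])  # most anterior point starts the ring
    ord <- c(i0:nrow(xy), seq_len(i0 - 1))
    list(xy = xy[ord, , drop = FALSE], prov = prov[ord])
  })
  ns <- vapply(rings, function(r) nrow(r$xy), integer(1))
  offs <- cumsum(c(0L, ns[-L]))
  verts <- do.call(rbind, lapply(seq_len(L), function(i)
    cbind(rings[[i]]$xy, z[i])))
  prov <- unlist(lapply(rings, `[[`, "prov"))
  faces <- NULL
  if (L > 1) {
    faces <- do.call(rbind, lapply(seq_len(L - 1), function(i)
      band_faces(ns[i], ns[i + 1], offs[i], offs[i + 1])$faces))
  }
  # caps: centroid fans, bottom facing -z, top facing +z
  cb <- colMeans(rings[[1]]$xy)
  ct <- colMeans(rings[[L]]$xy)
  vb <- nrow(verts) + 1L
  vt <- nrow(verts) + 2L
  verts <- rbind(verts, c(cb, z[1]), c(ct, z[L]))
  prov <- c(prov, "original", "original")
  i <- seq_len(ns[1]); ip <- c(i[-1], 1L)
  bottom <- cbind(vb, offs[1] + ip, offs[1] + i)
  j <- seq_len(ns[L]); jp <- c(j[-1], 1L)
  top <- cbind(vt, offs[L] + j, offs[L] + jp)
  faces <- rbind(faces, bottom, top)
  tags <- band_tags(faces, c(prov))
  m <- skull_mesh(verts, faces, tags)
  if (mesh_volume_signed(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Close an open band mesh with end caps
#'
#' Adds centroid-fan caps over the given end contours; used when a band
#' built with [stitch_layers()] must enclose a volume.
#'
#' @param mesh An open band `skull_mesh`.
#' @param bottom_contour,top_contour The end contours (closed, simple).
#' @param z_bottom,z_top Heights of the two end rings, mm.
#' @return A watertight `skull_mesh`.
#' @export
close_caps <- function(mesh, bottom_contour, top_contour,
                       z_bottom, z_top) {
  pb <- contour_xy(bottom_contour); pt <- contour_xy(top_contour)
  if (!is_simple_contour(pb) || !is_simple_contour(pt))
    abort("end contour is not simple")
  nb <- nrow(pb); nt <- nrow(pt)
  # locate the end rings among the mesh vertices
  ib <- ring_indices(mesh$vertices, pb, z_bottom)
  it <- ring_indices(mesh$vertices, pt, z_top)
  vb <- nrow(mesh$vertices) + 1L
  vt <- nrow(mesh$vertices) + 2L
  verts <- rbind(mesh$vertices, c(colMeans(pb), z_bottom),
                 c(colMeans(pt), z_top))
  i <- seq_len(nb); ipn <- c(i[-1], 1L)
  bottom <- cbind(vb, ib[ipn], ib[i])
  j <- seq_len(nt); jpn <- c(j[-1], 1L)
  top <- cbind(vt, it[j], it[jpn])
  faces <- rbind(mesh$faces, bottom, top)
  tags <- c(mesh$tags, rep("original", nb + nt))
  m <- skull_mesh(verts, faces, tags)
  if (mesh_volume_signed(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

ring_indices <- function(vertices, xy, z) {
  idx <- integer(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    d <- (vertices[, 1] - xy[i, 1])^2 + (vertices[, 2] - xy[i, 2])^2 +
      (vertices[, 3] - z)^2
    idx[i] <- which.min(d)
  }
  idx
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh watertight?
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh A `skull_mesh`.
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

open_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  names(tab)[tab != 2L]
}

mesh_volume_signed <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Euler characteristic V - E + F
#' @param mesh A `skull_mesh`.
#' @return Integer; 2 for a closed surface of sphere topology.
#' @export
euler_characteristic <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

#' Volume enclosed by a watertight mesh
#'
#' Signed-tetrahedron (divergence-theorem) volume against the origin,
#' reported as a positive value in cm3.
#'
#' @param mesh A watertight `skull_mesh`.
#' @return Volume, cm3.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_watertight(mesh)) {
    oe <- open_edges(mesh)
    abort(sprintf("mesh is not watertight: %d problem edge(s), e.g. %s",
                  length(oe), paste(utils::head(oe, 3), collapse = ", ")))
  }
  abs(mesh_volume_signed(mesh)) / 1000
}

#' Write a mesh as Wavefront OBJ
#'
#' `v x y z` records in mm and 1-based `f i j k` records; faces are
#' grouped as `g original` / `g reconstructed` so the flap colouring
#' survives a round-trip.
#'
#' @param mesh A `skull_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  for (tag in unique(mesh$tags)) {
    writeLines(paste("g", tag), con)
    f <- mesh$faces[mesh$tags == tag, , drop = FALSE]
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a Wavefront OBJ written by [write_obj()]
#'
#' Supports `v`, `f` (triangles, plain indices) and `g` records.
#'
#' @param path OBJ file path.
#' @return A `skull_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  verts <- list(); faces <- list(); tags <- character(0)
  tag <- "original"
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    parts <- strsplit(s, "\\s+")[[1]]
    if (parts[1] == "v") {
      if (length(parts) < 4) abort(sprintf("malformed v record at line %d", ln))
      verts[[length(verts) + 1]] <- as.numeric(parts[2:4])
    } else if (parts[1] == "f") {
      if (length(parts) != 4)
        abort(sprintf("malformed f record at line %d (triangles only)", ln))
      idx <- suppressWarnings(as.integer(sub("/.*", "", parts[2:4])))
      if (anyNA(idx)) abort(sprintf("malformed f record at line %d", ln))
      faces[[length(faces) + 1]] <- idx
      tags <- c(tags, tag)
    } else if (parts[1] == "g") {
      tag <- if (length(parts) > 1) parts[2] else "original"
    }
  }
  if (length(verts) == 0 || length(faces) == 0)
    abort("OBJ contains no vertices or no faces")
  skull_mesh(do.call(rbind, verts), do.call(rbind, faces), tags)
}
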