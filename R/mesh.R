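# error helper: all package errors carry a subclass so callers can condition on them
ctpop_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ctpop_error", "error")))
}

#' Triangle mesh in millimeter coordinates
#'
#' Constructs a triangle surface mesh, the representation used for 3D
#' anatomical structures, extraction-site cuboids, and corridors. Coordinates
#' are millimeters in a right-handed frame; closed meshes are expected to be
#' consistently outward-oriented so that the divergence-theorem volume is
#' positive.
#'
#' @param vertices numeric matrix, n x 3, one vertex per row (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param label human-readable label (e.g. an anatomical-structure name).
#' @param id identifier (e.g. an ontology ID).
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, label = "", id = "") {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      ctpop_stop("face index out of range", "ctpop_invalid_geometry")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(degen))
      ctpop_stop(sprintf("%d degenerate face(s) with repeated vertex indices", sum(degen)),
                 "ctpop_invalid_geometry")
  }
  structure(list(vertices = vertices, faces = faces,
                 label = as.character(label), id = as.character(id)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %s%s: %d vertices, %d faces\n",
              if (nzchar(x$id)) paste0(x$id, " ") else "",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_bbox(x)
  cat(sprintf("  bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @return 2 x 3 matrix; row 1 = minima, row 2 = maxima (mm).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin), returned as an absolute value in cubic millimeters. The mesh
#' must be closed; open meshes raise a `ctpop_not_closed` error.
#'
#' @param mesh a `tri_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (!rep$closed)
    ctpop_stop(sprintf("mesh '%s' is not closed (%d boundary edges)",
                       mesh$id, rep$n_boundary_edges), "ctpop_not_closed")
  abs(signed_volume(mesh$vertices, mesh$faces))
}

# raw divergence-theorem volume of a triangle soup (no validity checks)
signed_volume <- function(v, f) {
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# undirected edge table with direction counts; the workhorse for closedness /
# manifoldness checks and hole detection
edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(edges = e, key = key, counts = table(key))
}

#' Validate mesh closedness and manifoldness, optionally filling holes
#'
#' Checks that every undirected edge is shared by exactly two triangles
#' (edge-manifold and closed) with opposite winding (consistent orientation).
#' With `fill = TRUE`, simple holes (boundary loops in which every boundary
#' vertex has exactly two boundary edges) are closed by fanning triangles
#' around the loop centroid; anything more pathological raises
#' `ctpop_repair_failed` rather than guessing.
#'
#' @param mesh a `tri_mesh`.
#' @param fill attempt hole filling when the mesh is open.
#' @return A list with elements `closed`, `manifold`, `oriented`,
#'   `n_boundary_edges`, and (when `fill = TRUE`) `mesh`, the repaired mesh.
#' @export
validate_mesh <- function(mesh, fill = FALSE) {
  et <- edge_table(mesh$faces)
  cnt <- et$counts
  boundary_keys <- names(cnt)[cnt == 1L]
  nonmanifold <- any(cnt > 2L)
  # orientation: among edges seen twice, the two directed copies must oppose
  oriented <- TRUE
  if (!nonmanifold && length(boundary_keys) == 0L && nrow(mesh$faces) > 0) {
    dir_key <- paste(et$edges[, 1], et$edges[, 2])
    oriented <- !any(duplicated(dir_key))
  }
  out <- list(closed = length(boundary_keys) == 0L && nrow(mesh$faces) > 0,
              manifold = !nonmanifold,
              oriented = oriented,
              n_boundary_edges = length(boundary_keys))
  if (!fill) return(out)
  if (nonmanifold)
    ctpop_stop("cannot repair a non-manifold mesh", "ctpop_repair_failed")
  if (out$closed) {
    out$mesh <- mesh
    return(out)
  }
  # boundary edges keep their original direction (they occur once); a hole is
  # capped by triangles wound opposite to the boundary so orientation stays
  # consistent
  bnd <- et$edges[et$key %in% boundary_keys, , drop = FALSE]
  deg <- table(c(bnd[, 1], bnd[, 2]))
  if (any(deg != 2L))
    ctpop_stop("boundary is not a collection of simple loops", "ctpop_repair_failed")
  v <- mesh$vertices
  f <- mesh$faces
  nxt <- stats::setNames(bnd[, 2], as.character(bnd[, 1]))
  remaining <- rep(TRUE, nrow(bnd))
  names(remaining) <- as.character(bnd[, 1])
  visited <- character(0)
  starts <- as.character(bnd[, 1])
  for (s in starts) {
    if (s %in% visited) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, as.integer(cur))
      visited <- c(visited, cur)
      cur <- as.character(nxt[[cur]])
      if (cur == s) break
      if (length(loop) > nrow(bnd))
        ctpop_stop("boundary loop does not close", "ctpop_repair_failed")
    }
    centroid <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    k <- length(loop)
    # boundary edge (a -> b) gets cap triangle (b, a, centroid)
    cap <- cbind(loop[c(2:k, 1)], loop, ci)
    f <- rbind(f, cap)
  }
  repaired <- tri_mesh(v, f, label = mesh$label, id = mesh$id)
  rep2 <- validate_mesh(repaired)
  if (!rep2$closed)
    ctpop_stop("hole filling failed to close the mesh", "ctpop_repair_failed")
  out$mesh <- repaired
  out
}

#' Test whether a closed mesh is convex
#'
#' A mesh is treated as convex when every vertex lies on or behind the plane
#' of every face, within a relative tolerance. Convexity selects the exact
#' half-space-clipping route in collision detection.
#'
#' @param mesh a `tri_mesh`.
#' @param tol relative tolerance on the signed plane distance.
#' @return logical.
#' @export
is_convex_mesh <- function(mesh, tol = 1e-7) {
  pl <- face_planes(mesh)
  scale <- max(abs(mesh$vertices)) + 1
  d <- mesh$vertices %*% t(pl[, 1:3, drop = FALSE]) -
    rep(pl[, 4], each = nrow(mesh$vertices))
  all(d <= tol * scale)
}

# outward face planes (unit normal n, offset d with n . x = d on the plane);
# degenerate (zero-area) triangles are dropped
face_planes <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(n^2))
  keep <- len > 0
  n <- n[keep, , drop = FALSE] / len[keep]
  d <- rowSums(n * a[keep, , drop = FALSE])
  cbind(n, d)
}

# deduplicated face planes (cuboids have 12 triangles but 6 planes)
unique_planes <- function(mesh, digits = 9) {
  pl <- face_planes(mesh)
  key <- apply(round(pl, digits), 1, paste, collapse = ",")
  pl[!duplicated(key), , drop = FALSE]
}

#' Axis-aligned box mesh
#'
#' @param center box center (mm).
#' @param dims edge lengths (dx, dy, dz) in mm.
#' @param label,id passed to [tri_mesh()].
#' @return closed 12-triangle `tri_mesh` with outward orientation.
#' @export
box_mesh <- function(center = c(0, 0, 0), dims = c(1, 1, 1), label = "", id = "") {
  if (any(dims <= 0))
    ctpop_stop("box dimensions must be positive", "ctpop_invalid_geometry")
  h <- dims / 2
  corners <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                                   z = c(-h[3], h[3])))
  v <- sweep(corners, 2, center, "+")
  # outward-wound triangles over the 8 expand.grid corners
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-min
    c(5, 6, 7), c(6, 8, 7),   # z-max
    c(1, 2, 5), c(2, 6, 5),   # y-min
    c(3, 7, 4), c(4, 7, 8),   # y-max
    c(1, 5, 3), c(3, 5, 7),   # x-min
    c(2, 4, 6), c(4, 8, 6))   # x-max
  tri_mesh(v, f, label = label, id = id)
}

#' Icosphere mesh
#'
#' Geodesic sphere built by subdividing an icosahedron and projecting onto the
#' sphere; convex, closed, and consistently oriented.
#'
#' @param center sphere center (mm).
#' @param radius radius in mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = icosahedron).
#' @param label,id passed to [tri_mesh()].
#' @return a `tri_mesh`.
#' @export
icosphere_mesh <- function(center = c(0, 0, 0), radius = 1, subdivisions = 2,
                           label = "", id = "") {
  if (radius <= 0)
    ctpop_stop("radius must be positive", "ctpop_invalid_geometry")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    nf <- nrow(f)
    midkey <- new.env(parent = emptyenv())
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(midkey[[k]])) return(midkey[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      midkey[[k]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nf * 4, 3)
    for (j in seq_len(nf)) {
      a <- f[j, 1]; b <- f[j, 2]; c_ <- f[j, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      newf[(j - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- sweep(v * radius, 2, center, "+")
  tri_mesh(v, f, label = label, id = id)
}

#' Triangular-prism mesh
#'
#' Right prism over an equilateral-triangle cross-section, extruded along z;
#' convex and closed.
#'
#' @param center centroid position (mm).
#' @param side side length of the triangular cross-section (mm).
#' @param height extrusion length along z (mm).
#' @param label,id passed to [tri_mesh()].
#' @return a `tri_mesh`.
#' @export
prism_mesh <- function(center = c(0, 0, 0), side = 1, height = 1,
                       label = "", id = "") {
  if (side <= 0 || height <= 0)
    ctpop_stop("prism side and height must be positive", "ctpop_invalid_geometry")
  r <- side / sqrt(3)  # circumradius of the equilateral cross-section
  ang <- c(90, 210, 330) * pi / 180
  base <- cbind(r * cos(ang), r * sin(ang))
  v <- rbind(cbind(base, -height / 2), cbind(base, height / 2))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2),                       # bottom (outward = -z)
    c(4, 5, 6),                       # top
    c(1, 2, 4), c(2, 5, 4),
    c(2, 3, 5), c(3, 6, 5),
    c(3, 1, 6), c(1, 4, 6))
  tri_mesh(v, f, label = label, id = id)
}

# translate / transform helpers used throughout
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}
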