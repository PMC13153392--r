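# ---- convex boolean intersection via half-space clipping -------------------
#
# A triangle soup (list of matrices va, vb, vc, one row per triangle) is
# clipped against each face half-space of the second operand. After every
# plane clip the planar cross-section of a convex solid is a convex polygon,
# so the cap is rebuilt by angular ordering of the cut points. Exact for
# convex-convex pairs up to floating point; the voxel route covers the rest.

clip_soup_halfspace <- function(soup, n, d, scale) {
  if (nrow(soup$va) == 0) return(soup)
  eps <- 1e-12 * scale
  sa <- drop(soup$va %*% n) - d
  sb <- drop(soup$vb %*% n) - d
  sc <- drop(soup$vc %*% n) - d
  ina <- sa <= eps; inb <- sb <= eps; inc_ <- sc <= eps
  ni <- ina + inb + inc_
  keep_a <- list(); keep_b <- list(); keep_c <- list()
  cap_pts <- list()
  lerp <- function(p, q, sp, sq) p + (q - p) * (sp / (sp - sq))
  # all inside: kept verbatim
  w <- ni == 3L
  if (any(w)) {
    keep_a[[1]] <- soup$va[w, , drop = FALSE]
    keep_b[[1]] <- soup$vb[w, , drop = FALSE]
    keep_c[[1]] <- soup$vc[w, , drop = FALSE]
  }
  # one vertex inside: rotate so it is A; kept triangle (A, AB, CA)
  w <- which(ni == 1L)
  if (length(w)) {
    pa <- matrix(0, length(w), 3); pb <- pa; pc <- pa
    za <- numeric(length(w)); zb <- za; zc <- za
    for (r in seq_along(w)) {
      t <- w[r]
      ord <- if (ina[t]) 1:3 else if (inb[t]) c(2, 3, 1) else c(3, 1, 2)
      vs <- rbind(soup$va[t, ], soup$vb[t, ], soup$vc[t, ])[ord, ]
      ss <- c(sa[t], sb[t], sc[t])[ord]
      pa[r, ] <- vs[1, ]; pb[r, ] <- vs[2, ]; pc[r, ] <- vs[3, ]
      za[r] <- ss[1]; zb[r] <- ss[2]; zc[r] <- ss[3]
    }
    iab <- pa + (pb - pa) * (za / (za - zb))
    ica <- pc + (pa - pc) * (zc / (zc - za))
    keep_a[[length(keep_a) + 1]] <- pa
    keep_b[[length(keep_b) + 1]] <- iab
    keep_c[[length(keep_c) + 1]] <- ica
    cap_pts[[length(cap_pts) + 1]] <- iab
    cap_pts[[length(cap_pts) + 1]] <- ica
  }
  # two vertices inside: rotate so the outside vertex is C;
  # kept quad (A, B, BC, CA) split into two triangles
  w <- which(ni == 2L)
  if (length(w)) {
    pa <- matrix(0, length(w), 3); pb <- pa; pc <- pa
    za <- numeric(length(w)); zb <- za; zc <- za
    for (r in seq_along(w)) {
      t <- w[r]
      ord <- if (!ina[t]) c(2, 3, 1) else if (!inb[t]) c(3, 1, 2) else 1:3
      vs <- rbind(soup$va[t, ], soup$vb[t, ], soup$vc[t, ])[ord, ]
      ss <- c(sa[t], sb[t], sc[t])[ord]
      pa[r, ] <- vs[1, ]; pb[r, ] <- vs[2, ]; pc[r, ] <- vs[3, ]
      za[r] <- ss[1]; zb[r] <- ss[2]; zc[r] <- ss[3]
    }
    ibc <- pb + (pc - pb) * (zb / (zb - zc))
    ica <- pc + (pa - pc) * (zc / (zc - za))
    keep_a[[length(keep_a) + 1]] <- pa
    keep_b[[length(keep_b) + 1]] <- pb
    keep_c[[length(keep_c) + 1]] <- ibc
    keep_a[[length(keep_a) + 1]] <- pa
    keep_b[[length(keep_b) + 1]] <- ibc
    keep_c[[length(keep_c) + 1]] <- ica
    cap_pts[[length(cap_pts) + 1]] <- ibc
    cap_pts[[length(cap_pts) + 1]] <- ica
  }
  va <- do.call(rbind, keep_a); vb <- do.call(rbind, keep_b)
  vc <- do.call(rbind, keep_c)
  if (is.null(va)) return(list(va = matrix(0, 0, 3), vb = matrix(0, 0, 3),
                               vc = matrix(0, 0, 3)))
  # cap: convex cross-section, rebuilt as a fan in CCW order about the normal
  cp <- do.call(rbind, cap_pts)
  if (!is.null(cp) && nrow(cp) >= 3) {
    cp <- cp[!duplicated(round(cp / (1e-9 * scale))), , drop = FALSE]
    if (nrow(cp) >= 3) {
      ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * n) * n
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(n[2] * e1[3] - n[3] * e1[2],
              n[3] * e1[1] - n[1] * e1[3],
              n[1] * e1[2] - n[2] * e1[1])
      ctr <- colMeans(cp)
      rel <- sweep(cp, 2, ctr)
      ang <- atan2(drop(rel %*% e2), drop(rel %*% e1))
      cp <- cp[order(ang), , drop = FALSE]
      k <- nrow(cp)
      # fan about the centroid, wound so the cap normal is +n (outward of the
      # kept half-space); e1 x e2 = n and angles increase CCW about n, so the
      # fan (ctr, p_i, p_{i+1}) already has normal +n
      capa <- matrix(ctr, k, 3, byrow = TRUE)
      capb <- cp
      capc <- cp[c(2:k, 1), , drop = FALSE]
      va <- rbind(va, capa); vb <- rbind(vb, capb); vc <- rbind(vc, capc)
    }
  }
  list(va = va, vb = vb, vc = vc)
}

soup_from_mesh <- function(mesh) {
  f <- mesh$faces
  list(va = mesh$vertices[f[, 1], , drop = FALSE],
       vb = mesh$vertices[f[, 2], , drop = FALSE],
       vc = mesh$vertices[f[, 3], , drop = FALSE])
}

soup_volume <- function(soup) {
  a <- soup$va; b <- soup$vb; c_ <- soup$vc
  if (nrow(a) == 0) return(0)
  abs(sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6)
}

#' Exact intersection volume of two convex closed meshes
#'
#' Clips the first mesh's surface by every face half-space of the second
#' (Sutherland-Hodgman polyhedron clipping with planar caps) and evaluates
#' the divergence-theorem volume of the result. Exact, up to floating point,
#' whenever both operands are convex.
#'
#' @param mesh_a,mesh_b convex closed `tri_mesh` objects.
#' @return intersection volume in mm^3 (0 when disjoint).
#' @export
convex_intersection_volume <- function(mesh_a, mesh_b) {
  bba <- mesh_bbox(mesh_a); bbb <- mesh_bbox(mesh_b)
  if (any(bba[1, ] > bbb[2, ]) || any(bbb[1, ] > bba[2, ])) return(0)
  soup <- soup_from_mesh(mesh_a)
  scale <- max(abs(rbind(mesh_a$vertices, mesh_b$vertices))) + 1
  pl <- unique_planes(mesh_b)
  for (i in seq_len(nrow(pl))) {
    soup <- clip_soup_halfspace(soup, pl[i, 1:3], pl[i, 4], scale)
    if (nrow(soup$va) == 0) return(0)
  }
  soup_volume(soup)
}

#' Voxel-oracle intersection volume of two closed meshes
#'
#' Brute-force fallback and test oracle: both meshes are voxelized on a
#' common grid spanning their bounding-box overlap and the conjunction of the
#' occupancies is integrated. Works for arbitrary closed meshes.
#'
#' @param mesh_a,mesh_b closed `tri_mesh` objects.
#' @param pitch voxel edge, mm; default 1/40 of the smallest bounding-box
#'   edge of the smaller operand (clamped so the grid stays tractable).
#' @return estimated intersection volume in mm^3.
#' @export
voxel_intersection_volume <- function(mesh_a, mesh_b, pitch = NULL) {
  bba <- mesh_bbox(mesh_a); bbb <- mesh_bbox(mesh_b)
  lo <- pmax(bba[1, ], bbb[1, ]); hi <- pmin(bba[2, ], bbb[2, ])
  if (any(lo >= hi)) return(0)
  if (is.null(pitch)) {
    smaller <- if (prod(bba[2, ] - bba[1, ]) <= prod(bbb[2, ] - bbb[1, ]))
      bba else bbb
    pitch <- default_pitch(smaller)
    # keep the shared grid under ~8e6 cells
    while (prod(ceiling((hi - lo) / pitch)) > 8e6) pitch <- pitch * 2
  }
  bounds <- rbind(lo, hi)
  ga <- voxelize(mesh_a, pitch, bounds = bounds)
  gb <- voxelize(mesh_b, pitch, bounds = bounds)
  sum(ga$occ & gb$occ) * pitch^3
}

# ---- collision detection ---------------------------------------------------

check_organ_match <- function(site, organ) {
  if (nzchar(site$target_organ) && site$target_organ != organ$id)
    ctpop_stop(sprintf("site '%s' targets organ '%s' but got organ '%s'",
                       site$id, site$target_organ, organ$id),
               "ctpop_organ_mismatch")
}

#' Bounding-box collision detection
#'
#' Fast, imprecise broad phase: returns the ids of anatomical structures
#' whose axis-aligned bounding box intersects the bounding box of the placed
#' site cuboid. Always a superset of the mesh-based hits.
#'
#' @param site an `extraction_site`.
#' @param organ a `reference_organ` with the site's target organ id.
#' @return character vector of anatomical-structure ids.
#' @export
bbox_collisions <- function(site, organ) {
  check_organ_match(site, organ)
  sb <- mesh_bbox(cuboid_to_mesh(site))
  hits <- vapply(organ$structures, function(m) {
    bb <- mesh_bbox(m)
    all(sb[1, ] <= bb[2, ]) && all(bb[1, ] <= sb[2, ])
  }, logical(1))
  names(organ$structures)[hits]
}

#' Mesh-based collision detection with intersection volumes
#'
#' Narrow phase: for every anatomical structure surviving the bounding-box
#' prefilter, the exact intersection volume between the placed cuboid and the
#' structure mesh is computed by convex half-space clipping; non-convex
#' structures fall back to the voxel route and are flagged in the `method`
#' column. Zero-volume (face) contact is not a collision. Records are sorted
#' by descending volume, ties broken lexicographically by structure id.
#'
#' @param site an `extraction_site`.
#' @param organ a `reference_organ`.
#' @param fill repair open structure meshes by hole filling before testing.
#' @return data.frame with columns `as_id`, `as_label`, `organ_id`,
#'   `intersection_volume`, `percentage_of_site`, `method`.
#' @export
mesh_collisions <- function(site, organ, fill = TRUE) {
  check_organ_match(site, organ)
  cand <- bbox_collisions(site, organ)
  sm <- cuboid_to_mesh(site)
  vsite <- site_volume(site)
  rows <- list()
  for (as_id in cand) {
    m <- organ$structures[[as_id]]
    rep <- validate_mesh(m, fill = fill)
    if (!rep$closed && !fill)
      ctpop_stop(sprintf("anatomical structure '%s' is not closed", as_id),
                 "ctpop_not_closed")
    if (fill && !is.null(rep$mesh)) m <- rep$mesh
    rep2 <- validate_mesh(m)
    if (!rep2$closed)
      ctpop_stop(sprintf("anatomical structure '%s' is not closed after repair",
                         as_id), "ctpop_not_closed")
    if (is_convex_mesh(m)) {
      vol <- convex_intersection_volume(sm, m)
      method <- "mesh-boolean"
    } else {
      vol <- voxel_intersection_volume(sm, m)
      method <- "voxel"
    }
    if (vol > 1e-12 * vsite) {
      rows[[length(rows) + 1]] <- data.frame(
        as_id = as_id, as_label = m$label, organ_id = organ$id,
        intersection_volume = vol,
        percentage_of_site = 100 * vol / vsite,
        method = method, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(as_id = character(0), as_label = character(0),
               organ_id = character(0), intersection_volume = numeric(0),
               percentage_of_site = numeric(0), method = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(-out$intersection_volume, out$as_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anatomical-structure tags for an extraction site
#'
#' Labels of the structures the site collides with, in the order returned by
#' [mesh_collisions()] (largest intersection first).
#'
#' @inheritParams mesh_collisions
#' @return character vector of structure labels.
#' @export
as_tags <- function(site, organ) {
  mesh_collisions(site, organ)$as_label
}

#' Detect mutually intersecting anatomical structures in a reference organ
#'
#' Reference structures are supposed to tile the organ without overlap so that
#' populations are specific to a single structure; this audit reports every
#' unordered structure pair with positive shared volume.
#'
#' @param organ a `reference_organ`.
#' @return data.frame with columns `as_id_a`, `as_id_b`, `shared_volume`.
#' @export
detect_reference_overlaps <- function(organ) {
  ids <- names(organ$structures)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq((i + 1), length(ids))) {
        ma <- organ$structures[[ids[i]]]
        mb <- organ$structures[[ids[j]]]
        bba <- mesh_bbox(ma); bbb <- mesh_bbox(mb)
        if (any(bba[1, ] > bbb[2, ]) || any(bbb[1, ] > bba[2, ])) next
        vol <- if (is_convex_mesh(ma) && is_convex_mesh(mb))
          convex_intersection_volume(ma, mb)
        else voxel_intersection_volume(ma, mb)
        if (vol > 0) {
          a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
          rows[[length(rows) + 1]] <- data.frame(
            as_id_a = a, as_id_b = b, shared_volume = vol,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(as_id_a = character(0), as_id_b = character(0),
               shared_volume = numeric(0), stringsAsFactors = FALSE)
}
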