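#' Corridor search parameters
#'
#' @param step sliding-window step size in mm. Default (`NULL`) is 10% of the
#'   smallest site dimension, resolved when a site is available.
#' @param tolerance relative tolerance on each preserved intersection volume;
#'   a candidate placement is feasible when every re-measured target volume is
#'   within `tolerance * target` of the observed one. Default 0.1, i.e. the
#'   re-measured volume may not deviate by more than 10% of the true
#'   intersection volume.
#' @param wrap_offset outward offset (mm) applied when wrapping the union of
#'   feasible cuboids into a corridor surface. Default (`NULL`) is `step / 2`.
#' @return An object of class `corridor_params`.
#' @export
corridor_params <- function(step = NULL, tolerance = 0.1, wrap_offset = NULL) {
  if (!is.null(step) && (!is.finite(step) || step <= 0))
    ctpop_stop("step must be positive", "ctpop_invalid_parameter")
  if (!is.finite(tolerance) || tolerance < 0 || tolerance >= 1)
    ctpop_stop("tolerance must be in [0, 1)", "ctpop_invalid_parameter")
  if (!is.null(wrap_offset) && (!is.finite(wrap_offset) || wrap_offset < 0))
    ctpop_stop("wrap_offset must be nonnegative", "ctpop_invalid_parameter")
  structure(list(step = step, tolerance = tolerance, wrap_offset = wrap_offset),
            class = "corridor_params")
}

resolve_params <- function(params, site) {
  if (is.null(params$step)) params$step <- 0.1 * min(site$dimensions)
  if (is.null(params$wrap_offset)) params$wrap_offset <- params$step / 2
  params
}

#' Search domain for feasible site translations
#'
#' Filter stage: every collided structure is approximated by its minimum
#' (axis-aligned) bounding box, and the admissible region Omega of center
#' translations is the set from which the fixed-size, axis-aligned bounding
#' box of the site can still intersect every target box -- each target box
#' Minkowski-expanded by the site's half extents, then intersected across
#' targets.
#'
#' @param site an `extraction_site`.
#' @param target_as_meshes list of `tri_mesh` (the collided structures).
#' @return 2 x 3 matrix (min row, max row) of admissible center translations.
#' @export
search_domain <- function(site, target_as_meshes) {
  if (length(target_as_meshes) < 1)
    ctpop_stop("at least one target structure is required", "ctpop_invalid_input")
  sm <- cuboid_to_mesh(site)
  half <- (mesh_bbox(sm)[2, ] - mesh_bbox(sm)[1, ]) / 2
  lo <- rep(-Inf, 3); hi <- rep(Inf, 3)
  for (m in target_as_meshes) {
    bb <- mesh_bbox(m)
    lo <- pmax(lo, bb[1, ] - half)
    hi <- pmin(hi, bb[2, ] + half)
  }
  if (any(lo > hi))
    ctpop_stop("no translation can reach every target bounding box",
               "ctpop_infeasible_domain")
  rbind(min = lo, max = hi)
}

#' Feasible placements of an extraction site (search stage)
#'
#' Brute-force sliding-window search: candidate center translations form a
#' grid of spacing `step` over the search domain, anchored at the original
#' translation (so refining the step keeps coarse grid points). Rotation and
#' dimensions stay fixed. A candidate is feasible when, for every target
#' structure, its re-measured intersection volume is within
#' `tolerance * target volume` of the observed one. The original translation
#' is always evaluated and appended when absent from the grid.
#'
#' @param site an `extraction_site`.
#' @param organ a `reference_organ`.
#' @param targets named numeric vector: observed intersection volume (mm^3)
#'   per target structure id, from a prior [mesh_collisions()] call.
#' @param params a [corridor_params()].
#' @return data.frame with columns `tx`, `ty`, `tz`, `feasible` volumes per
#'   target as a matrix attribute `volumes`, plus attribute `inconsistent`
#'   when some target volume exceeds the site volume.
#' @export
feasible_placements <- function(site, organ, targets, params = corridor_params()) {
  check_organ_match(site, organ)
  params <- resolve_params(params, site)
  ids <- names(targets)
  if (length(ids) < 1)
    ctpop_stop("targets must be a named vector of intersection volumes",
               "ctpop_invalid_input")
  meshes <- lapply(ids, function(i) {
    m <- organ$structures[[i]]
    if (is.null(m))
      ctpop_stop(sprintf("target structure '%s' not in organ", i),
                 "ctpop_invalid_input")
    m
  })
  inconsistent <- any(targets > site_volume(site) * (1 + 1e-9))
  dom <- search_domain(site, meshes)
  step <- params$step
  axes <- lapply(1:3, function(a) {
    k <- c(rev(seq(0, by = -step, length.out =
                     floor((site$translation[a] - dom[1, a]) / step) + 1)),
           seq(step, by = step, length.out =
                 floor((dom[2, a] - site$translation[a]) / step)))
    site$translation[a] + k
  })
  cand <- as.matrix(expand.grid(tx = axes[[1]], ty = axes[[2]], tz = axes[[3]]))
  # make sure the original placement is on the list
  orig <- site$translation
  if (!any(rowSums(abs(sweep(cand, 2, orig))) < 1e-12))
    cand <- rbind(cand, orig)
  sm0 <- cuboid_to_mesh(site)
  sm0$vertices <- sweep(sm0$vertices, 2, site$translation)  # centered copy
  half <- (mesh_bbox(sm0)[2, ] - mesh_bbox(sm0)[1, ]) / 2
  tol <- params$tolerance
  bbs <- lapply(meshes, mesh_bbox)
  convex <- vapply(meshes, is_convex_mesh, logical(1))
  nfeas <- nrow(cand)
  feas <- rep(TRUE, nfeas)
  vols <- matrix(NA_real_, nfeas, length(ids), dimnames = list(NULL, ids))
  for (r in seq_len(nfeas)) {
    ctr <- cand[r, ]
    ok <- TRUE
    for (j in seq_along(ids)) {
      # bbox prune: the axis-aligned overlap volume bounds the true volume
      ov <- pmin(bbs[[j]][2, ], ctr + half) - pmax(bbs[[j]][1, ], ctr - half)
      ub <- if (all(ov > 0)) prod(ov) else 0
      if (ub < (1 - tol) * targets[j]) { ok <- FALSE; break }
      smr <- sm0
      smr$vertices <- sweep(smr$vertices, 2, ctr, "+")
      vol <- if (convex[j]) convex_intersection_volume(smr, meshes[[j]])
      else voxel_intersection_volume(smr, meshes[[j]])
      vols[r, j] <- vol
      if (abs(vol - targets[j]) > tol * targets[j]) { ok <- FALSE; break }
    }
    feas[r] <- ok
  }
  out <- data.frame(tx = cand[, 1], ty = cand[, 2], tz = cand[, 3],
                    feasible = feas)
  attr(out, "volumes") <- vols
  attr(out, "inconsistent") <- inconsistent
  attr(out, "params") <- params
  out
}

#' Corridor of plausible extraction-site placements
#'
#' The corridor is the 3D volume of all placements of the site that preserve
#' its observed intersection volumes with the collided structures, built by a
#' three-case rule on the number of collided structures:
#' \describe{
#'   \item{one structure}{the entire structure mesh is returned verbatim as
#'     the corridor;}
#'   \item{two structures}{a filter-search over translations finds all
#'     feasible placements, and the union of their cuboids is wrapped into a
#'     closed surface with an outward offset (`wrap_offset`);}
#'   \item{three or more structures}{the site is considered fixed in place
#'     and the corridor is exactly the site cuboid.}
#' }
#'
#' @param site an `extraction_site`.
#' @param organ a `reference_organ`.
#' @param params a [corridor_params()].
#' @return a closed `tri_mesh`; its `id` is the site id. The attribute
#'   `case` records which rule applied; for case 2 the attribute
#'   `placements` carries the feasible-placement table.
#' @export
build_corridor <- function(site, organ, params = corridor_params()) {
  col <- mesh_collisions(site, organ)
  if (nrow(col) == 0)
    ctpop_stop(sprintf("site '%s' collides with no structure", site$id),
               "ctpop_no_collision")
  params <- resolve_params(params, site)
  if (nrow(col) == 1) {
    out <- organ$structures[[col$as_id[1]]]
    out$id <- site$id
    attr(out, "case") <- 1L
    return(out)
  }
  if (nrow(col) >= 3) {
    out <- cuboid_to_mesh(site)
    attr(out, "case") <- 3L
    return(out)
  }
  targets <- stats::setNames(col$intersection_volume, col$as_id)
  fp <- feasible_placements(site, organ, targets, params)
  pts <- as.matrix(fp[fp$feasible, c("tx", "ty", "tz"), drop = FALSE])
  if (nrow(pts) == 0) pts <- matrix(site$translation, 1, 3)
  # voxel union of feasible cuboids, then outward offset, then surfacing
  pitch <- params$step / 2
  sm0 <- cuboid_to_mesh(site)
  sm0$vertices <- sweep(sm0$vertices, 2, site$translation)
  half <- (mesh_bbox(sm0)[2, ] - mesh_bbox(sm0)[1, ]) / 2
  lo <- apply(pts, 2, min) - half - pitch
  hi <- apply(pts, 2, max) + half + pitch
  dim3 <- pmax(1L, as.integer(ceiling((hi - lo) / pitch)))
  if (prod(dim3) > 4e7)
    ctpop_stop("corridor voxel grid too large; increase step", "ctpop_invalid_parameter")
  occ <- array(FALSE, dim = dim3)
  ctrs <- list(lo[1] + (seq_len(dim3[1]) - 0.5) * pitch,
               lo[2] + (seq_len(dim3[2]) - 0.5) * pitch,
               lo[3] + (seq_len(dim3[3]) - 0.5) * pitch)
  rot <- euler_xyz(site$rotation)
  hd <- site$dimensions / 2
  for (r in seq_len(nrow(pts))) {
    ctr <- pts[r, ]
    rng <- lapply(1:3, function(a)
      which(ctrs[[a]] >= ctr[a] - half[a] - pitch / 2 &
            ctrs[[a]] <= ctr[a] + half[a] + pitch / 2))
    if (any(lengths(rng) == 0)) next
    g <- as.matrix(expand.grid(ctrs[[1]][rng[[1]]], ctrs[[2]][rng[[2]]],
                               ctrs[[3]][rng[[3]]]))
    local <- sweep(g, 2, ctr) %*% rot  # world -> local is R^T = %*% rot
    ins <- abs(local[, 1]) <= hd[1] & abs(local[, 2]) <= hd[2] &
      abs(local[, 3]) <= hd[3]
    if (any(ins)) {
      idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))[ins, , drop = FALSE]
      occ[idx] <- TRUE
    }
  }
  grid <- structure(list(origin = lo, pitch = pitch, dim = dim3, occ = occ),
                    class = "voxel_grid")
  r_dilate <- as.integer(ceiling(params$wrap_offset / pitch))
  grid <- dilate_grid(grid, r_dilate)
  out <- voxel_surface_mesh(grid, label = paste0("corridor ", site$id),
                            id = site$id)
  attr(out, "case") <- 2L
  attr(out, "placements") <- fp
  out
}

#' Test whether points lie inside a placed site cuboid
#' @keywords internal
points_in_cuboid <- function(points, site, center = site$translation) {
  rot <- euler_xyz(site$rotation)
  local <- sweep(points, 2, center) %*% rot
  hd <- site$dimensions / 2
  abs(local[, 1]) <= hd[1] & abs(local[, 2]) <= hd[2] & abs(local[, 3]) <= hd[3]
}

#' Test whether points lie inside a closed convex mesh
#' @keywords internal
points_in_convex_mesh <- function(points, mesh, tol = 1e-9) {
  pl <- unique_planes(mesh)
  d <- points %*% t(pl[, 1:3, drop = FALSE]) -
    rep(pl[, 4], each = nrow(points))
  rowSums(d > tol) == 0
}
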