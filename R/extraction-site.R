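#' Cuboid tissue-extraction site
#'
#' A placed cuboid recording where a tissue block was extracted: edge lengths,
#' a rotation applied about the cuboid center, and a translation of that
#' center, all in the millimeter frame of the target reference organ.
#' Rotation is intrinsic X-then-Y-then-Z in degrees (the convention used by
#' all fixtures and readers in this package).
#'
#' @param id site identifier.
#' @param dimensions edge lengths (dx, dy, dz), mm, all positive.
#' @param translation cuboid-center position (tx, ty, tz), mm.
#' @param rotation Euler angles (rx, ry, rz), degrees.
#' @param target_organ reference-organ id the placement refers to.
#' @param organ_sex "male" or "female".
#' @param laterality "left", "right" or "none".
#' @return An object of class `extraction_site`.
#' @export
extraction_site <- function(id, dimensions, translation = c(0, 0, 0),
                            rotation = c(0, 0, 0), target_organ = "",
                            organ_sex = c("female", "male"),
                            laterality = c("none", "left", "right")) {
  dimensions <- as.numeric(dimensions)
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  if (length(dimensions) != 3 || any(!is.finite(dimensions)) || any(dimensions <= 0))
    ctpop_stop("extraction-site dimensions must be three positive numbers",
               "ctpop_invalid_geometry")
  if (any(!is.finite(rotation)))
    ctpop_stop("rotation angles must be finite", "ctpop_invalid_geometry")
  structure(list(id = as.character(id), dimensions = dimensions,
                 translation = translation, rotation = rotation,
                 target_organ = as.character(target_organ),
                 organ_sex = match.arg(organ_sex),
                 laterality = match.arg(laterality)),
            class = "extraction_site")
}

#' @export
print.extraction_site <- function(x, ...) {
  cat(sprintf("<extraction_site> %s: %.3g x %.3g x %.3g mm (%.4g mm^3)\n",
              x$id, x$dimensions[1], x$dimensions[2], x$dimensions[3],
              prod(x$dimensions)))
  cat(sprintf("  center (%.3g, %.3g, %.3g) mm, rotation (%g, %g, %g) deg, organ %s [%s]\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$target_organ, x$organ_sex))
  invisible(x)
}

#' Site volume in cubic millimeters
#' @param site an `extraction_site`.
#' @return dx * dy * dz.
#' @export
site_volume <- function(site) prod(site$dimensions)

# intrinsic X-then-Y-then-Z rotation matrix, angles in degrees
euler_xyz <- function(rotation) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

#' Triangle mesh of a placed extraction-site cuboid
#'
#' Builds the closed 12-triangle cuboid in organ coordinates: local corners at
#' +/- dimensions/2, rotated about the cuboid center (intrinsic X-then-Y-then-Z,
#' degrees), then translated so the center lands on `translation`.
#'
#' @param site an `extraction_site`.
#' @return a closed, outward-oriented `tri_mesh`.
#' @export
cuboid_to_mesh <- function(site) {
  stopifnot(inherits(site, "extraction_site"))
  m <- box_mesh(center = c(0, 0, 0), dims = site$dimensions,
                label = site$id, id = site$id)
  rot <- euler_xyz(site$rotation)
  m$vertices <- m$vertices %*% t(rot)
  m$vertices <- sweep(m$vertices, 2, site$translation, "+")
  m
}

#' Reference organ: a set of anatomical-structure meshes
#'
#' @param id organ identifier.
#' @param sex "male" or "female".
#' @param structures list of `tri_mesh`, one per anatomical structure; ids
#'   must be unique within the organ.
#' @return An object of class `reference_organ`.
#' @export
reference_organ <- function(id, sex = c("female", "male"), structures = list()) {
  ids <- vapply(structures, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    ctpop_stop("anatomical-structure ids must be unique within an organ",
               "ctpop_invalid_input")
  names(structures) <- ids
  structure(list(id = as.character(id), sex = match.arg(sex),
                 structures = structures),
            class = "reference_organ")
}

#' @export
print.reference_organ <- function(x, ...) {
  cat(sprintf("<reference_organ> %s (%s): %d anatomical structures\n",
              x$id, x$sex, length(x$structures)))
  for (m in x$structures)
    cat(sprintf("  %s %s (%d faces)\n", m$id, m$label, nrow(m$faces)))
  invisible(x)
}
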