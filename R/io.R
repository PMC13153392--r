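#' Read a mesh from an OFF file
#'
#' Object File Format: the underlying 3D model format for collision
#' detection. Vertex-count / face-count header, vertex coordinates, then
#' polygonal faces (triangles expected; larger polygons are fan-triangulated).
#'
#' @param path file path.
#' @param label,id passed to [tri_mesh()]; `id` defaults to the file stem.
#' @return a `tri_mesh`.
#' @export
read_off <- function(path, label = "", id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) == "OFF") lines <- lines[-1]
  else if (startsWith(toupper(lines[1]), "OFF"))
    lines[1] <- trimws(sub("^OFF", "", lines[1], ignore.case = TRUE))
  lines <- lines[nzchar(lines)]
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vtx <- do.call(rbind, lapply(lines[2:(1 + nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])))
  faces <- list()
  for (l in lines[(2 + nv):(1 + nv + nf)]) {
    tok <- as.integer(strsplit(l, "\\s+")[[1]])
    k <- tok[1]
    poly <- tok[2:(1 + k)] + 1L
    for (t in seq_len(k - 2))
      faces[[length(faces) + 1]] <- c(poly[1], poly[t + 1], poly[t + 2])
  }
  tri_mesh(vtx, do.call(rbind, faces), label = label, id = id)
}

#' Write a mesh to an OFF file
#'
#' Deterministic output: fixed `%.17g` coordinate formatting and `\n` line
#' endings, so identical meshes serialize byte-identically.
#'
#' @param mesh a `tri_mesh`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
               sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             con = con, sep = "\n")
  invisible(path)
}

# ---- GLB (binary glTF 2.0, minimal single-primitive subset) ----------------

#' Write a mesh to a binary glTF (GLB) file
#'
#' Minimal glTF 2.0 container: one scene, one node, one mesh with a single
#' triangle primitive (float32 POSITION, uint32 indices).
#'
#' @param mesh a `tri_mesh`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_glb <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  idx <- as.integer(t(f)) - 1L
  pos <- as.numeric(t(v))
  idx_bytes <- length(idx) * 4L
  idx_pad <- (4L - idx_bytes %% 4L) %% 4L
  pos_off <- idx_bytes + idx_pad
  pos_bytes <- length(pos) * 4L
  bin_len <- pos_off + pos_bytes
  bin_pad <- (4L - bin_len %% 4L) %% 4L
  gltf <- list(
    asset = list(version = "2.0", generator = "ctpop"),
    scene = 0L, scenes = list(list(nodes = list(0L))),
    nodes = list(list(mesh = 0L, name = mesh$id)),
    meshes = list(list(primitives = list(list(
      attributes = list(POSITION = 1L), indices = 0L, mode = 4L)))),
    buffers = list(list(byteLength = bin_len + bin_pad)),
    bufferViews = list(
      list(buffer = 0L, byteOffset = 0L, byteLength = idx_bytes, target = 34963L),
      list(buffer = 0L, byteOffset = pos_off, byteLength = pos_bytes,
           target = 34962L)),
    accessors = list(
      list(bufferView = 0L, componentType = 5125L, count = length(idx),
           type = "SCALAR"),
      list(bufferView = 1L, componentType = 5126L, count = nrow(v),
           type = "VEC3", min = as.list(apply(v, 2, min)),
           max = as.list(apply(v, 2, max)))))
  json <- jsonlite::toJSON(gltf, auto_unbox = TRUE, digits = NA)
  json_raw <- charToRaw(as.character(json))
  json_pad <- (4L - length(json_raw) %% 4L) %% 4L
  json_raw <- c(json_raw, charToRaw(strrep(" ", json_pad)))
  con <- file(path, "wb")
  on.exit(close(con))
  total <- 12L + 8L + length(json_raw) + 8L + bin_len + bin_pad
  writeBin(c(0x46546C67L, 2L, total), con, size = 4, endian = "little")
  writeBin(c(length(json_raw), 0x4E4F534AL), con, size = 4, endian = "little")
  writeBin(json_raw, con)
  writeBin(c(bin_len + bin_pad, 0x004E4942L), con, size = 4, endian = "little")
  writeBin(idx, con, size = 4, endian = "little")
  if (idx_pad > 0) writeBin(raw(idx_pad), con)
  writeBin(pos, con, size = 4, endian = "little")
  if (bin_pad > 0) writeBin(raw(bin_pad), con)
  invisible(path)
}

#' Read a mesh from a binary glTF (GLB) file
#'
#' Reads the first triangle primitive of the first mesh. Supports float32
#' positions and uint8/uint16/uint32 indices in tightly packed buffer views.
#'
#' @param path file path.
#' @param label,id passed to [tri_mesh()]; `id` defaults to the file stem.
#' @return a `tri_mesh`.
#' @export
read_glb <- function(path, label = "", id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u32 <- function(off) {
    sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (u32(0) != 0x46546C67)
    ctpop_stop("not a GLB file (bad magic)", "ctpop_invalid_input")
  total <- u32(8)
  off <- 12
  json <- NULL; bin <- NULL
  while (off < total) {
    clen <- u32(off); ctype <- u32(off + 4)
    chunk <- raw[(off + 8 + 1):(off + 8 + clen)]
    if (ctype == 0x4E4F534A) json <- chunk else if (ctype == 0x004E4942) bin <- chunk
    off <- off + 8 + clen
  }
  g <- jsonlite::fromJSON(rawToChar(json), simplifyVector = FALSE)
  prim <- g$meshes[[1]]$primitives[[1]]
  read_accessor <- function(ai) {
    acc <- g$accessors[[ai + 1]]
    bv <- g$bufferViews[[acc$bufferView + 1]]
    start <- (if (is.null(bv$byteOffset)) 0 else bv$byteOffset) +
      (if (is.null(acc$byteOffset)) 0 else acc$byteOffset)
    ncomp <- c(SCALAR = 1, VEC2 = 2, VEC3 = 3, VEC4 = 4)[[acc$type]]
    n <- acc$count * ncomp
    con <- rawConnection(bin[(start + 1):length(bin)])
    on.exit(close(con), add = TRUE)
    switch(as.character(acc$componentType),
           "5126" = readBin(con, "double", n = n, size = 4, endian = "little"),
           "5125" = readBin(con, "integer", n = n, size = 4, endian = "little"),
           "5123" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                            endian = "little"),
           "5121" = as.integer(readBin(con, "raw", n = n)),
           ctpop_stop("unsupported accessor component type", "ctpop_invalid_input"))
  }
  pos <- read_accessor(prim$attributes$POSITION)
  idx <- read_accessor(prim$indices)
  tri_mesh(matrix(pos, ncol = 3, byrow = TRUE),
           matrix(as.integer(idx) + 1L, ncol = 3, byrow = TRUE),
           label = label, id = id)
}

#' Convert a GLB mesh file to OFF
#'
#' @param glb_path input GLB file.
#' @param off_path output OFF file; defaults to the same stem.
#' @return the OFF path, invisibly.
#' @export
glb_to_off <- function(glb_path, off_path = sub("\\.glb$", ".off", glb_path)) {
  write_off(read_glb(glb_path), off_path)
}

#' Write a mesh, format chosen by file extension (.off or .glb)
#' @param mesh a `tri_mesh`.
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, off = write_off(mesh, path), glb = write_glb(mesh, path),
         ctpop_stop(sprintf("unsupported mesh format '.%s'", ext),
                    "ctpop_invalid_input"))
}

# ---- reference organ directories -------------------------------------------

#' Write a reference organ as a directory of mesh files plus manifest
#'
#' Layout: one mesh file per anatomical structure, `manifest.csv` with
#' columns `file`, `as_id`, `as_label`, and `organ.json` with the organ id
#' and sex.
#'
#' @param organ a `reference_organ`.
#' @param dir destination directory (created if needed).
#' @param format "off" or "glb".
#' @return `dir`, invisibly.
#' @export
write_reference_organ <- function(organ, dir, format = c("off", "glb")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(organ$structures, function(m) {
    fn <- paste0(m$id, ".", format)
    write_mesh(m, file.path(dir, fn))
    data.frame(file = fn, as_id = m$id, as_label = m$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(id = organ$id, sex = organ$sex),
                       file.path(dir, "organ.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a reference organ from a mesh directory with manifest
#'
#' @param dir directory written by [write_reference_organ()] (or following
#'   the same layout).
#' @return a `reference_organ`.
#' @export
read_reference_organ <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    ctpop_stop(sprintf("no manifest.csv in '%s'", dir), "ctpop_invalid_input")
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  meta <- if (file.exists(file.path(dir, "organ.json")))
    jsonlite::fromJSON(file.path(dir, "organ.json"))
  else list(id = basename(dir), sex = "female")
  structures <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- file.path(dir, manifest$file[i])
    ext <- tolower(sub(".*\\.", "", p))
    m <- switch(ext, off = read_off(p), glb = read_glb(p),
                ctpop_stop(sprintf("unsupported mesh file '%s'", p),
                           "ctpop_invalid_input"))
    m$id <- manifest$as_id[i]
    m$label <- manifest$as_label[i]
    m
  })
  reference_organ(meta$id, meta$sex, structures)
}

# ---- extraction-site JSON ---------------------------------------------------

#' Write extraction sites to a JSON registration file
#' @param sites list of `extraction_site` objects.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_extraction_sites <- function(sites, path) {
  recs <- lapply(sites, function(s)
    list(id = s$id, dimensions = s$dimensions, translation = s$translation,
         rotation = s$rotation, target_organ = s$target_organ,
         organ_sex = s$organ_sex, laterality = s$laterality))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read extraction sites from a JSON registration file
#' @param path file path.
#' @return named list of `extraction_site` objects.
#' @export
read_extraction_sites <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sites <- lapply(recs, function(r)
    extraction_site(r$id, unlist(r$dimensions), unlist(r$translation),
                    unlist(r$rotation), r$target_organ, r$organ_sex,
                    r$laterality))
  stats::setNames(sites, vapply(sites, function(s) s$id, character(1)))
}

# ---- population serialization ----------------------------------------------

#' Serialize populations to JSON
#'
#' Mirrors the atlas product field names: `owner`, `owner_kind`,
#' `annotation_method` (the tool), `modality`, `entries`, optional `markers`
#' and `datasets` (provenance).
#'
#' @param pops list of `ct_population` objects.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_populations_json <- function(pops, path) {
  recs <- lapply(unname(pops), function(p) {
    r <- list(owner = p$owner_id, owner_kind = p$owner_kind,
              annotation_method = p$tool, modality = p$modality,
              entries = p$entries)
    if (!is.null(p$markers)) r$markers <- p$markers
    if (!is.null(attr(p, "datasets"))) r$datasets <- attr(p, "datasets")
    if (!is.null(attr(p, "sex"))) r$sex <- attr(p, "sex")
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Flatten populations to a CSV-ready table
#'
#' One row per (owner, tool, cell type): columns `owner_id`, `owner_kind`,
#' `sex`, `tool`, `as_label`, `ct_id`, `ct_label`, `count`, `percentage`.
#'
#' @param pops list of `ct_population` objects.
#' @return data.frame.
#' @export
populations_to_table <- function(pops) {
  rows <- lapply(unname(pops), function(p) {
    e <- p$entries
    data.frame(owner_id = p$owner_id, owner_kind = p$owner_kind,
               sex = if (!is.null(attr(p, "sex"))) attr(p, "sex") else NA_character_,
               tool = p$tool,
               as_label = if (!is.null(attr(p, "as_label")))
                 attr(p, "as_label") else NA_character_,
               ct_id = e$ct_id, ct_label = e$ct_label,
               count = e$count, percentage = e$percentage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(owner_id = character(0))
  out
}
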