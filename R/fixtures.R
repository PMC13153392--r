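# Synthetic fixtures: reference organs, registrations, annotated cell
# datasets with known ground truth, crosswalks and gene-id lookups. All
# generators are pure functions of their arguments plus the seed, so reruns
# are byte-identical. Geometry is restricted to convex shapes so analytic
# (interval-arithmetic) ground truth is available.

#' Generate a synthetic reference organ
#'
#' Convex anatomical structures (boxes, icospheres, triangular prisms) laid
#' out on a gapped line along x, pairwise disjoint unless overlapping pairs
#' are requested explicitly (for overlap-audit tests).
#'
#' @param n_structures number of structures.
#' @param shapes shape cycle, subset of "box", "sphere", "prism".
#' @param size characteristic edge/diameter in mm.
#' @param gap clearance between neighboring structures, mm.
#' @param sex organ sex.
#' @param id organ id.
#' @param overlap_pairs number of deliberately overlapping neighbor pairs
#'   (appended after the disjoint run).
#' @param seed RNG seed (reserved; the layout itself is deterministic).
#' @return a `reference_organ`; attribute `layout` records centers and sizes.
#' @export
make_reference_organ <- function(n_structures = 3, shapes = "box", size = 2,
                                 gap = 1, sex = "female", id = "organ1",
                                 overlap_pairs = 0, seed = 1) {
  if (n_structures < 1)
    ctpop_stop("need at least one structure", "ctpop_invalid_parameter")
  shapes <- rep(shapes, length.out = n_structures)
  centers <- cbind((seq_len(n_structures) - 1) * (size + gap), 0, 0)
  structures <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    aid <- sprintf("AS%d", i)
    lab <- sprintf("structure %d (%s)", i, shapes[i])
    structures[[i]] <- switch(
      shapes[i],
      box = box_mesh(centers[i, ], rep(size, 3), label = lab, id = aid),
      sphere = icosphere_mesh(centers[i, ], size / 2, subdivisions = 2,
                              label = lab, id = aid),
      prism = prism_mesh(centers[i, ], side = size, height = size,
                         label = lab, id = aid),
      ctpop_stop(sprintf("unknown shape '%s'", shapes[i]),
                 "ctpop_invalid_parameter"))
  }
  if (overlap_pairs > 0) {
    # each overlapping pair: two boxes sharing a size/2 slab, placed on a
    # separate y-line so they stay clear of the disjoint run
    for (k in seq_len(overlap_pairs)) {
      y <- -2 * (size + gap) * k
      n0 <- length(structures)
      structures[[n0 + 1]] <- box_mesh(c(0, y, 0), rep(size, 3),
                                       label = sprintf("overlap %da", k),
                                       id = sprintf("OV%da", k))
      structures[[n0 + 2]] <- box_mesh(c(size / 2, y, 0), rep(size, 3),
                                       label = sprintf("overlap %db", k),
                                       id = sprintf("OV%db", k))
    }
  }
  org <- reference_organ(id, sex, structures)
  attr(org, "layout") <- list(centers = centers, size = size, gap = gap,
                              shapes = shapes)
  org
}

#' Generate extraction sites with known analytic intersection ground truth
#'
#' @param organ organ from [make_reference_organ()].
#' @param n number of sites.
#' @param containment placement scheme: "full" (site strictly inside one
#'   structure), "straddle2" (axis-aligned site spanning two neighboring box
#'   structures), "straddle3" (spanning three), "outside" (disjoint from all).
#' @param seed RNG seed (site-to-structure assignment cycles, so the output
#'   is deterministic).
#' @return named list of `extraction_site`; attribute `ground_truth` is a
#'   data.frame (site_id, as_id, volume, percentage) of analytic
#'   intersection volumes (empty for "outside").
#' @export
make_extraction_sites <- function(organ, n = 1,
                                  containment = c("full", "straddle2",
                                                  "straddle3", "outside"),
                                  seed = 1) {
  containment <- match.arg(containment)
  lay <- attr(organ, "layout")
  if (is.null(lay))
    ctpop_stop("organ lacks fixture layout metadata", "ctpop_invalid_input")
  size <- lay$size; gap <- lay$gap
  nas <- nrow(lay$centers)
  sites <- list()
  gt <- list()
  for (k in seq_len(n)) {
    sid <- sprintf("site-%s-%d", containment, k)
    if (containment == "full") {
      i <- ((k - 1) %% nas) + 1
      dims <- rep(0.4 * size, 3)
      s <- extraction_site(sid, dims, lay$centers[i, ], c(0, 0, 0),
                           target_organ = organ$id, organ_sex = organ$sex)
      gt[[sid]] <- data.frame(site_id = sid, as_id = sprintf("AS%d", i),
                              volume = prod(dims), percentage = 100)
    } else if (containment == "straddle2") {
      pairs <- which(lay$shapes[-nas] == "box" & lay$shapes[-1] == "box")
      if (length(pairs) == 0)
        ctpop_stop("straddle2 needs two neighboring box structures",
                   "ctpop_invalid_parameter")
      i <- pairs[((k - 1) %% length(pairs)) + 1]
      depth <- 0.25 * size                    # penetration into each box
      dx <- gap + 2 * depth
      dims <- c(dx, 0.5 * size, 0.5 * size)
      mid <- (lay$centers[i, ] + lay$centers[i + 1, ]) / 2
      s <- extraction_site(sid, dims, mid, c(0, 0, 0),
                           target_organ = organ$id, organ_sex = organ$sex)
      v <- depth * dims[2] * dims[3]
      gt[[sid]] <- data.frame(site_id = sid,
                              as_id = sprintf("AS%d", c(i, i + 1)),
                              volume = c(v, v),
                              percentage = 100 * c(v, v) / prod(dims))
    } else if (containment == "straddle3") {
      triples <- which(lay$shapes[seq_len(max(nas - 2, 0))] == "box" &
                       lay$shapes[seq_len(max(nas - 2, 0)) + 1] == "box" &
                       lay$shapes[seq_len(max(nas - 2, 0)) + 2] == "box")
      if (length(triples) == 0)
        ctpop_stop("straddle3 needs three neighboring box structures",
                   "ctpop_invalid_parameter")
      i <- triples[((k - 1) %% length(triples)) + 1]
      depth <- 0.25 * size
      ctr <- lay$centers[i + 1, ]
      dx <- (size + gap) * 2 - size + 2 * depth  # from inside box i to box i+2
      dims <- c(dx, 0.5 * size, 0.5 * size)
      s <- extraction_site(sid, dims, ctr, c(0, 0, 0),
                           target_organ = organ$id, organ_sex = organ$sex)
      vend <- depth * dims[2] * dims[3]
      vmid <- size * dims[2] * dims[3]
      gt[[sid]] <- data.frame(site_id = sid,
                              as_id = sprintf("AS%d", c(i + 1, i, i + 2)),
                              volume = c(vmid, vend, vend),
                              percentage = 100 * c(vmid, vend, vend) / prod(dims))
    } else {
      dims <- rep(0.4 * size, 3)
      ctr <- c(0, -10 * (size + gap), 0) - (k - 1) * c(0, size, 0)
      s <- extraction_site(sid, dims, ctr, c(0, 0, 0),
                           target_organ = organ$id, organ_sex = organ$sex)
    }
    sites[[sid]] <- s
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(site_id = character(0), as_id = character(0),
               volume = numeric(0), percentage = numeric(0))
  rownames(gt) <- NULL
  attr(sites, "ground_truth") <- gt
  sites
}

#' Generate an annotated synthetic cell dataset with ground truth
#'
#' Cell labels are drawn from a per-structure cell-type mixture; the count
#' matrix plants `markers_per_ct` exclusive high-expression genes per cell
#' type over a low background, with negative-binomial overdispersion, plus a
#' few ribosomal/mitochondrial genes for QC summaries. The realized (not
#' expected) population is stored as ground truth.
#'
#' @param dataset_id dataset identifier.
#' @param mixture named numeric vector of cell-type fractions (sums to 1);
#'   names are canonical cell-type keys (e.g. "ct1").
#' @param n_cells number of cells.
#' @param tools annotation tools to emulate; each tool labels every cell with
#'   its tool-specific source label `<tool>:<ct>`.
#' @param n_genes number of background genes.
#' @param markers_per_ct planted exclusive markers per cell type.
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param donor named list overriding donor metadata fields (`age`, `sex`,
#'   `bmi`, `race`, `donor_id`).
#' @param seed RNG seed.
#' @return list with `cells` (data.frame: cell_id, ct_label, tool), `counts`
#'   (cells x genes, Ensembl-style ids as colnames), `donor`,
#'   `truth` (realized counts per canonical ct), `markers` (named list of
#'   planted marker gene ids per ct).
#' @export
make_cell_dataset <- function(dataset_id, mixture, n_cells = 500,
                              tools = "azimuth", n_genes = 40,
                              markers_per_ct = 3, dispersion = 0.3,
                              donor = list(), seed = 1) {
  if (abs(sum(mixture) - 1) > 1e-9)
    ctpop_stop("mixture fractions must sum to 1", "ctpop_invalid_parameter")
  set.seed(seed)
  cts <- names(mixture)
  labels <- sample(cts, n_cells, replace = TRUE, prob = mixture)
  cell_ids <- sprintf("%s-c%05d", dataset_id, seq_len(n_cells))
  cells <- do.call(rbind, lapply(tools, function(tl)
    data.frame(cell_id = cell_ids, ct_label = paste(tl, labels, sep = ":"),
               tool = tl, stringsAsFactors = FALSE)))
  # genes: per-ct exclusive markers, background, and QC genes
  marker_ids <- lapply(seq_along(cts), function(i)
    sprintf("ENSF%06d", (i - 1) * markers_per_ct + seq_len(markers_per_ct)))
  names(marker_ids) <- cts
  bg_ids <- sprintf("ENSB%06d", seq_len(n_genes))
  qc_genes <- c("MT-ND1", "MT-CO1", "RPS4X", "RPL13")
  genes <- c(unlist(marker_ids), bg_ids, qc_genes)
  mu <- matrix(1, n_cells, length(genes), dimnames = list(cell_ids, genes))
  for (ct in cts) {
    mu[, marker_ids[[ct]]] <- 0.05
    mu[labels == ct, marker_ids[[ct]]] <- 25
  }
  mu[, qc_genes] <- 2
  size <- if (dispersion > 0) 1 / dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), mu),
    nrow = n_cells, dimnames = dimnames(mu))
  truth <- table(factor(labels, levels = cts))
  donor_defaults <- list(
    donor_id = paste0(dataset_id, "-donor"),
    age = sample(25:70, 1), sex = sample(c("male", "female"), 1),
    bmi = round(stats::runif(1, 19, 34), 1),
    race = sample(c("white", "black", "asian", "other"), 1))
  donor <- utils::modifyList(donor_defaults, donor)
  list(cells = cells, counts = counts, donor = donor,
       truth = as.numeric(truth) |> stats::setNames(cts),
       markers = marker_ids)
}

#' Generate crosswalk, parent map and gene-id lookup fixtures
#'
#' Maps tool-specific source labels `<tool>:<ct>` to canonical ontology ids
#' `CL:000000<k>`. A deterministic fraction of cell types is deliberately
#' left unmapped; optional narrow rows merge sibling cell types onto one more
#' general target. A parent map pools cell types under two high-level
#' classes, and the gene lookup maps planted Ensembl-style ids to approved
#' symbols.
#'
#' @param cts canonical cell-type keys (e.g. c("ct1", "ct2")).
#' @param tools tools to generate rows for.
#' @param unmapped_fraction fraction of cell types (rounded) left out of the
#'   crosswalk entirely.
#' @param narrow_pairs number of adjacent ct pairs merged onto one target by
#'   narrow matches.
#' @param gene_ids Ensembl-style ids to include in the gene lookup.
#' @param seed RNG seed controlling which cts go unmapped.
#' @return list with `crosswalk` ([crosswalk_table()]), `parent_map`,
#'   `gene_lookup`, `ct_ids` (named map ct -> CL id; unmapped cts are NA).
#' @export
make_crosswalk <- function(cts, tools = "azimuth", unmapped_fraction = 0,
                           narrow_pairs = 0, gene_ids = character(0),
                           seed = 1) {
  set.seed(seed)
  k <- length(cts)
  n_unmapped <- round(unmapped_fraction * k)
  unmapped <- if (n_unmapped > 0) sample(cts, n_unmapped) else character(0)
  cl_ids <- stats::setNames(sprintf("CL:%07d", seq_len(k)), cts)
  cl_labels <- stats::setNames(paste("cell type", cts), cts)
  match_type <- stats::setNames(rep("exact", k), cts)
  if (narrow_pairs > 0) {
    # merge ct pairs (1,2), (3,4), ... onto the odd member's target
    for (p in seq_len(narrow_pairs)) {
      a <- 2 * p - 1; b <- 2 * p
      if (b > k) break
      cl_ids[cts[b]] <- cl_ids[cts[a]]
      cl_labels[cts[b]] <- cl_labels[cts[a]]
      match_type[cts[a]] <- "narrow"; match_type[cts[b]] <- "narrow"
    }
  }
  cl_ids[unmapped] <- NA
  rows <- list()
  for (tl in tools) {
    keep <- cts[!cts %in% unmapped]
    rows[[tl]] <- data.frame(
      tool = tl, source_label = paste(tl, keep, sep = ":"),
      source_id = paste0("src:", keep), target_id = cl_ids[keep],
      target_label = cl_labels[keep], match_type = match_type[keep],
      stringsAsFactors = FALSE)
  }
  xw <- crosswalk_table(do.call(rbind, rows))
  mapped_ids <- unique(stats::na.omit(cl_ids))
  parent <- rep(c("CL:HIGH0001", "CL:HIGH0002"), length.out = length(mapped_ids))
  parent_label <- ifelse(parent == "CL:HIGH0001", "high-level class A",
                         "high-level class B")
  parent_map <- data.frame(ct_id = mapped_ids, parent_id = parent,
                           parent_label = parent_label,
                           stringsAsFactors = FALSE)
  gene_lookup <- data.frame(
    stable_id = gene_ids,
    symbol = sprintf("GENE%d", seq_along(gene_ids)),
    stringsAsFactors = FALSE)
  list(crosswalk = xw, parent_map = parent_map, gene_lookup = gene_lookup,
       ct_ids = cl_ids)
}

#' Simulate a complete synthetic study
#'
#' Presets bundle the generators into pipeline-ready inputs with full ground
#' truth:
#' \describe{
#'   \item{small}{3 box structures, one fully contained extraction site per
#'     structure, 6 healthy-adult datasets (2 per site), exact 1:1 crosswalk
#'     -- population recovery is exact by construction.}
#'   \item{kidney-like}{5 structures (boxes with a sphere and a prism in
#'     non-straddled positions), fully contained and two-structure straddling
#'     sites, 10 datasets including gate-failing ones (missing site, minor
#'     donor, missing sex, non-QC source, too few cells).}
#' }
#'
#' @param preset "small" or "kidney-like".
#' @param seed RNG seed driving every stochastic choice.
#' @param out optional directory; when given, all inputs are written in the
#'   formats [build_atlas()] reads (organ mesh directory + manifest, site
#'   JSON, dataset CSV, per-dataset cell CSVs, crosswalk/parent/gene CSVs).
#' @return list with `organ`, `sites`, `datasets`, `cell_tables`,
#'   `counts_matrices`, `crosswalk`, `parent_map`, `gene_lookup`, `truth`
#'   (per-dataset realized counts keyed by ontology id, plus analytic site
#'   intersection percentages), and `config` ready for [build_atlas()].
#' @export
simulate_preset <- function(preset = c("small", "kidney-like"), seed = 1,
                            out = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  n_ct <- 5
  cts <- sprintf("ct%d", seq_len(n_ct))
  if (preset == "small") {
    organ <- make_reference_organ(3, "box", size = 2, gap = 1,
                                  sex = "female", id = "organ-small")
    sites <- make_extraction_sites(organ, 3, "full", seed = seed)
    n_datasets <- 6
    site_of_ds <- rep(names(sites), each = 2)
  } else {
    organ <- make_reference_organ(5, c("box", "box", "box", "sphere", "prism"),
                                  size = 2, gap = 1, sex = "male",
                                  id = "organ-kidney-like")
    full <- make_extraction_sites(organ, 2, "full", seed = seed)
    straddle <- make_extraction_sites(organ, 2, "straddle2", seed = seed)
    sites <- c(full, straddle)
    attr(sites, "ground_truth") <- rbind(attr(full, "ground_truth"),
                                         attr(straddle, "ground_truth"))
    n_datasets <- 10
    site_of_ds <- c(rep(names(sites), length.out = 8), NA, names(sites)[1])
  }
  # one distinct mixture per structure so structures are distinguishable
  as_ids <- names(organ$structures)
  mixtures <- lapply(seq_along(as_ids), function(i) {
    w <- rep(1, n_ct); w[((i - 1) %% n_ct) + 1] <- 6
    stats::setNames(w / sum(w), cts)
  })
  names(mixtures) <- as_ids
  gt_sites <- attr(sites, "ground_truth")
  primary_as <- vapply(names(sites), function(sid) {
    g <- gt_sites[gt_sites$site_id == sid, ]
    g$as_id[which.max(g$volume)]
  }, character(1))
  tools_of <- function(i) if (i %% 3 == 0) c("azimuth", "celltypist") else "azimuth"
  datasets <- list(); cell_tables <- list(); counts_m <- list()
  truth <- list()
  for (i in seq_len(n_datasets)) {
    did <- sprintf("ds%02d", i)
    sid <- site_of_ds[i]
    mix <- if (!is.na(sid)) mixtures[[primary_as[[sid]]]] else mixtures[[1]]
    d <- make_cell_dataset(did, mix, n_cells = 400, tools = tools_of(i),
                           seed = seed * 1000 + i)
    rec <- data.frame(
      dataset_id = did, donor_id = d$donor$donor_id, age = d$donor$age,
      sex = d$donor$sex, bmi = d$donor$bmi, race = d$donor$race,
      modality = "sc_transcriptomics", source = "portal_with_qc",
      extraction_site_id = if (is.na(sid)) NA_character_ else sid,
      disease_status = "healthy", stringsAsFactors = FALSE)
    if (preset == "kidney-like") {
      # planted gate failures
      if (i == 5) rec$age <- 17
      if (i == 6) rec$sex <- NA_character_
      if (i == 7) rec$source <- "other"
      if (i == 10) {                       # too few cells
        d$cells <- d$cells[d$cells$cell_id %in% unique(d$cells$cell_id)[1:50], ]
        d$counts <- d$counts[1:50, , drop = FALSE]
        d$truth <- table(factor(sub("^[a-z]+:", "",
                                    d$cells$ct_label[d$cells$tool == "azimuth"]),
                                levels = cts)) |> as.numeric() |>
          stats::setNames(cts)
      }
    }
    datasets[[did]] <- rec
    cell_tables[[did]] <- d$cells
    counts_m[[did]] <- d$counts
    truth[[did]] <- list(counts = d$truth, markers = d$markers,
                         tools = tools_of(i))
  }
  datasets <- do.call(rbind, datasets)
  rownames(datasets) <- NULL
  gene_ids <- colnames(counts_m[[1]])
  gene_ids <- gene_ids[startsWith(gene_ids, "ENS")]
  xw <- make_crosswalk(cts, tools = c("azimuth", "celltypist"),
                       gene_ids = gene_ids, seed = seed)
  config <- list(organs = list(organ), sites = sites, datasets = datasets,
                 cell_tables = cell_tables, crosswalk = xw$crosswalk,
                 min_cells = 100)
  res <- list(organ = organ, sites = sites, datasets = datasets,
              cell_tables = cell_tables, counts_matrices = counts_m,
              crosswalk = xw$crosswalk, parent_map = xw$parent_map,
              gene_lookup = xw$gene_lookup,
              truth = list(datasets = truth, sites = gt_sites,
                           mixtures = mixtures, ct_ids = xw$ct_ids),
              config = config)
  if (!is.null(out)) write_simulation(res, out)
  res
}

# write a simulated study in the formats the pipeline reads
write_simulation <- function(sim, out) {
  dir.create(file.path(out, "organs", sim$organ$id), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "cells"), recursive = TRUE, showWarnings = FALSE)
  write_reference_organ(sim$organ, file.path(out, "organs", sim$organ$id))
  write_extraction_sites(sim$sites, file.path(out, "sites.json"))
  utils::write.csv(sim$datasets, file.path(out, "datasets.csv"),
                   row.names = FALSE)
  for (did in names(sim$cell_tables))
    utils::write.csv(sim$cell_tables[[did]],
                     file.path(out, "cells", paste0(did, ".cells.csv")),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(sim$crosswalk),
                   file.path(out, "crosswalk.csv"), row.names = FALSE)
  utils::write.csv(sim$parent_map, file.path(out, "parent_map.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$gene_lookup, file.path(out, "gene_lookup.csv"),
                   row.names = FALSE)
  invisible(out)
}
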