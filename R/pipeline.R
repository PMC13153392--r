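#' Minimum-cell filter
#'
#' Datasets with fewer than `threshold` cells (default 100) are filtered out
#' before annotation and population computation.
#'
#' @param n_cells cell count of the dataset (or a cell table, whose rows are
#'   counted).
#' @param threshold minimum cell count to pass.
#' @return logical: `TRUE` when the dataset passes.
#' @export
min_cell_filter <- function(n_cells, threshold = 100) {
  if (is.data.frame(n_cells)) n_cells <- nrow(n_cells)
  isTRUE(n_cells >= threshold)
}

#' Quality-criteria gate for a dataset
#'
#' The four atlas inclusion criteria:
#' \describe{
#'   \item{C1}{the dataset has a registered 3D extraction site with
#'     anatomical-structure tags;}
#'   \item{C2}{the dataset has a cell-type population;}
#'   \item{C3}{the dataset comes from a portal with built-in QA/QC or has an
#'     associated peer-reviewed publication;}
#'   \item{C4}{the donor is a healthy adult: disease status healthy, sex
#'     recorded, and age recorded and greater than 18. A dataset whose source
#'     attests adult-only donors (listed in `adult_only_sources`) passes the
#'     age check despite carrying only an age range.}
#' }
#' Failures are data, not errors.
#'
#' @param dataset one-row data.frame (or list) with fields `dataset_id`,
#'   `extraction_site_id`, `source`, `disease_status`, `age`, `sex`.
#' @param site_tags named list: extraction-site id -> character vector of
#'   structure tags (from [as_tags()]).
#' @param populations named list: dataset id -> list of `ct_population`.
#' @param adult_only_sources sources whose donors are attested adults.
#' @return list with `dataset_id`, `passed`, `failed_criteria`.
#' @export
check_criteria <- function(dataset, site_tags, populations,
                           adult_only_sources = character(0)) {
  failed <- character(0)
  esid <- dataset$extraction_site_id
  has_site <- !is.null(esid) && !is.na(esid) && nzchar(esid)
  if (!has_site || is.null(site_tags[[esid]]) || length(site_tags[[esid]]) == 0)
    failed <- c(failed, "C1")
  pops <- populations[[dataset$dataset_id]]
  if (is.null(pops) || length(pops) == 0)
    failed <- c(failed, "C2")
  if (!isTRUE(dataset$source %in% c("portal_with_qc", "publication")))
    failed <- c(failed, "C3")
  healthy <- isTRUE(dataset$disease_status == "healthy")
  sex_ok <- !is.null(dataset$sex) && !is.na(dataset$sex) &&
    dataset$sex %in% c("male", "female")
  age_ok <- if (isTRUE(dataset$source %in% adult_only_sources)) TRUE else
    !is.null(dataset$age) && !is.na(dataset$age) && dataset$age > 18
  if (!healthy || !sex_ok || !age_ok)
    failed <- c(failed, "C4")
  list(dataset_id = dataset$dataset_id, passed = length(failed) == 0,
       failed_criteria = failed)
}

#' Gate a panel of datasets by the quality criteria and minimum-cell rule
#'
#' @param datasets data.frame of dataset records (one row each; see
#'   [check_criteria()] for fields).
#' @param site_tags named list of structure tags per extraction site.
#' @param populations named list of population lists per dataset.
#' @param cell_counts named numeric vector of cell counts per dataset;
#'   datasets absent from it skip the minimum-cell check.
#' @param min_cells threshold for [min_cell_filter()].
#' @param adult_only_sources passed to [check_criteria()].
#' @return data.frame with columns `dataset_id`, `passed`, `failed_criteria`
#'   (comma-separated subset of C1, C2, C3, C4, MIN_CELLS).
#' @export
gate_datasets <- function(datasets, site_tags, populations,
                          cell_counts = NULL, min_cells = 100,
                          adult_only_sources = character(0)) {
  rows <- lapply(seq_len(nrow(datasets)), function(i) {
    ds <- as.list(datasets[i, , drop = FALSE])
    g <- check_criteria(ds, site_tags, populations, adult_only_sources)
    failed <- g$failed_criteria
    if (!is.null(cell_counts) && ds$dataset_id %in% names(cell_counts) &&
        !min_cell_filter(cell_counts[[ds$dataset_id]], min_cells))
      failed <- c(failed, "MIN_CELLS")
    data.frame(dataset_id = ds$dataset_id, passed = length(failed) == 0,
               failed_criteria = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate dataset populations to their shared extraction site
#'
#' Counts are summed across datasets per cell type, percentages renormalized.
#' All populations must come from the same annotation tool; populations from
#' different tools are never mixed.
#'
#' @param pops list of `ct_population` (owner_kind "dataset") registered to
#'   one extraction site.
#' @param site_id the extraction-site id.
#' @param tool annotation tool; defaults to the populations' common tool.
#' @return a `ct_population` with `owner_kind = "extraction_site"`; the
#'   attribute `datasets` lists the contributing dataset ids.
#' @export
aggregate_extraction_site <- function(pops, site_id, tool = NULL) {
  if (length(pops) == 0)
    ctpop_stop("no populations to aggregate", "ctpop_empty_input")
  tools <- unique(vapply(pops, function(p) p$tool, character(1)))
  if (length(tools) != 1)
    ctpop_stop("refusing to mix annotation tools in one population",
               "ctpop_invalid_input")
  if (is.null(tool)) tool <- tools
  ent <- do.call(rbind, lapply(pops, function(p)
    p$entries[, c("ct_id", "ct_label", "count")]))
  agg <- stats::aggregate(list(count = ent$count),
                          by = list(ct_id = ent$ct_id, ct_label = ent$ct_label),
                          FUN = sum)
  agg <- agg[order(agg$ct_id), , drop = FALSE]
  out <- ct_population(site_id, "extraction_site", tool, agg,
                       modality = pops[[1]]$modality)
  attr(out, "datasets") <- sort(unique(vapply(pops, function(p) p$owner_id,
                                              character(1))))
  out
}

#' Aggregate extraction-site populations into an anatomical-structure
#' population
#'
#' Each contributing site's counts are scaled by its intersection percentage
#' with the structure (percentage_of_site / 100) and summed per cell type;
#' percentages are then renormalized. Weighted counts stay fractional.
#'
#' @param site_pops named list of `ct_population` (owner_kind
#'   "extraction_site"), keyed by site id.
#' @param collisions data.frame from [mesh_collisions()] calls, with columns
#'   `site_id`, `as_id`, `percentage_of_site`; every contributing site must
#'   have a record for `as_id`.
#' @param as_id the anatomical structure to aggregate for.
#' @param sex organ sex recorded on the population.
#' @param as_label optional structure label for the output metadata.
#' @return a `ct_population` with `owner_kind = "anatomical_structure"`;
#'   attributes `sex`, `as_label` and `datasets` carry the metadata and
#'   provenance.
#' @export
aggregate_as_population <- function(site_pops, collisions, as_id, sex,
                                    as_label = NULL) {
  if (length(site_pops) == 0)
    ctpop_stop("no site populations to aggregate", "ctpop_empty_input")
  tools <- unique(vapply(site_pops, function(p) p$tool, character(1)))
  if (length(tools) != 1)
    ctpop_stop("refusing to mix annotation tools in one population",
               "ctpop_invalid_input")
  ents <- list()
  prov <- character(0)
  for (sid in names(site_pops)) {
    rec <- collisions[collisions$site_id == sid & collisions$as_id == as_id, ]
    if (nrow(rec) == 0)
      ctpop_stop(sprintf("site '%s' has no collision record for structure '%s'",
                         sid, as_id), "ctpop_provenance")
    p <- site_pops[[sid]]
    e <- p$entries[, c("ct_id", "ct_label", "count")]
    e$count <- e$count * rec$percentage_of_site[1] / 100
    ents[[sid]] <- e
    prov <- c(prov, attr(p, "datasets"), if (is.null(attr(p, "datasets"))) p$owner_id)
  }
  ent <- do.call(rbind, ents)
  agg <- stats::aggregate(list(count = ent$count),
                          by = list(ct_id = ent$ct_id, ct_label = ent$ct_label),
                          FUN = sum)
  agg <- agg[order(agg$ct_id), , drop = FALSE]
  out <- ct_population(as_id, "anatomical_structure", tools, agg,
                       modality = site_pops[[1]]$modality)
  attr(out, "sex") <- sex
  attr(out, "as_label") <- as_label
  attr(out, "datasets") <- sort(unique(prov))
  out
}

#' Select one population per dataset by tool preference
#'
#' The atlas prefers Azimuth annotation (if present) over CellTypist (if
#' present) over popV; single-modality proteomics populations fall through.
#'
#' @param pops list of `ct_population` for one dataset (one per tool).
#' @param preference ordered character vector of tools.
#' @return the selected `ct_population`.
#' @export
select_tool <- function(pops, preference = c("azimuth", "celltypist", "popv")) {
  if (length(pops) == 0)
    ctpop_stop("no populations to select from", "ctpop_empty_input")
  tools <- vapply(pops, function(p) p$tool, character(1))
  for (t in preference) if (t %in% tools) return(pops[[which(tools == t)[1]]])
  pops[[order(tools)[1]]]
}

#' Build the atlas: gate, collide, crosswalk, aggregate, report
#'
#' Deterministic end-to-end run over a configuration that names the inputs:
#' gate datasets by the quality criteria and minimum-cell rule, compute
#' mesh-based collisions for every referenced extraction site, build dataset
#' populations from cell tables, crosswalk them to ontology terms, aggregate
#' to extraction sites and then -- weighted by intersection percentage -- to
#' anatomical structures, grouped strictly by (organ sex, tool).
#'
#' @param config list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{organs}{list of `reference_organ` objects, or a directory of
#'       organ subdirectories readable by [read_reference_organ()].}
#'     \item{sites}{named list of `extraction_site` objects, or a JSON file
#'       for [read_extraction_sites()].}
#'     \item{datasets}{data.frame of dataset records, or a CSV path.}
#'     \item{cell_tables}{named list (by dataset id) of cell-table
#'       data.frames, or a directory of `<dataset_id>.cells.csv` files.}
#'     \item{crosswalk}{a [crosswalk_table()] or CSV path.}
#'     \item{min_cells, adult_only_sources, tool_preference}{optional gate
#'       and selection settings.}
#'   }
#' @param out optional output directory; when given, populations (JSON +
#'   flat CSVs), the gate/collision/unmapped reports, count tables and a run
#'   log are written there deterministically.
#' @return list with elements `aspop`, `despop_sites`, `despop_datasets`,
#'   `gate`, `collisions`, `unmapped`, `counts`, `log`.
#' @export
build_atlas <- function(config, out = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  organs <- config$organs
  if (is.character(organs)) {
    dirs <- list.dirs(organs, recursive = FALSE)
    organs <- lapply(dirs, read_reference_organ)
  }
  names(organs) <- vapply(organs, function(o) o$id, character(1))
  sites <- config$sites
  if (is.character(sites)) sites <- read_extraction_sites(sites)
  datasets <- config$datasets
  if (is.character(datasets))
    datasets <- utils::read.csv(datasets, stringsAsFactors = FALSE)
  cell_tables <- config$cell_tables
  if (is.character(cell_tables)) {
    files <- sort(list.files(cell_tables, pattern = "\\.cells\\.csv$",
                             full.names = TRUE))
    cell_tables <- stats::setNames(
      lapply(files, utils::read.csv, stringsAsFactors = FALSE),
      sub("\\.cells\\.csv$", "", basename(files)))
  }
  xwalk <- config$crosswalk
  if (is.character(xwalk))
    xwalk <- crosswalk_table(utils::read.csv(xwalk, stringsAsFactors = FALSE))
  min_cells <- if (is.null(config$min_cells)) 100 else config$min_cells
  adult_only <- if (is.null(config$adult_only_sources)) character(0) else
    config$adult_only_sources
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  note("datasets: %d, sites: %d, organs: %d", nrow(datasets), length(sites),
       length(organs))

  # collisions for every site referenced by a dataset
  used_sites <- sort(unique(stats::na.omit(datasets$extraction_site_id)))
  collisions <- list()
  site_tags <- list()
  for (sid in used_sites) {
    s <- sites[[sid]]
    if (is.null(s)) next
    org <- organs[[s$target_organ]]
    if (is.null(org))
      ctpop_stop(sprintf("site '%s' targets unknown organ '%s'", sid,
                         s$target_organ), "ctpop_invalid_input")
    col <- mesh_collisions(s, org)
    if (nrow(col) > 0) {
      col <- cbind(site_id = sid, col, stringsAsFactors = FALSE)
      collisions[[sid]] <- col
    }
    site_tags[[sid]] <- col$as_label
  }
  collisions <- if (length(collisions)) do.call(rbind, collisions) else
    data.frame(site_id = character(0), as_id = character(0),
               as_label = character(0), organ_id = character(0),
               intersection_volume = numeric(0),
               percentage_of_site = numeric(0), method = character(0))
  rownames(collisions) <- NULL
  note("collision records: %d over %d sites", nrow(collisions),
       length(unique(collisions$site_id)))

  # dataset populations per tool, crosswalked
  ds_pops <- list()   # dataset_id -> list of ct_population
  unmapped <- list()
  for (did in sort(names(cell_tables))) {
    tab <- cell_tables[[did]]
    if (nrow(tab) == 0) next
    mod <- datasets$modality[match(did, datasets$dataset_id)]
    if (is.na(mod) || !nzchar(mod)) mod <- "sc_transcriptomics"
    for (tl in sort(unique(tab$tool))) {
      sub <- tab[tab$tool == tl, , drop = FALSE]
      pop <- population_from_cell_table(sub, tool = tl, owner_id = did,
                                        modality = mod)
      cw <- apply_crosswalk(pop, xwalk)
      ds_pops[[did]] <- c(ds_pops[[did]], list(cw$population))
      if (length(cw$unmapped))
        unmapped[[paste(did, tl)]] <- data.frame(
          dataset_id = did, tool = tl, source_label = cw$unmapped,
          stringsAsFactors = FALSE)
    }
  }
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else
    data.frame(dataset_id = character(0), tool = character(0),
               source_label = character(0))
  rownames(unmapped) <- NULL

  cell_counts <- vapply(cell_tables, function(t)
    length(unique(t$cell_id)), numeric(1))
  gate <- gate_datasets(datasets, site_tags, ds_pops, cell_counts,
                        min_cells = min_cells, adult_only_sources = adult_only)
  passing <- gate$dataset_id[gate$passed]
  note("gate: %d of %d datasets pass", length(passing), nrow(gate))

  # extraction-site populations per (site, tool) over passing datasets
  site_pops <- list()  # "<site>|<tool>" -> ct_population
  for (sid in used_sites) {
    dids <- datasets$dataset_id[datasets$extraction_site_id %in% sid]
    dids <- sort(intersect(dids, passing))
    if (!length(dids)) next
    tools <- sort(unique(unlist(lapply(dids, function(d)
      vapply(ds_pops[[d]], function(p) p$tool, character(1))))))
    for (tl in tools) {
      contrib <- list()
      for (d in dids) {
        for (p in ds_pops[[d]]) if (p$tool == tl) contrib[[d]] <- p
      }
      if (length(contrib))
        site_pops[[paste(sid, tl, sep = "|")]] <-
          aggregate_extraction_site(contrib, sid, tl)
    }
  }
  note("extraction-site populations: %d", length(site_pops))

  # anatomical-structure populations per (organ sex, tool, AS)
  aspop <- list()
  if (nrow(collisions) > 0 && length(site_pops) > 0) {
    keys <- strsplit(names(site_pops), "|", fixed = TRUE)
    sp_site <- vapply(keys, `[`, character(1), 1)
    sp_tool <- vapply(keys, `[`, character(1), 2)
    for (tl in sort(unique(sp_tool))) {
      for (oid in sort(names(organs))) {
        org <- organs[[oid]]
        col_o <- collisions[collisions$organ_id == oid, , drop = FALSE]
        for (aid in sort(unique(col_o$as_id))) {
          sids <- col_o$site_id[col_o$as_id == aid]
          sel <- sp_tool == tl & sp_site %in% sids
          if (!any(sel)) next
          sps <- stats::setNames(site_pops[sel], sp_site[sel])
          pop <- aggregate_as_population(
            sps, col_o, aid, sex = org$sex,
            as_label = org$structures[[aid]]$label)
          aspop[[paste(org$sex, tl, aid, sep = "|")]] <- pop
        }
      }
    }
  }
  note("anatomical-structure populations: %d", length(aspop))

  ds_pops_pass <- unlist(lapply(sort(passing), function(d) ds_pops[[d]]),
                         recursive = FALSE)
  res <- list(aspop = aspop, despop_sites = site_pops,
              despop_datasets = ds_pops_pass, gate = gate,
              collisions = collisions, unmapped = unmapped, log = log)
  res$counts <- report_counts(res, datasets, sites)
  if (!is.null(out)) write_atlas_outputs(res, out)
  res
}

#' Count tables for an atlas build
#'
#' Counts of datasets, extraction sites, anatomical structures and organs in
#' the built atlas, split by sex, tool and modality.
#'
#' @param atlas result list from [build_atlas()].
#' @param datasets dataset metadata used for the build.
#' @param sites the extraction-site registry used for the build.
#' @return list of data.frames `totals` and `by_group`.
#' @export
report_counts <- function(atlas, datasets, sites) {
  passing <- atlas$gate$dataset_id[atlas$gate$passed]
  ds <- datasets[datasets$dataset_id %in% passing, , drop = FALSE]
  used_sites <- sort(unique(stats::na.omit(ds$extraction_site_id)))
  hit_as <- unique(atlas$collisions[atlas$collisions$site_id %in% used_sites,
                                    c("organ_id", "as_id")])
  totals <- data.frame(
    datasets = length(passing),
    extraction_sites = length(used_sites),
    anatomical_structures = nrow(hit_as),
    organs = length(unique(hit_as$organ_id)))
  by_group <- if (nrow(ds) > 0) {
    sexes <- vapply(ds$extraction_site_id, function(sid)
      if (!is.na(sid) && !is.null(sites[[sid]])) sites[[sid]]$organ_sex
      else NA_character_, character(1))
    agg <- stats::aggregate(list(datasets = ds$dataset_id),
                            by = list(sex = sexes, modality = ds$modality),
                            FUN = length)
    agg[order(agg$sex, agg$modality), , drop = FALSE]
  } else data.frame(sex = character(0), modality = character(0),
                    datasets = integer(0))
  rownames(by_group) <- NULL
  list(totals = totals, by_group = by_group)
}

# deterministic on-disk outputs for a build
write_atlas_outputs <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_populations_json(res$aspop, file.path(out, "aspop.json"))
  write_populations_json(c(res$despop_sites, res$despop_datasets),
                         file.path(out, "despop.json"))
  utils::write.csv(populations_to_table(res$aspop),
                   file.path(out, "cell_types_per_anatomical_structure.csv"),
                   row.names = FALSE)
  utils::write.csv(populations_to_table(res$despop_sites),
                   file.path(out, "cell_types_per_extraction_site.csv"),
                   row.names = FALSE)
  utils::write.csv(populations_to_table(res$despop_datasets),
                   file.path(out, "cell_types_per_dataset.csv"),
                   row.names = FALSE)
  utils::write.csv(res$gate, file.path(out, "gate_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$collisions, file.path(out, "collision_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$unmapped, file.path(out, "unmapped_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$counts$totals, file.path(out, "counts_totals.csv"),
                   row.names = FALSE)
  utils::write.csv(res$counts$by_group, file.path(out, "counts_by_group.csv"),
                   row.names = FALSE)
  writeLines(res$log, file.path(out, "run_log.txt"))
  invisible(out)
}
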