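#' Cell-type population
#'
#' A listing of unique cell types and their counts for one owner (a dataset,
#' an extraction site, or an anatomical structure), produced by exactly one
#' annotation tool. Counts may be fractional after intersection-percentage
#' weighting; percentages are always renormalized to sum to 100.
#'
#' @param owner_id identifier of the owning entity.
#' @param owner_kind one of "dataset", "extraction_site",
#'   "anatomical_structure".
#' @param tool annotation tool: "azimuth", "celltypist", "popv" or
#'   "sc_proteomics".
#' @param entries data.frame with columns `ct_id`, `ct_label`, `count`
#'   (nonnegative); a `percentage` column is (re)computed.
#' @param modality "sc_transcriptomics" or "sc_proteomics".
#' @param markers optional named list (by `ct_id`) of data.frames with
#'   columns `gene`, `mean_in_group`, `mean_rest`.
#' @return An object of class `ct_population`.
#' @export
ct_population <- function(owner_id, owner_kind = c("dataset", "extraction_site",
                                                   "anatomical_structure"),
                          tool, entries,
                          modality = c("sc_transcriptomics", "sc_proteomics"),
                          markers = NULL) {
  owner_kind <- match.arg(owner_kind)
  modality <- match.arg(modality)
  tool <- match.arg(tool, c("azimuth", "celltypist", "popv", "sc_proteomics"))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("ct_id", "ct_label", "count") %in% names(entries)))
  if (any(entries$count < 0))
    ctpop_stop("cell-type counts must be nonnegative", "ctpop_invalid_input")
  if (anyDuplicated(entries$ct_id))
    ctpop_stop("ct_id must be unique within a population", "ctpop_invalid_input")
  total <- sum(entries$count)
  entries$percentage <- if (total > 0) 100 * entries$count / total else
    rep(0, nrow(entries))
  rownames(entries) <- NULL
  structure(list(owner_id = as.character(owner_id), owner_kind = owner_kind,
                 tool = tool, modality = modality,
                 entries = entries[, c("ct_id", "ct_label", "count", "percentage")],
                 markers = markers),
            class = "ct_population")
}

#' @export
print.ct_population <- function(x, ...) {
  cat(sprintf("<ct_population> %s (%s, %s): %d cell types, %.4g cells\n",
              x$owner_id, x$owner_kind, x$tool, nrow(x$entries),
              sum(x$entries$count)))
  print(utils::head(x$entries[order(-x$entries$count), ], 8), row.names = FALSE)
  invisible(x)
}

#' Total cell count of a population
#' @param pop a `ct_population`.
#' @return numeric; fractional after intersection weighting.
#' @export
total_cells <- function(pop) sum(pop$entries$count)

#' Build a cell-type population from an annotated cell table
#'
#' Counts label multiplicities in a per-cell annotation table and normalizes
#' to percentages.
#'
#' @param cells data.frame with columns `cell_id`, `ct_label`, optional
#'   `ct_id` (defaults to the label) and `tool`.
#' @param tool annotation tool; defaults to the table's unique `tool` value.
#' @param owner_id owner of the resulting population.
#' @param modality passed to [ct_population()].
#' @return a `ct_population` with `owner_kind = "dataset"`.
#' @export
population_from_cell_table <- function(cells, tool = NULL, owner_id = "dataset",
                                       modality = "sc_transcriptomics") {
  if (is.null(cells) || nrow(cells) == 0)
    ctpop_stop("cell table is empty", "ctpop_empty_input")
  if (anyDuplicated(cells$cell_id))
    ctpop_stop("duplicate cell_id in cell table", "ctpop_duplicate_cell")
  if (is.null(tool)) {
    tool <- unique(cells$tool)
    if (length(tool) != 1)
      ctpop_stop("cell table mixes tools; pass `tool` explicitly",
                 "ctpop_invalid_input")
  }
  if (is.null(cells$ct_id)) cells$ct_id <- cells$ct_label
  tab <- stats::aggregate(list(count = cells$cell_id),
                          by = list(ct_id = cells$ct_id, ct_label = cells$ct_label),
                          FUN = length)
  tab <- tab[order(tab$ct_id), , drop = FALSE]
  ct_population(owner_id, "dataset", tool, tab, modality = modality)
}

#' Crosswalk table from tool labels to ontology terms
#'
#' @param rows data.frame with columns `tool`, `source_label`, `source_id`,
#'   `target_id`, `target_label`, `match_type` ("exact" or "narrow").
#' @return validated data.frame of class `crosswalk_table`.
#' @export
crosswalk_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("tool", "source_label", "source_id", "target_id", "target_label",
            "match_type")
  stopifnot(all(need %in% names(rows)))
  if (!all(rows$match_type %in% c("exact", "narrow")))
    ctpop_stop("match_type must be 'exact' or 'narrow'", "ctpop_invalid_input")
  if (anyDuplicated(rows[, c("tool", "source_label")]))
    ctpop_stop("(tool, source_label) must be unique in a crosswalk",
               "ctpop_invalid_input")
  class(rows) <- c("crosswalk_table", "data.frame")
  rows
}

#' Apply an ontology crosswalk to a population
#'
#' Re-keys tool-assigned labels to ontology terms. Two source labels mapping
#' to one target (a narrow match onto a more general class) are merged with
#' counts summed. Labels absent from the crosswalk are retained with their
#' original key, flagged `not_crosswalked`, and listed in the unmapped report
#' -- unmapped is data, not an error.
#'
#' @param pop a `ct_population`.
#' @param table a [crosswalk_table()].
#' @return list with elements `population` (re-keyed) and `unmapped`
#'   (character vector of source labels without a mapping).
#' @export
apply_crosswalk <- function(pop, table) {
  tw <- table[table$tool == pop$tool, , drop = FALSE]
  e <- pop$entries
  m <- match(e$ct_label, tw$source_label)
  mapped <- !is.na(m)
  new_id <- ifelse(mapped, tw$target_id[m], e$ct_id)
  new_label <- ifelse(mapped, tw$target_label[m], e$ct_label)
  crosswalked <- mapped
  agg <- stats::aggregate(list(count = e$count),
                          by = list(ct_id = new_id, ct_label = new_label,
                                    crosswalked = crosswalked),
                          FUN = sum)
  agg <- agg[order(agg$ct_id), , drop = FALSE]
  out <- ct_population(pop$owner_id, pop$owner_kind, pop$tool,
                       agg[, c("ct_id", "ct_label", "count")],
                       modality = pop$modality, markers = pop$markers)
  out$entries$not_crosswalked <- !agg$crosswalked
  list(population = out, unmapped = sort(unique(e$ct_label[!mapped])))
}

#' Roll a population up to high-level parent cell types
#'
#' Aggregates counts under parent terms of the ontology's high-level slim.
#' Crosswalked types with no parent mapping are pooled under
#' `no_mapped_parent`; types that were never crosswalked are pooled under
#' `not_crosswalked`.
#'
#' @param pop a `ct_population` (after [apply_crosswalk()]).
#' @param parent_map data.frame with columns `ct_id`, `parent_id`,
#'   `parent_label`.
#' @return a rolled-up `ct_population`.
#' @export
rollup_to_parents <- function(pop, parent_map) {
  e <- pop$entries
  ncw <- if (!is.null(e$not_crosswalked)) e$not_crosswalked else
    rep(FALSE, nrow(e))
  m <- match(e$ct_id, parent_map$ct_id)
  pid <- ifelse(ncw, "not_crosswalked",
                ifelse(is.na(m), "no_mapped_parent", parent_map$parent_id[m]))
  plab <- ifelse(ncw, "not crosswalked",
                 ifelse(is.na(m), "no mapped parent cell",
                        parent_map$parent_label[m]))
  agg <- stats::aggregate(list(count = e$count),
                          by = list(ct_id = pid, ct_label = plab), FUN = sum)
  agg <- agg[order(agg$ct_id), , drop = FALSE]
  ct_population(pop$owner_id, pop$owner_kind, pop$tool, agg,
                modality = pop$modality)
}

#' Weighted cosine similarity between two populations
#'
#' Populations are expanded to percentage vectors over the union of their
#' cell-type ids (absent types contribute 0) and compared by
#' sum(w u v) / (sqrt(sum(w u^2)) sqrt(sum(w v^2))). Zero when either norm
#' vanishes. With unit weights this is plain cosine similarity.
#'
#' @param pop_a,pop_b `ct_population` objects.
#' @param weights optional named numeric vector of per-cell-type weights
#'   (default all 1); must be nonnegative.
#' @return similarity in [0, 1] for nonnegative vectors.
#' @export
weighted_cosine <- function(pop_a, pop_b, weights = NULL) {
  ids <- sort(union(pop_a$entries$ct_id, pop_b$entries$ct_id))
  u <- stats::setNames(rep(0, length(ids)), ids)
  v <- u
  u[pop_a$entries$ct_id] <- pop_a$entries$percentage
  v[pop_b$entries$ct_id] <- pop_b$entries$percentage
  w <- rep(1, length(ids))
  if (!is.null(weights)) {
    if (any(weights < 0))
      ctpop_stop("weights must be nonnegative", "ctpop_invalid_parameter")
    names(w) <- ids
    hit <- ids %in% names(weights)
    w[hit] <- weights[ids[hit]]
  }
  nu <- sqrt(sum(w * u^2)); nv <- sqrt(sum(w * v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(w * u * v) / (nu * nv)
}

#' Rank candidate tissue origins by population similarity
#'
#' Sorts candidate populations (e.g. anatomical structures or other
#' extraction sites) by descending weighted cosine similarity to the query
#' population; ties are broken lexicographically by candidate id.
#'
#' @param pop query `ct_population`.
#' @param candidates named list of `ct_population` objects.
#' @param weights passed to [weighted_cosine()].
#' @return data.frame with columns `id`, `similarity`, best first.
#' @export
predict_origin <- function(pop, candidates, weights = NULL) {
  if (length(candidates) < 1)
    ctpop_stop("at least one candidate is required", "ctpop_invalid_input")
  sims <- vapply(candidates, weighted_cosine, numeric(1), pop_a = pop,
                 weights = weights)
  out <- data.frame(id = names(candidates), similarity = unname(sims),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardized z-scores of mean cell-type percentages
#'
#' Standardizes each cell-type row of a (cell type x anatomical structure)
#' matrix of mean percentages: Z = (x - mu) / sigma, with mu the row mean and
#' sigma the population standard deviation over the row. Rows with sigma = 0
#' map to 0. Non-constant rows therefore have mean 0 and population SD 1.
#'
#' @param mean_pct numeric matrix, cell types in rows.
#' @return matrix of the same shape.
#' @export
zscore_matrix <- function(mean_pct) {
  mean_pct <- as.matrix(mean_pct)
  if (any(!is.finite(mean_pct)))
    ctpop_stop("matrix must be finite", "ctpop_invalid_input")
  z <- t(apply(mean_pct, 1, function(x) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma == 0) rep(0, length(x)) else (x - mu) / sigma
  }))
  if (ncol(mean_pct) == 1) z <- matrix(0, nrow(mean_pct), 1)
  dimnames(z) <- dimnames(mean_pct)
  z
}
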