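#' Rank marker genes per cell type
#'
#' Differential expression of each cell type against the rest of the dataset.
#' Raw counts are normalized per cell to 10,000 total (CP10K) and log1p
#' transformed; each gene is then scored by the standardized mean difference
#' between the in-group and rest-of-dataset expression (difference of means
#' over the pooled standard deviation). The top-`n` genes per cell type are
#' returned together with their mean in-group and mean rest expression on the
#' normalized log scale. Ties are broken lexicographically by gene symbol, so
#' the ranking is deterministic.
#'
#' @param cells data.frame with columns `cell_id` and `ct_label` (and
#'   optionally `ct_id`, used as the key when present).
#' @param counts numeric matrix of raw counts, cells x genes, rownames
#'   matching `cell_id`, colnames = gene symbols.
#' @param n number of top genes per cell type (default 10); when larger than
#'   the gene count, all genes are returned ranked.
#' @return named list (by cell-type key) of data.frames with columns `gene`,
#'   `score`, `mean_in_group`, `mean_rest`.
#' @export
rank_markers <- function(cells, counts, n = 10) {
  if (is.null(counts))
    ctpop_stop("a counts matrix is required", "ctpop_invalid_input")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- cells$cell_id
  counts <- counts[match(cells$cell_id, rownames(counts)), , drop = FALSE]
  key <- if (!is.null(cells$ct_id)) cells$ct_id else cells$ct_label
  groups <- sort(unique(key))
  if (length(groups) < 2)
    ctpop_stop("marker ranking needs at least two cell-type groups",
               "ctpop_no_contrast")
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  x <- log1p(counts / tot * 1e4)
  out <- list()
  for (g in groups) {
    ing <- key == g
    n1 <- sum(ing); n2 <- sum(!ing)
    m1 <- colMeans(x[ing, , drop = FALSE])
    m2 <- colMeans(x[!ing, , drop = FALSE])
    v1 <- apply(x[ing, , drop = FALSE], 2, stats::var)
    v2 <- apply(x[!ing, , drop = FALSE], 2, stats::var)
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / max(n1 + n2 - 2, 1))
    score <- (m1 - m2) / (sp + 1e-9)
    ord <- order(-score, colnames(x))
    take <- ord[seq_len(min(n, ncol(x)))]
    out[[g]] <- data.frame(gene = colnames(x)[take], score = score[take],
                           mean_in_group = m1[take], mean_rest = m2[take],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Normalize gene identifiers to approved symbols
#'
#' Replaces stable identifiers (e.g. Ensembl gene ids) found in a lookup
#' table by their approved symbols; identifiers absent from the lookup are
#' passed through unchanged and reported, so downstream steps never lose
#' genes to harmonization.
#'
#' @param genes character vector of gene identifiers or symbols.
#' @param lookup data.frame with columns `stable_id`, `symbol`.
#' @return list with elements `genes` (normalized vector, same length/order)
#'   and `unmatched` (identifiers not found and not already symbols).
#' @export
normalize_gene_ids <- function(genes, lookup) {
  m <- match(genes, lookup$stable_id)
  out <- ifelse(is.na(m), genes, lookup$symbol[m])
  already <- genes %in% lookup$symbol
  unmatched <- sort(unique(genes[is.na(m) & !already]))
  list(genes = out, unmatched = unmatched)
}

#' Ribosomal and mitochondrial QC percentages for a dataset
#'
#' Per-cell percentages of total raw counts falling on ribosomal genes
#' (symbols prefixed RPS/RPL) and mitochondrial genes (prefixed MT-), then
#' dataset-level mean, median and standard deviation, plus the mean number of
#' genes with positive counts and the mean total counts per cell. Cells with
#' zero total counts are excluded from the percentages and counted in the
#' report.
#'
#' @param counts raw count matrix, cells x genes, colnames = normalized
#'   gene symbols.
#' @return one-row data.frame of QC summaries.
#' @export
qc_gene_percentages <- function(counts) {
  counts <- as.matrix(counts)
  sym <- colnames(counts)
  ribo <- grepl("^RP[SL]", sym)
  mito <- grepl("^MT-", sym)
  tot <- rowSums(counts)
  nonzero <- tot > 0
  pr <- if (any(ribo)) 100 * rowSums(counts[, ribo, drop = FALSE]) / pmax(tot, 1)
    else rep(0, nrow(counts))
  pm <- if (any(mito)) 100 * rowSums(counts[, mito, drop = FALSE]) / pmax(tot, 1)
    else rep(0, nrow(counts))
  pr <- pr[nonzero]; pm <- pm[nonzero]
  data.frame(
    n_cells = nrow(counts),
    n_zero_cells = sum(!nonzero),
    pct_ribosomal_mean = mean(pr), pct_ribosomal_median = stats::median(pr),
    pct_ribosomal_sd = stats::sd(pr),
    pct_mitochondrial_mean = mean(pm),
    pct_mitochondrial_median = stats::median(pm),
    pct_mitochondrial_sd = stats::sd(pm),
    genes_with_positive_counts_mean = mean(rowSums(counts[nonzero, , drop = FALSE] > 0)),
    total_counts_mean = mean(tot[nonzero]))
}
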