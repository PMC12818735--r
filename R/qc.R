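#' Quality-control configuration
#'
#' Defaults follow the standard single-cell filtering recipe for UMI data:
#' cells with fewer than 1000 total counts, fewer than 1000 detected genes,
#' or more than 15% mitochondrial content are removed; genes detected in
#' fewer than 3 cells, mitochondrial genes, and ribosomal genes are removed;
#' normalization scales each cell to 10,000 counts before `log(1 + x)`;
#' 2000 highly variable genes are selected as classifier features.
#'
#' @param min_counts_per_cell,min_genes_per_cell Minimum total counts /
#'   detected genes per kept cell.
#' @param max_mito_fraction Maximum mitochondrial fraction of a kept cell;
#'   cells strictly above it are removed (a cell at exactly the boundary is
#'   kept).
#' @param min_cells_per_gene Minimum number of cells a kept gene is detected
#'   in.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes
#'   (mouse convention `"mt-"`; matching is case-sensitive).
#' @param ribo_prefixes Prefixes identifying ribosomal genes.
#' @param scale_factor Per-cell library-size target of [normalize_counts()].
#' @param n_hvgs Number of highly variable genes returned by
#'   [select_hvgs()].
#' @param n_bins Mean-expression bins used to standardize dispersions in
#'   [select_hvgs()].
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_counts_per_cell = 1000, min_genes_per_cell = 1000,
                      max_mito_fraction = 0.15, min_cells_per_gene = 3,
                      mito_prefix = "mt-", ribo_prefixes = c("Rps", "Rpl"),
                      scale_factor = 10000, n_hvgs = 2000, n_bins = 20) {
  if (min_counts_per_cell < 0 || min_genes_per_cell < 0 || min_cells_per_gene < 0)
    config_error("min_counts_per_cell", "thresholds must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    config_error("max_mito_fraction", "must be in [0, 1]")
  if (scale_factor <= 0) config_error("scale_factor", "must be positive")
  structure(list(min_counts_per_cell = min_counts_per_cell,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix, ribo_prefixes = ribo_prefixes,
                 scale_factor = scale_factor, n_hvgs = n_hvgs,
                 n_bins = n_bins),
            class = "qc_config")
}

mito_genes <- function(gene_ids, cfg) startsWith(gene_ids, cfg$mito_prefix)

#' Filter low-quality cells
#'
#' Keeps cells with total counts >= `min_counts_per_cell`, detected genes >=
#' `min_genes_per_cell`, and mitochondrial fraction <= `max_mito_fraction`.
#' A cell may fail several criteria; the report counts each.
#'
#' @param counts Sparse gene x cell count matrix with dimnames.
#' @param cfg A [qc_config()].
#' @return A list with `counts` (the filtered matrix, column order preserved)
#'   and `report` (per-criterion removal counts).
#' @export
filter_cells <- function(counts, cfg = qc_config()) {
  assert_count_matrix(counts)
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- mito_genes(rownames(counts), cfg)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(counts))
  fail_counts <- totals < cfg$min_counts_per_cell
  fail_genes <- detected < cfg$min_genes_per_cell
  fail_mito <- mito_frac > cfg$max_mito_fraction
  keep <- !(fail_counts | fail_genes | fail_mito)
  report <- list(n_input = ncol(counts), n_kept = sum(keep),
                 removed_low_counts = sum(fail_counts),
                 removed_low_genes = sum(fail_genes),
                 removed_high_mito = sum(fail_mito),
                 removed_total = sum(!keep))
  if (!any(keep)) warning("filter_cells removed every cell", call. = FALSE)
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Filter genes
#'
#' Removes genes detected in fewer than `min_cells_per_gene` cells, and all
#' mitochondrial and ribosomal genes (recognized by symbol prefix).
#'
#' @inheritParams filter_cells
#' @return The filtered count matrix (row order preserved).
#' @export
filter_genes <- function(counts, cfg = qc_config()) {
  assert_count_matrix(counts)
  detected_in <- Matrix::rowSums(counts > 0)
  drop_prefix <- mito_genes(rownames(counts), cfg)
  for (p in cfg$ribo_prefixes)
    drop_prefix <- drop_prefix | startsWith(rownames(counts), p)
  keep <- detected_in >= cfg$min_cells_per_gene & !drop_prefix
  counts[keep, , drop = FALSE]
}

#' Library-size log-normalization
#'
#' Each entry becomes `log(1 + count / cell_total * scale_factor)`, so per
#' cell `sum(expm1(values))` equals `scale_factor` exactly (up to floating
#' point).
#'
#' @inheritParams filter_cells
#' @return A sparse normalized expression matrix with the input dimnames.
#' @export
normalize_counts <- function(counts, cfg = qc_config()) {
  assert_count_matrix(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop(sprintf("cell(s) with zero total counts (e.g. `%s`); run filter_cells first",
                 colnames(counts)[which(totals == 0)[1]]), call. = FALSE)
  norm <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix") %*%
    Matrix::Diagonal(x = cfg$scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' The classic dispersion-based recipe: per gene, mean and dispersion
#' (variance/mean) are computed on the de-logged (`expm1`) normalized values;
#' genes are grouped into `n_bins` equal-width bins of mean expression, the
#' dispersion is z-scored within each bin, and genes are ranked by the
#' standardized dispersion. Deterministic; ties are broken by gene identifier
#' order, so the result is stable under gene reordering.
#'
#' @param norm Normalized expression matrix from [normalize_counts()].
#' @param cfg A [qc_config()]; uses `n_hvgs` and `n_bins`.
#' @return Character vector of gene identifiers, length
#'   `min(n_hvgs, n_genes)`, ordered most to least variable.
#' @export
select_hvgs <- function(norm, cfg = qc_config()) {
  assert_count_matrix(norm, "norm")
  e <- methods::as(methods::as(norm, "CsparseMatrix"), "generalMatrix")
  e@x <- expm1(e@x)
  n <- ncol(e)
  mu <- Matrix::rowSums(e) / n
  ex2 <- Matrix::rowSums(e^2)
  v <- if (n > 1) (ex2 - n * mu^2) / (n - 1) else rep(0, nrow(e))
  v <- pmax(v, 0)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- if (diff(range(mu)) < 1e-8 * max(abs(mu), 1)) rep(1L, length(mu)) else
    as.integer(cut(mu, breaks = cfg$n_bins))
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (sum(i) < 2L || is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(norm))
  rownames(norm)[ord][seq_len(min(cfg$n_hvgs, nrow(norm)))]
}
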