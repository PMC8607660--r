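#' Per-cell quality-control profile
#'
#' Computes, for every cell, the number of detected genes (>= 1 UMI), the
#' total UMI count, and the mitochondrial UMI fraction.
#'
#' @param m A [umi_matrix()].
#' @return A data.frame with one row per cell: `barcode`, `n_genes`,
#'   `n_umi`, `mito_fraction`. Cells with zero UMI get `mito_fraction = 0`
#'   and `zero_umi = TRUE` in an extra flag column.
#' @export
qc_profile <- function(m) {
  stopifnot(inherits(m, "umi_matrix"))
  counts <- m$counts
  n_genes <- Matrix::rowSums(counts >= 1)
  n_umi <- Matrix::rowSums(counts)
  mito_umi <- if (length(m$mito_genes))
    Matrix::rowSums(counts[, m$mito_genes, drop = FALSE])
  else rep(0, nrow(counts))
  zero <- n_umi == 0
  mito_fraction <- ifelse(zero, 0, mito_umi / pmax(n_umi, 1))
  data.frame(barcode = rownames(counts), n_genes = as.integer(n_genes),
             n_umi = as.numeric(n_umi), mito_fraction = mito_fraction,
             zero_umi = zero, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Removes cells with too few or too many detected genes, too few or too
#' many UMIs, or an excessive mitochondrial fraction. All comparisons at
#' the thresholds are inclusive: the removal rules are strict inequalities
#' ("fewer than 200", "over 9000", "more than 5%"), so a cell sitting
#' exactly on a boundary is retained. The gene set is unchanged.
#'
#' @param m A [umi_matrix()].
#' @param profiles Output of [qc_profile()] for `m` (computed if `NULL`).
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param min_umi,max_umi Inclusive bounds on total UMI per cell.
#' @param max_mito Inclusive upper bound on the mitochondrial fraction.
#' @return A `umi_matrix` containing only the retained cells.
#' @export
filter_cells <- function(m, profiles = NULL, min_genes = 200,
                         max_genes = 9000, min_umi = 500, max_umi = 70000,
                         max_mito = 0.05) {
  stopifnot(inherits(m, "umi_matrix"))
  if (is.null(profiles)) profiles <- qc_profile(m)
  if (!identical(profiles$barcode, cell_ids(m)))
    stop("profiles do not match the cells of the matrix")
  keep <- profiles$n_genes >= min_genes & profiles$n_genes <= max_genes &
    profiles$n_umi >= min_umi & profiles$n_umi <= max_umi &
    profiles$mito_fraction <= max_mito
  if (!any(keep)) warning("no cells survive QC filtering")
  subset_umi(m, cells = which(keep))
}

#' Filter genes on minimum cell prevalence
#'
#' Retains genes detected (>= 1 UMI) in at least `min_cells` cells; the
#' cell set is unchanged. Applied after [filter_cells()] in the standard
#' workflow, so prevalence is re-evaluated on the surviving cells.
#' Idempotent: a second application removes nothing further.
#'
#' @param m A [umi_matrix()].
#' @param min_cells Minimum number of cells with >= 1 UMI (inclusive).
#' @return A `umi_matrix` containing only the retained genes.
#' @export
filter_genes <- function(m, min_cells = 3) {
  stopifnot(inherits(m, "umi_matrix"))
  n_cells <- Matrix::colSums(m$counts >= 1)
  subset_umi(m, genes = which(n_cells >= min_cells))
}

#' Log-normalize a UMI matrix
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' `value = ln(1 + scale * count / cell_total_umi)`. Zeros are preserved,
#' so sparsity is unchanged.
#'
#' @param m A [umi_matrix()] with no zero-total cells (run [filter_cells()]
#'   first).
#' @param scale Scale factor for the per-cell totals (default 10,000).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (sparse cell x gene `dgCMatrix` of normalized values) and `scale`.
#' @export
log_normalize <- function(m, scale = 10000) {
  stopifnot(inherits(m, "umi_matrix"))
  counts <- m$counts
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("cells with zero total UMI present; run filter_cells() first")
  tm <- as(counts, "TsparseMatrix")
  vals <- Matrix::sparseMatrix(
    i = tm@i + 1L, j = tm@j + 1L,
    x = log1p(scale * tm@x / totals[tm@i + 1L]),
    dims = dim(counts), dimnames = dimnames(counts))
  structure(list(values = vals, scale = scale), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Run the full QC stage and report counts
#'
#' Applies [filter_cells()] then [filter_genes()] and records cell/gene
#' counts before and after each step. Gene prevalence is evaluated both
#' before and after cell filtering, and both gene-survivor counts are
#' reported, since cell filtering changes prevalence.
#'
#' @param m A [umi_matrix()].
#' @param min_genes,max_genes,min_umi,max_umi,max_mito See [filter_cells()].
#' @param min_cells See [filter_genes()].
#' @return A list with `matrix` (the filtered `umi_matrix`), `profiles`
#'   (pre-filter [qc_profile()]), and `report` (a one-row data.frame of
#'   counts).
#' @export
run_qc <- function(m, min_genes = 200, max_genes = 9000, min_umi = 500,
                   max_umi = 70000, max_mito = 0.05, min_cells = 3) {
  profiles <- qc_profile(m)
  genes_pass_pre <- sum(Matrix::colSums(m$counts >= 1) >= min_cells)
  mc <- filter_cells(m, profiles, min_genes = min_genes,
                     max_genes = max_genes, min_umi = min_umi,
                     max_umi = max_umi, max_mito = max_mito)
  mg <- filter_genes(mc, min_cells = min_cells)
  report <- data.frame(
    cells_in = nrow(m$counts), cells_out = nrow(mg$counts),
    genes_in = ncol(m$counts),
    genes_pass_before_cell_filter = genes_pass_pre,
    genes_out = ncol(mg$counts))
  list(matrix = mg, profiles = profiles, report = report)
}
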