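#' Construct a UMI count matrix container
#'
#' Wraps a sparse cell-by-gene matrix of deduplicated transcript (UMI)
#' counts together with the set of genes designated as mitochondrial.
#' Cells are rows and genes are columns throughout the package, regardless
#' of on-disk orientation.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   cells in rows, genes in columns, with unique row (barcode) and column
#'   (gene id) names.
#' @param mito_genes Character vector of gene ids designated mitochondrial;
#'   must be a subset of `colnames(counts)`.
#' @return An object of class `umi_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `mito_genes`.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 1),
#'                           dims = c(2, 2))
#' dimnames(m) <- list(c("BC1", "BC2"), c("G1", "MT-G1"))
#' umi_matrix(m, mito_genes = "MT-G1")
#' @export
umi_matrix <- function(counts, mito_genes = character()) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have barcode rownames and gene id colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell barcodes in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene ids in counts")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  mito_genes <- as.character(mito_genes)
  if (!all(mito_genes %in% colnames(counts)))
    stop("mito_genes must be a subset of the gene ids")
  structure(list(counts = counts, mito_genes = mito_genes),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d cells x %d genes, %d nonzero, %d mito genes\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              length(x$mito_genes)))
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

cell_ids <- function(m) rownames(m$counts)
gene_ids <- function(m) colnames(m$counts)

#' Subset a UMI matrix by cells and/or genes
#'
#' @param m A [umi_matrix()].
#' @param cells,genes Character vectors of ids (or logical/integer indices)
#'   to retain; `NULL` keeps all.
#' @return A `umi_matrix` restricted to the requested cells and genes; the
#'   mitochondrial set is intersected with the retained genes.
#' @export
subset_umi <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  counts <- m$counts
  if (!is.null(cells)) counts <- counts[cells, , drop = FALSE]
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  umi_matrix(counts, intersect(m$mito_genes, colnames(counts)))
}

#' Validate and attach a cluster assignment
#'
#' Cluster labels are an external input (graph clustering upstream, or the
#' synthetic generator); this helper checks them against a matrix.
#'
#' @param m A [umi_matrix()].
#' @param clusters Named character/factor vector mapping barcodes to cluster
#'   labels; every cell of `m` must be present.
#' @return A factor of cluster labels ordered as the cells of `m`.
#' @export
align_clusters <- function(m, clusters) {
  stopifnot(inherits(m, "umi_matrix"))
  if (is.null(names(clusters)))
    stop("clusters must be named by cell barcode")
  missing <- setdiff(cell_ids(m), names(clusters))
  if (length(missing))
    stop(sprintf("%d cells have no cluster label (e.g. %s)",
                 length(missing), missing[1]))
  cl <- factor(as.character(clusters[cell_ids(m)]))
  if (any(table(cl) == 0)) cl <- droplevels(cl)
  cl
}
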