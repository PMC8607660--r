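#' Read a 10x-style MatrixMarket bundle
#'
#' Reads a MatrixMarket coordinate file plus its barcode and feature TSVs
#' into a [umi_matrix()]. The 10x convention stores genes (features) in rows
#' and cells in columns; the matrix is transposed on read so that the
#' in-memory orientation is always cell x gene.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param barcodes_path Path to the barcodes TSV (one barcode per line).
#' @param features_path Path to the features TSV (id, then optional name).
#' @param mito_genes Explicit character vector of mitochondrial gene ids,
#'   or `NULL`.
#' @param mito_prefix A gene-id prefix (e.g. `"MT-"`) marking mitochondrial
#'   genes; used when `mito_genes` is `NULL`. `NULL` designates none.
#' @return A [umi_matrix()] with cells in rows and genes in columns.
#' @export
read_mtx_bundle <- function(matrix_path, barcodes_path, features_path,
                            mito_genes = NULL, mito_prefix = NULL) {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  feats <- read.delim(features_path, header = FALSE,
                      colClasses = "character")
  features <- feats[[1]]
  if (anyDuplicated(features))
    stop(sprintf("%s: duplicated gene id '%s'", features_path,
                 features[duplicated(features)][1]))
  if (anyDuplicated(barcodes))
    stop(sprintf("%s: duplicated barcode '%s'", barcodes_path,
                 barcodes[duplicated(barcodes)][1]))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop(sprintf(
      "%s: dimensions %d x %d do not match %d features x %d barcodes",
      matrix_path, nrow(m), ncol(m), length(features), length(barcodes)))
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(m@x) && any(m@x != round(m@x)))
    stop(sprintf("%s: non-integer count value %s (counts must be integral)",
                 matrix_path, format(m@x[m@x != round(m@x)][1])))
  if (length(m@x) && any(m@x < 0))
    stop(sprintf("%s: negative count value", matrix_path))
  dimnames(m) <- list(features, barcodes)
  counts <- Matrix::t(m)
  if (is.null(mito_genes) && !is.null(mito_prefix))
    mito_genes <- features[startsWith(features, mito_prefix)]
  if (is.null(mito_genes)) mito_genes <- character()
  umi_matrix(counts, mito_genes = intersect(mito_genes, features))
}

#' Write a UMI matrix as a 10x-style MatrixMarket bundle
#'
#' Writes the gene x cell (10x on-disk orientation) MatrixMarket coordinate
#' file and the barcode/feature TSVs. Round-trips bit-exactly through
#' [read_mtx_bundle()].
#'
#' @param m A [umi_matrix()].
#' @param matrix_path,barcodes_path,features_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_mtx_bundle <- function(m, matrix_path, barcodes_path, features_path) {
  stopifnot(inherits(m, "umi_matrix"))
  Matrix::writeMM(Matrix::t(m$counts), matrix_path)
  writeLines(cell_ids(m), barcodes_path)
  write.table(data.frame(id = gene_ids(m), name = gene_ids(m)),
              features_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(matrix = matrix_path, barcodes = barcodes_path,
              features = features_path))
}

#' Read a cluster-label TSV
#'
#' @param path Two-column TSV: barcode TAB cluster label, no header.
#' @return Named character vector mapping barcodes to labels.
#' @export
read_cluster_labels <- function(path) {
  d <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(d) < 2) stop(sprintf("%s: expected barcode TAB label", path))
  if (anyDuplicated(d[[1]]))
    stop(sprintf("%s: duplicated barcode '%s'", path,
                 d[[1]][duplicated(d[[1]])][1]))
  setNames(d[[2]], d[[1]])
}

#' Write a cluster-label TSV
#' @param clusters Named vector (barcode -> label).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_labels <- function(clusters, path) {
  write.table(data.frame(barcode = names(clusters),
                         cluster = as.character(clusters)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-pair TSV
#'
#' Pair lists (e.g. WGD-derived paralogs identified by synteny upstream)
#' are inputs to this package. The TSV has a header and columns
#' `gene_a`, `gene_b`, and optionally `dn`, `ds`, `dnds_ratio`.
#'
#' @param path Path to the pair TSV.
#' @param origin Origin tag recorded on the pairs (`"wgd"` or `"random"`).
#' @return A data.frame with columns `gene_a`, `gene_b`, `origin` and any
#'   optional divergence columns present.
#' @export
read_gene_pairs <- function(path, origin = "wgd") {
  d <- read.delim(path, header = TRUE, colClasses = NA)
  if (!all(c("gene_a", "gene_b") %in% names(d)))
    stop(sprintf("%s: expected header columns gene_a, gene_b", path))
  d$gene_a <- as.character(d$gene_a)
  d$gene_b <- as.character(d$gene_b)
  if (any(d$gene_a == d$gene_b))
    stop(sprintf("%s: self-pair '%s'", path, d$gene_a[d$gene_a == d$gene_b][1]))
  d$origin <- origin
  keep <- intersect(c("gene_a", "gene_b", "origin", "dn", "ds", "dnds_ratio"),
                    names(d))
  d[, keep, drop = FALSE]
}

#' Write a gene-pair TSV
#' @param pairs Data.frame with at least `gene_a`, `gene_b`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_pairs <- function(pairs, path) {
  cols <- intersect(c("gene_a", "gene_b", "dn", "ds", "dnds_ratio"),
                    names(pairs))
  write.table(pairs[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-to-term annotation TSV
#'
#' @param path Two-column TSV (gene TAB term), no header. A gene may appear
#'   on multiple lines, one per term.
#' @param labels_path Optional two-column TSV (term TAB label), no header.
#' @return A list with `gene2terms` (named list of character vectors) and
#'   `term_labels` (named character vector, possibly empty).
#' @export
read_annotation <- function(path, labels_path = NULL) {
  d <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(d) < 2) stop(sprintf("%s: expected gene TAB term", path))
  gene2terms <- lapply(split(d[[2]], d[[1]]), unique)
  term_labels <- character()
  if (!is.null(labels_path)) {
    lab <- read.delim(labels_path, header = FALSE, colClasses = "character")
    term_labels <- setNames(lab[[2]], lab[[1]])
  }
  list(gene2terms = gene2terms, term_labels = term_labels)
}

#' Write a gene-to-term annotation TSV
#' @param gene2terms Named list: gene id -> character vector of terms.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(gene2terms, path) {
  genes <- rep(names(gene2terms), lengths(gene2terms))
  terms <- unlist(gene2terms, use.names = FALSE)
  write.table(data.frame(gene = genes, term = terms), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
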