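#' Binarize expression at a UMI threshold
#'
#' Cells with at least `min_umi` UMIs of a gene are coded 1, all other
#' cells 0. Per-gene prevalence (fraction of cells positive) is computed
#' on the same matrix.
#'
#' @param m A [umi_matrix()] (QC-filtered).
#' @param min_umi Minimum UMI count for presence (default 1).
#' @return An object of class `binarized_matrix`: list with `presence`
#'   (sparse cell x gene 0/1 matrix), `prevalence` (named fraction per
#'   gene), and `n_cells`.
#' @export
binarize <- function(m, min_umi = 1) {
  stopifnot(inherits(m, "umi_matrix"))
  presence <- as(as(m$counts >= min_umi, "dMatrix"), "CsparseMatrix")
  prev <- Matrix::colSums(presence) / nrow(presence)
  structure(list(presence = presence,
                 prevalence = setNames(as.numeric(prev), gene_ids(m)),
                 n_cells = nrow(presence)),
            class = "binarized_matrix")
}

#' @export
print.binarized_matrix <- function(x, ...) {
  cat(sprintf("binarized_matrix: %d cells x %d genes\n", x$n_cells,
              ncol(x$presence)))
  invisible(x)
}

#' Genes passing a minimum prevalence
#'
#' Retains genes expressed (presence = 1) in at least `min_frac` of the
#' cells; the boundary is inclusive.
#'
#' @param bin A [binarize()] result.
#' @param min_frac Minimum fraction of cells (default 0.01).
#' @return Character vector of retained gene ids.
#' @export
prevalence_filter <- function(bin, min_frac = 0.01) {
  stopifnot(inherits(bin, "binarized_matrix"))
  keep <- names(bin$prevalence)[bin$prevalence >= min_frac]
  if (!length(keep)) warning("no genes pass the prevalence filter")
  keep
}

#' Jaccard co-expression index for gene pairs
#'
#' For each pair, the Jaccard index of the two positive-cell sets:
#' `n_both / n_either`. Pairs with a member failing the prevalence filter
#' are dropped (with a message); pairs naming unknown genes are an error.
#'
#' @param bin A [binarize()] result.
#' @param pairs Data.frame with columns `gene_a`, `gene_b` (see
#'   [read_gene_pairs()]); extra columns are carried through.
#' @param min_frac Prevalence filter applied to pair members (default 0.01).
#' @return A data.frame: the surviving pairs with `n_both`, `n_either`,
#'   `jaccard` columns appended. Attribute `n_dropped` records how many
#'   pairs were removed by the prevalence filter.
#' @export
jaccard_pairs <- function(bin, pairs, min_frac = 0.01) {
  stopifnot(inherits(bin, "binarized_matrix"))
  genes <- colnames(bin$presence)
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes)
  if (length(unknown))
    stop(sprintf("pair references unknown gene id '%s'", unknown[1]))
  retained <- prevalence_filter(bin, min_frac)
  ok <- pairs$gene_a %in% retained & pairs$gene_b %in% retained
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(sprintf("dropping %d pair(s) with a member below %.3g prevalence",
                    n_dropped, min_frac))
  pairs <- pairs[ok, , drop = FALSE]
  pos_count <- bin$prevalence * bin$n_cells
  p <- bin$presence
  n_both <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(p[, pairs$gene_a[i]] * p[, pairs$gene_b[i]])
  }, numeric(1))
  n_either <- pos_count[pairs$gene_a] + pos_count[pairs$gene_b] - n_both
  pairs$n_both <- as.integer(round(n_both))
  pairs$n_either <- as.integer(round(unname(n_either)))
  pairs$jaccard <- ifelse(pairs$n_either > 0, n_both / n_either, NA_real_)
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped") <- n_dropped
  pairs
}

#' One-vs-all Jaccard profile of a gene
#'
#' Jaccard index between one gene and every other prevalence-passing gene,
#' plus a histogram summary of the distribution.
#'
#' @param bin A [binarize()] result.
#' @param gene Gene id (must pass the prevalence filter).
#' @param min_frac Prevalence filter (default 0.01).
#' @param breaks Histogram breaks over \[0, 1\] (default 20 equal bins).
#' @return A list with `values` (named vector of Jaccard indices against
#'   every other retained gene) and `histogram` (data.frame `bin_lo`,
#'   `bin_hi`, `count`).
#' @export
jaccard_profile <- function(bin, gene, min_frac = 0.01,
                            breaks = seq(0, 1, length.out = 21)) {
  stopifnot(inherits(bin, "binarized_matrix"))
  if (!gene %in% colnames(bin$presence))
    stop(sprintf("unknown gene '%s'", gene))
  retained <- prevalence_filter(bin, min_frac)
  if (!gene %in% retained)
    stop(sprintf("gene '%s' does not pass the prevalence filter", gene))
  others <- setdiff(retained, gene)
  p <- bin$presence
  v <- p[, gene]
  n_g <- sum(v)
  n_both <- as.numeric(Matrix::crossprod(p[, others, drop = FALSE], v))
  n_pos <- bin$prevalence[others] * bin$n_cells
  n_either <- n_pos + n_g - n_both
  vals <- setNames(ifelse(n_either > 0, n_both / n_either, NA_real_), others)
  bins <- cut(vals[!is.na(vals)], breaks = breaks, include.lowest = TRUE,
              right = TRUE)
  list(values = vals,
       histogram = data.frame(bin_lo = head(breaks, -1),
                              bin_hi = breaks[-1],
                              count = as.integer(table(bins))))
}

#' Pearson co-expression network
#'
#' Pearson correlation of log-normalized expression over all retained
#' cells, reported as an edge list of gene pairs with `|r| >= threshold`.
#' Zero-variance genes are excluded (their correlation is undefined) and
#' counted.
#'
#' @param norm A [log_normalize()] result.
#' @param genes Gene ids to correlate.
#' @param threshold Minimum absolute correlation for an edge.
#' @return A data.frame of edges `gene_a`, `gene_b`, `r` (upper triangle
#'   only, no self-edges), with attribute `n_zero_variance`.
#' @export
pearson_network <- function(norm, genes, threshold = 0.5) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (nrow(norm$values) < 3) stop("at least 3 cells are required")
  unknown <- setdiff(genes, colnames(norm$values))
  if (length(unknown)) stop(sprintf("unknown gene '%s'", unknown[1]))
  x <- as.matrix(norm$values[, genes, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  zero_var <- sum(sds == 0)
  if (zero_var)
    message(sprintf("omitting %d zero-variance gene(s)", zero_var))
  x <- x[, sds > 0, drop = FALSE]
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (ncol(x) >= 2) {
    cm <- cor(x)
    idx <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
    if (nrow(idx))
      edges <- data.frame(gene_a = colnames(x)[idx[, 1]],
                          gene_b = colnames(x)[idx[, 2]],
                          r = cm[idx], stringsAsFactors = FALSE)
  }
  attr(edges, "n_zero_variance") <- zero_var
  edges
}
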