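#' Per-cluster expression percentages
#'
#' For every gene and cluster, the fraction of the cluster's cells with at
#' least one UMI.
#'
#' @param m A [umi_matrix()] (post-QC).
#' @param clusters Named vector mapping barcodes to cluster labels (see
#'   [align_clusters()]).
#' @return A genes x clusters numeric matrix of fractions in \[0, 1\], with
#'   attribute `cluster_sizes` (named integer vector).
#' @export
expression_pct <- function(m, clusters) {
  stopifnot(inherits(m, "umi_matrix"))
  cl <- align_clusters(m, clusters)
  sizes <- table(cl)
  if (any(sizes == 0)) stop("cluster with zero cells")
  presence <- m$counts >= 1
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(cl),
                              x = 1, dims = c(length(cl), nlevels(cl)))
  counts <- as.matrix(Matrix::crossprod(presence, ind))
  pct <- sweep(counts, 2, as.numeric(sizes), "/")
  dimnames(pct) <- list(gene_ids(m), levels(cl))
  attr(pct, "cluster_sizes") <- setNames(as.integer(sizes), levels(cl))
  pct
}

# mean of expm1 over a set of rows, per gene, on a sparse value matrix
.expm1_means <- function(vals, rows) {
  sub <- vals[rows, , drop = FALSE]
  e <- sub
  e@x <- expm1(e@x)
  as.numeric(Matrix::colSums(e)) / length(rows)
}

#' Natural-log fold change between a cluster and the rest
#'
#' Uses the convention of the standard single-cell toolkits:
#' `log_fc = ln(mean(expm1(x_in)) + 1) - ln(mean(expm1(x_out)) + 1)` with
#' `x` the log-normalized values, so a threshold of 0.58 corresponds to a
#' fold change of about 1.79 on the de-logged scale.
#'
#' @param norm A [log_normalize()] result.
#' @param clusters Named vector of cluster labels.
#' @param gene Gene id.
#' @param cluster Cluster label (the "in" group; the rest is the "out").
#' @return The natural-log fold change (scalar).
#' @export
cluster_log_fc <- function(norm, clusters, gene, cluster) {
  stopifnot(inherits(norm, "normalized_matrix"))
  vals <- norm$values
  if (!gene %in% colnames(vals)) stop(sprintf("unknown gene '%s'", gene))
  cl <- as.character(clusters[rownames(vals)])
  in_rows <- which(cl == cluster)
  out_rows <- which(cl != cluster)
  if (!length(in_rows) || !length(out_rows))
    stop("cluster and its complement must both be non-empty")
  x <- vals[, gene]
  log(mean(expm1(x[in_rows])) + 1) - log(mean(expm1(x[out_rows])) + 1)
}

#' Call cluster-enriched genes (one-vs-rest)
#'
#' For each cluster, genes are screened by expression prevalence
#' (`max(pct_in, pct_rest) >= min_pct`) and natural-log fold change
#' (`log_fc >= logfc_threshold`), then tested with a two-sided Wilcoxon
#' rank-sum test on the log-normalized values ([ranksum_test()]; exact for
#' small groups, normal approximation with tie correction otherwise).
#' p-values are Benjamini-Hochberg adjusted across all tests performed.
#'
#' @param norm A [log_normalize()] result.
#' @param clusters Named vector of cluster labels covering all cells.
#' @param min_pct Prevalence screen (default 0.25).
#' @param logfc_threshold Natural-log fold-change screen (default 0.58).
#' @param alpha Adjusted-p cutoff for the `is_enriched` flag (default 0.05).
#' @return A data.frame of tested (gene, cluster) records: `gene`,
#'   `cluster`, `pct_in`, `pct_rest`, `max_pct_out`, `log_fc`, `p_value`,
#'   `p_adjusted`, `is_enriched`, with attribute `pct_table` (the full
#'   [expression_pct()] matrix, computed from the same cells).
#' @export
call_enriched <- function(norm, clusters, min_pct = 0.25,
                          logfc_threshold = 0.58, alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  vals <- norm$values
  cl <- align_clusters(
    structure(list(counts = vals, mito_genes = character()),
              class = "umi_matrix"), clusters)
  if (nlevels(cl) < 2)
    stop("at least two clusters are required (no 'rest' group otherwise)")
  presence <- vals > 0
  n_cells <- nrow(vals)
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells), j = as.integer(cl),
                              x = 1, dims = c(n_cells, nlevels(cl)))
  pos_counts <- as.matrix(Matrix::crossprod(presence, ind))
  sizes <- as.numeric(table(cl))
  pct_table <- sweep(pos_counts, 2, sizes, "/")
  dimnames(pct_table) <- list(colnames(vals), levels(cl))
  attr(pct_table, "cluster_sizes") <- setNames(as.integer(sizes), levels(cl))

  records <- vector("list", nlevels(cl))
  for (k in seq_len(nlevels(cl))) {
    in_rows <- which(as.integer(cl) == k)
    out_rows <- which(as.integer(cl) != k)
    pct_in <- pct_table[, k]
    pct_rest <- (rowSums(pos_counts) - pos_counts[, k]) / length(out_rows)
    mean_in <- .expm1_means(vals, in_rows)
    mean_out <- .expm1_means(vals, out_rows)
    log_fc <- log(mean_in + 1) - log(mean_out + 1)
    test <- which(pmax(pct_in, pct_rest) >= min_pct &
                    log_fc >= logfc_threshold)
    if (!length(test)) next
    pvals <- vapply(test, function(g) {
      col <- as.numeric(vals[, g])
      ranksum_test(col[in_rows], col[out_rows])$p_value
    }, numeric(1))
    max_out <- if (nlevels(cl) > 2)
      apply(pct_table[test, -k, drop = FALSE], 1, max)
    else pct_table[test, -k]
    records[[k]] <- data.frame(
      gene = colnames(vals)[test], cluster = levels(cl)[k],
      pct_in = unname(pct_in[test]), pct_rest = unname(pct_rest[test]),
      max_pct_out = unname(max_out), log_fc = unname(log_fc[test]),
      p_value = pvals, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(gene = character(), cluster = character(),
                      pct_in = numeric(), pct_rest = numeric(),
                      max_pct_out = numeric(), log_fc = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$p_adjusted <- if (nrow(out)) p.adjust(out$p_value, "BH") else numeric()
  out$is_enriched <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "pct_table") <- pct_table
  out
}

#' Flag cluster-specific markers among enriched genes
#'
#' A cluster-specific marker is an enriched gene expressed in at least
#' `in_threshold` of the cells of its cluster ("at least": inclusive) and
#' in less than `out_threshold` of the cells of every other cluster
#' ("less than": strict).
#'
#' @param records Output of [call_enriched()].
#' @param pct_table A genes x clusters percentage matrix from
#'   [expression_pct()]; defaults to the one attached to `records`.
#' @param in_threshold,out_threshold Fractions (defaults 0.25).
#' @return `records` with an added logical `is_specific` column.
#' @export
call_specific <- function(records, pct_table = attr(records, "pct_table"),
                          in_threshold = 0.25, out_threshold = 0.25) {
  if (is.null(pct_table)) stop("pct_table is required")
  if (!nrow(records)) {
    records$is_specific <- logical()
    return(records)
  }
  others_ok <- vapply(seq_len(nrow(records)), function(i) {
    g <- records$gene[i]; c <- records$cluster[i]
    all(pct_table[g, setdiff(colnames(pct_table), c)] < out_threshold)
  }, logical(1))
  records$is_specific <- records$is_enriched &
    records$pct_in >= in_threshold & others_ok
  records
}
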