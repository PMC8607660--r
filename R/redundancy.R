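#' Sample random background gene pairs
#'
#' Samples `n` distinct unordered pairs uniformly from the supplied genes,
#' excluding any pair in the focal (e.g. WGD) set. With `n` equal to the
#' number of analyzed focal pairs this yields one background pair per
#' focal pair, enabling an index-matched signed-rank comparison.
#'
#' @param retained_genes Character vector of (prevalence-passing) gene ids.
#' @param wgd_pairs Data.frame with `gene_a`, `gene_b` to exclude.
#' @param n Number of background pairs to draw.
#' @param seed Integer seed; sampling is reproducible.
#' @return A data.frame `gene_a`, `gene_b`, `origin = "random"`.
#' @export
sample_background_pairs <- function(retained_genes, wgd_pairs, n, seed) {
  g <- unique(retained_genes)
  if (length(g) < 2) stop("need at least 2 retained genes")
  if (n < 1) stop("n must be >= 1")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  excluded <- unique(key(wgd_pairs$gene_a, wgd_pairs$gene_b))
  n_avail <- choose(length(g), 2) - length(excluded)
  if (n > n_avail)
    stop(sprintf("requested %d pairs but only %.0f distinct pairs available",
                 n, n_avail))
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  chosen <- character(0)
  out_a <- character(0); out_b <- character(0)
  while (length(out_a) < n) {
    need <- n - length(out_a)
    a <- sample(g, 2 * need + 10, replace = TRUE)
    b <- sample(g, 2 * need + 10, replace = TRUE)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    k <- key(a, b)
    ok <- !k %in% excluded & !k %in% chosen & !duplicated(k)
    a <- a[ok]; b <- b[ok]; k <- k[ok]
    take <- seq_len(min(need, length(a)))
    out_a <- c(out_a, pmin(a, b)[take])
    out_b <- c(out_b, pmax(a, b)[take])
    chosen <- c(chosen, k[take])
  }
  data.frame(gene_a = out_a, gene_b = out_b, origin = "random",
             stringsAsFactors = FALSE)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old_seed, envir = .GlobalEnv)
}

#' Compare focal-pair co-expression to a background
#'
#' Paired mode (default): two-sided Wilcoxon signed-rank test on the
#' index-matched differences `wgd - background` ([signed_rank_test()];
#' exact for small n, normal approximation with tie and continuity
#' correction otherwise). The unpaired Mann-Whitney U p-value is reported
#' alongside, since a two-sample framing is also defensible.
#'
#' @param wgd_scores Numeric vector of focal (e.g. WGD-pair) Jaccard
#'   indices.
#' @param background_scores Numeric vector of background Jaccard indices;
#'   in paired mode, same length and index-matched.
#' @param paired Use the signed-rank test on differences (default TRUE).
#' @return A one-row data.frame: `n_pairs`, `median_wgd_jaccard`,
#'   `median_background_jaccard`, `statistic`, `p_value`, `test_name`,
#'   and `mann_whitney_p` (the unpaired check).
#' @export
compare_to_background <- function(wgd_scores, background_scores,
                                  paired = TRUE) {
  if (paired && length(wgd_scores) != length(background_scores))
    stop("paired comparison requires equal-length, index-matched vectors")
  mw <- suppressWarnings(
    wilcox.test(wgd_scores, background_scores, exact = FALSE))
  if (paired) {
    sr <- signed_rank_test(wgd_scores - background_scores)
    stat <- sr$statistic; p <- sr$p_value; name <- "wilcoxon_signed_rank"
  } else {
    stat <- unname(mw$statistic); p <- mw$p.value; name <- "mann_whitney_u"
  }
  data.frame(n_pairs = length(wgd_scores),
             median_wgd_jaccard = median(wgd_scores),
             median_background_jaccard = median(background_scores),
             statistic = stat, p_value = p, test_name = name,
             mann_whitney_p = mw$p.value)
}

#' Per-pair overlapping clusters
#'
#' A cluster is overlapping for a gene pair when both copies are expressed
#' in more than `threshold` of its cells (strict inequality: a copy at
#' exactly the threshold does not overlap).
#'
#' @param pairs Data.frame with `gene_a`, `gene_b`.
#' @param pct_table Genes x clusters matrix from [expression_pct()].
#' @param threshold Fraction (default 0.25).
#' @return `pairs` with `overlap_clusters` (comma-separated labels) and
#'   `overlap_count` columns appended.
#' @export
overlap_clusters <- function(pairs, pct_table, threshold = 0.25) {
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                     rownames(pct_table))
  if (length(unknown))
    stop(sprintf("gene '%s' missing from pct_table", unknown[1]))
  ov <- (pct_table[pairs$gene_a, , drop = FALSE] > threshold) &
    (pct_table[pairs$gene_b, , drop = FALSE] > threshold)
  pairs$overlap_clusters <- apply(ov, 1, function(r)
    paste(colnames(pct_table)[r], collapse = ","))
  pairs$overlap_count <- as.integer(rowSums(ov))
  rownames(pairs) <- NULL
  pairs
}

#' Classify redundancy candidates
#'
#' A pair is a redundancy candidate when its Jaccard index falls in the
#' top `top_fraction` of the analyzed pair set (ties at the quantile are
#' included) while overlapping in only `min_overlap` to `max_overlap`
#' clusters: strong overall co-expression restricted to one or two cell
#' types suggests redundant function there.
#'
#' @param scores Data.frame with `jaccard` and `overlap_count` columns
#'   (see [jaccard_pairs()] and [overlap_clusters()]).
#' @param top_fraction Fraction of the Jaccard distribution taken as "top"
#'   (default 0.10).
#' @param min_overlap,max_overlap Allowed overlapping-cluster counts
#'   (defaults 1 and 2).
#' @return `scores` with `decile_rank` (percentile of the pair's Jaccard
#'   within the analyzed set, in \[0, 100\]) and logical `is_candidate`
#'   columns appended.
#' @export
call_candidates <- function(scores, top_fraction = 0.10, min_overlap = 1,
                            max_overlap = 2) {
  stopifnot(all(c("jaccard", "overlap_count") %in% names(scores)))
  j <- scores$jaccard
  cutoff <- quantile(j, probs = 1 - top_fraction, na.rm = TRUE,
                     names = FALSE)
  n <- sum(!is.na(j))
  scores$decile_rank <- 100 * (rank(j, na.last = "keep") - 1) / max(n - 1, 1)
  scores$is_candidate <- !is.na(j) & j >= cutoff &
    scores$overlap_count >= min_overlap &
    scores$overlap_count <= max_overlap
  scores
}

#' Jaccard vs dN/dS trend
#'
#' Bins pairs into quantile bins of dN/dS, reports the per-bin median
#' Jaccard, and computes the Spearman rank correlation between Jaccard and
#' dN/dS across pairs. Pairs with an undefined ratio (e.g. dS = 0) are
#' excluded and counted.
#'
#' @param scores Data.frame with `jaccard` and `dnds_ratio` columns.
#' @param n_bins Number of quantile bins (default 5).
#' @return A list with `bins` (data.frame `bin`, `ratio_lo`, `ratio_hi`,
#'   `n`, `median_jaccard`), `spearman_rho`, `spearman_p`, `n_pairs`,
#'   `n_excluded`. `spearman_rho` is `NA` when all ratios are identical.
#' @export
jaccard_dnds_trend <- function(scores, n_bins = 5) {
  stopifnot(all(c("jaccard", "dnds_ratio") %in% names(scores)))
  ok <- is.finite(scores$dnds_ratio) & is.finite(scores$jaccard)
  n_excluded <- sum(!ok)
  d <- scores[ok, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 pairs with finite dN/dS")
  if (length(unique(d$dnds_ratio)) == 1) {
    rho <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(d$jaccard, d$dnds_ratio, method = "spearman"))
    rho <- unname(ct$estimate); pv <- ct$p.value
  }
  qs <- unique(quantile(d$dnds_ratio, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(qs) < 2) qs <- c(qs, qs + 1e-9)   # all ratios identical
  bin <- cut(d$dnds_ratio, breaks = qs, include.lowest = TRUE)
  bins <- data.frame(
    bin = seq_along(levels(bin)),
    ratio_lo = head(qs, -1)[seq_along(levels(bin))],
    ratio_hi = qs[-1][seq_along(levels(bin))],
    n = as.integer(table(bin)),
    median_jaccard = as.numeric(tapply(d$jaccard, bin, median)))
  list(bins = bins, spearman_rho = rho, spearman_p = pv,
       n_pairs = nrow(d), n_excluded = n_excluded)
}
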