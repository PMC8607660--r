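#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up adjustment (delegates to [stats::p.adjust()]) with
#' input validation: p-values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1], any order.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' One-sided Fisher term enrichment
#'
#' Tests each annotation term for over-representation in a study gene set
#' against a background, with a one-sided Fisher's exact test on the 2x2
#' table (study-with-term, study-without; background-only-with-term,
#' background-only-without). Both sets are first restricted to annotated
#' genes (drops are counted). BH adjustment is computed across the terms
#' with at least one study gene (`k >= 1`); terms with `k = 0` have
#' `p_value = 1` and `p_adjusted = NA`.
#'
#' @param study_genes Character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector defining the universe (e.g.
#'   all genes, or the expressed genes of one tissue).
#' @param annotation A [read_annotation()] result, or a named list
#'   gene -> character vector of terms.
#' @param two_sided Use the two-sided Fisher test instead (default FALSE).
#' @return A data.frame sorted by p-value: `term`, `label`, `k`, `n`,
#'   `K`, `M`, `p_value`, `p_adjusted`, with attributes
#'   `n_study_unannotated` and `n_background_unannotated`.
#' @export
fisher_enrichment <- function(study_genes, background_genes, annotation,
                              two_sided = FALSE) {
  if (is.list(annotation) && !is.null(annotation$gene2terms)) {
    gene2terms <- annotation$gene2terms
    labels <- annotation$term_labels
  } else {
    gene2terms <- annotation
    labels <- character()
  }
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!all(study_genes %in% background_genes))
    stop("study genes must be a subset of the background")
  annotated <- names(gene2terms)
  n_study_drop <- sum(!study_genes %in% annotated)
  n_bg_drop <- sum(!background_genes %in% annotated)
  study <- intersect(study_genes, annotated)
  bg <- intersect(background_genes, annotated)
  if (!length(study))
    stop("no annotated study genes remain after restriction")
  n <- length(study); M <- length(bg)
  bg_terms <- gene2terms[bg]
  term_K <- table(unlist(bg_terms, use.names = FALSE))
  term_k <- table(unlist(gene2terms[study], use.names = FALSE))
  terms <- names(term_K)
  k <- as.integer(term_k[terms]); k[is.na(k)] <- 0L
  K <- as.integer(term_K[terms])
  alt <- if (two_sided) "two.sided" else "greater"
  p <- vapply(seq_along(terms), function(i) {
    tab <- matrix(c(k[i], n - k[i], K[i] - k[i], M - n - K[i] + k[i]),
                  nrow = 2)
    fisher.test(tab, alternative = alt)$p.value
  }, numeric(1))
  p_adj <- rep(NA_real_, length(terms))
  tested <- k >= 1
  if (any(tested)) p_adj[tested] <- bh_adjust(p[tested])
  out <- data.frame(
    term = terms,
    label = ifelse(terms %in% names(labels), labels[terms], terms),
    k = k, n = n, K = K, M = M, p_value = p, p_adjusted = p_adj,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_study_unannotated") <- n_study_drop
  attr(out, "n_background_unannotated") <- n_bg_drop
  out
}
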