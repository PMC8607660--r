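# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive everything by direct
# enumeration rather than calling package internals.

# --- dense fixture builder -------------------------------------------------

# dense cells x genes matrix -> umi_matrix, generating ids when absent
make_umi <- function(mat, mito = character()) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("BC%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("G%03d", seq_len(ncol(mat)))
  umi_matrix(Matrix::Matrix(mat, sparse = TRUE), mito_genes = mito)
}

# --- rank-test oracles -----------------------------------------------------

# exact two-sided rank-sum p by complete enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_lo <- mean(w_all <= w_obs + eps)
  p_hi <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  eps <- 1e-9
  p_lo <- mean(v_all <= v_obs + eps)
  p_hi <- mean(v_all >= v_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# --- enrichment oracle -----------------------------------------------------

# one-sided over-representation p as an explicit hypergeometric tail sum
oracle_fisher_greater <- function(k, n, K, M) {
  i <- k:min(n, K)
  sum(stats::dhyper(i, K, M - K, n))
}

# --- NG86 oracles ----------------------------------------------------------

oracle_code <- Biostrings::GENETIC_CODE
oracle_bases <- c("A", "C", "G", "T")
oracle_stops <- names(oracle_code)[oracle_code == "*"]
oracle_sense <- setdiff(names(oracle_code), oracle_stops)

# synonymous site count of one codon by explicit neighbor enumeration
oracle_syn_sites <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in setdiff(oracle_bases, cs[pos])) {
      alt <- cs; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (!(alt %in% oracle_stops) &&
          oracle_code[[alt]] == oracle_code[[codon]])
        syn <- syn + 1
    }
    s <- s + syn / 3
  }
  s
}

# (Nd, Sd) of a codon pair by recursive pathway enumeration, excluding
# stop-passing pathways unless every pathway passes through a stop
oracle_codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(list(nd = 0, sd = 0, stopped = FALSE)))
    out <- list()
    for (p in pos) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      syn <- !(oracle_code[[cur]] == "*" || oracle_code[[nxt]] == "*") &&
        oracle_code[[cur]] == oracle_code[[nxt]]
      hit_stop <- oracle_code[[nxt]] == "*" && nxt != target
      for (tail in walk(nxt, target))
        out[[length(out) + 1]] <- list(
          nd = tail$nd + !syn, sd = tail$sd + syn,
          stopped = tail$stopped || hit_stop)
    }
    out
  }
  paths <- walk(c1, c2)
  ok <- !vapply(paths, `[[`, logical(1), "stopped")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  nd <- vapply(paths, `[[`, numeric(1), "nd")[ok]
  sd_ <- vapply(paths, `[[`, numeric(1), "sd")[ok]
  c(mean(nd), mean(sd_))
}

# random stop-free codon sequence (helper for oracle comparisons)
random_codon_seq <- function(n_codons) {
  paste(sample(oracle_sense, n_codons, replace = TRUE), collapse = "")
}
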