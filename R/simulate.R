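#' Configuration for the synthetic atlas generator
#'
#' Builds and validates the parameter set for [simulate_atlas()]. Defaults
#' describe a desk-scale vascular-tissue-like atlas: 8 clusters of 188
#' cells (1504 cells), 2000 genes, negative-binomial counts with a shared
#' dispersion, log-normal library-size variation, 20 planted markers per
#' cluster at 8-fold up-regulation, and 100 planted WGD pairs whose second
#' copy mixes the first copy's cluster-mean profile with an independent
#' profile at weight `rho_per_pair` (default 0.8).
#'
#' @param n_clusters Number of clusters.
#' @param cells_per_cluster Integer vector of cluster sizes (length
#'   `n_clusters`).
#' @param n_genes Total genes, including mitochondrial, marker and pair
#'   genes.
#' @param n_mito_genes Genes designated mitochondrial (ids prefixed
#'   `"MT-"`); their baseline means are rescaled so the expected
#'   mitochondrial fraction of a healthy cell is `mito_target_fraction`.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma Log-normal
#'   parameters of the per-gene baseline mean.
#' @param nb_dispersion Shared negative-binomial overdispersion `phi`
#'   (variance `mu + phi mu^2`); must be > 0.
#' @param lib_size_log_sigma Log-normal sigma of the per-cell library-size
#'   factor.
#' @param markers_per_cluster Planted cluster markers per cluster.
#' @param marker_fold In-cluster mean multiplier for planted markers
#'   (> 1).
#' @param marker_base_mean Out-of-cluster mean of planted markers; kept
#'   low so markers stay below the 25% out-of-cluster prevalence rule.
#' @param n_wgd_pairs Planted WGD-like paralog pairs.
#' @param rho_per_pair Mixing weight in \[0, 1\] per pair (length
#'   `n_wgd_pairs`, recycled if scalar).
#' @param pair_on_prob Probability that a pair-gene profile is "on" in a
#'   given cluster.
#' @param pair_on_mean,pair_off_mean Cluster means of pair genes in on/off
#'   clusters.
#' @param mito_target_fraction Expected mitochondrial UMI fraction of a
#'   healthy cell.
#' @param n_lowq_cells Planted low-quality cells, constructed
#'   deterministically to violate exactly one QC rule each (cycling
#'   through: too few detected genes, too many UMIs, excessive
#'   mitochondrial fraction), so QC survivor counts are exactly
#'   predictable.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 8,
                       cells_per_cluster = rep(188L, n_clusters),
                       n_genes = 2000, n_mito_genes = 50,
                       baseline_mean_log_mu = log(0.7),
                       baseline_mean_log_sigma = 1,
                       nb_dispersion = 0.5, lib_size_log_sigma = 0.3,
                       markers_per_cluster = 20, marker_fold = 8,
                       marker_base_mean = 0.1,
                       n_wgd_pairs = 100,
                       rho_per_pair = rep(0.8, n_wgd_pairs),
                       pair_on_prob = 0.4, pair_on_mean = 3,
                       pair_off_mean = 0.05,
                       mito_target_fraction = 0.02,
                       n_lowq_cells = 12, seed = 1) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              cells_per_cluster = as.integer(cells_per_cluster),
              n_genes = as.integer(n_genes),
              n_mito_genes = as.integer(n_mito_genes),
              baseline_mean_log_mu = baseline_mean_log_mu,
              baseline_mean_log_sigma = baseline_mean_log_sigma,
              nb_dispersion = nb_dispersion,
              lib_size_log_sigma = lib_size_log_sigma,
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_fold = marker_fold,
              marker_base_mean = marker_base_mean,
              n_wgd_pairs = as.integer(n_wgd_pairs),
              rho_per_pair = rep_len(rho_per_pair, n_wgd_pairs),
              pair_on_prob = pair_on_prob,
              pair_on_mean = pair_on_mean,
              pair_off_mean = pair_off_mean,
              mito_target_fraction = mito_target_fraction,
              n_lowq_cells = as.integer(n_lowq_cells),
              seed = as.integer(seed))
  for (f in c("n_clusters", "n_genes", "n_mito_genes",
              "markers_per_cluster", "n_wgd_pairs", "n_lowq_cells"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("invalid config: '%s' must be a non-negative count", f))
  if (length(cfg$cells_per_cluster) != cfg$n_clusters)
    stop("invalid config: 'cells_per_cluster' length must equal 'n_clusters'")
  if (any(cfg$cells_per_cluster < 1))
    stop("invalid config: 'cells_per_cluster' entries must be >= 1")
  if (length(cfg$rho_per_pair) != cfg$n_wgd_pairs ||
      any(cfg$rho_per_pair < 0 | cfg$rho_per_pair > 1))
    stop("invalid config: 'rho_per_pair' must be n_wgd_pairs values in [0, 1]")
  if (cfg$nb_dispersion <= 0)
    stop("invalid config: 'nb_dispersion' must be > 0")
  if (cfg$marker_fold <= 1)
    stop("invalid config: 'marker_fold' must be > 1")
  reserved <- cfg$n_mito_genes +
    cfg$n_clusters * cfg$markers_per_cluster + 2 * cfg$n_wgd_pairs
  if (reserved > cfg$n_genes)
    stop(sprintf(
      "invalid config: 'n_genes' (%d) too small for %d reserved genes",
      cfg$n_genes, reserved))
  structure(cfg, class = "sim_config")
}

#' Simulate a clustered UMI atlas with planted ground truth
#'
#' Draws per-gene negative-binomial counts with cluster-dependent means.
#' Each cluster's planted markers have their mean multiplied by
#' `marker_fold` in that cluster only. For each planted WGD pair, copy B's
#' cluster-mean profile is `rho * profile(A) + (1 - rho) * independent`,
#' with on/off cluster profiles for both. Low-quality cells are appended
#' deterministically so that QC survivor counts are exactly the designed
#' values. Fully reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_atlas`: `matrix` (a [umi_matrix()]),
#'   `clusters` (named labels for every cell, planted low-quality cells
#'   included), and `truth` (list: `marker_map` cluster -> gene ids,
#'   `pairs` data.frame `gene_a`, `gene_b`, `rho`, `lowq_cell_ids`,
#'   `annotation` gene -> term list, `config`).
#' @export
simulate_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(restore_seed(old_seed))
  set.seed(config$seed)
  K <- config$n_clusters
  G <- config$n_genes
  P <- config$n_wgd_pairs
  mpc <- config$markers_per_cluster

  ids <- sprintf("G%05d", seq_len(G))
  idx_mito <- seq_len(config$n_mito_genes)
  ids[idx_mito] <- sprintf("MT-G%04d", idx_mito)
  idx_marker <- config$n_mito_genes + seq_len(K * mpc)
  idx_pair <- config$n_mito_genes + K * mpc + seq_len(2 * P)
  idx_pair_a <- idx_pair[seq_len(P) * 2 - 1]
  idx_pair_b <- idx_pair[seq_len(P) * 2]

  base <- rlnorm(G, config$baseline_mean_log_mu,
                 config$baseline_mean_log_sigma)
  base[idx_marker] <- config$marker_base_mean
  if (length(idx_mito)) {
    f <- config$mito_target_fraction
    target <- f / (1 - f) * sum(base[-idx_mito])
    base[idx_mito] <- base[idx_mito] * target / sum(base[idx_mito])
  }

  M <- matrix(base, nrow = G, ncol = K)
  marker_map <- list()
  for (k in seq_len(K)) {
    mk <- idx_marker[(k - 1) * mpc + seq_len(mpc)]
    M[mk, k] <- config$marker_base_mean * config$marker_fold
    marker_map[[paste0("C", k)]] <- ids[mk]
  }
  on_profile <- function() {
    on <- runif(K) < config$pair_on_prob
    if (!any(on)) on[sample.int(K, 1)] <- TRUE
    ifelse(on, config$pair_on_mean, config$pair_off_mean)
  }
  for (p in seq_len(P)) {
    prof_a <- on_profile()
    prof_c <- on_profile()
    rho <- config$rho_per_pair[p]
    M[idx_pair_a[p], ] <- prof_a
    M[idx_pair_b[p], ] <- rho * prof_a + (1 - rho) * prof_c
  }

  n_cells <- sum(config$cells_per_cluster)
  labels <- rep(paste0("C", seq_len(K)), config$cells_per_cluster)
  size_f <- rlnorm(n_cells, 0, config$lib_size_log_sigma)
  nb_size <- 1 / config$nb_dispersion
  blocks <- vector("list", K)
  cell0 <- 0
  for (k in seq_len(K)) {
    nk <- config$cells_per_cluster[k]
    mu <- M[, k] %o% size_f[cell0 + seq_len(nk)]
    blocks[[k]] <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                          nrow = G)
    cell0 <- cell0 + nk
  }
  counts <- do.call(cbind, blocks)

  # deterministic low-quality cells, one violated QC rule each
  nl <- config$n_lowq_cells
  if (nl > 0) {
    lq <- matrix(0, nrow = G, ncol = nl)
    non_mito <- setdiff(seq_len(G), idx_mito)
    for (j in seq_len(nl)) {
      type <- (j - 1) %% 3 + 1
      if (type == 1) {            # too few detected genes, UMI in range
        g <- non_mito[seq_len(min(150, length(non_mito)))]
        lq[g, j] <- 1
        lq[g[1], j] <- 400       # e.g. 150 genes, 549 UMI
      } else if (type == 2) {     # too many UMIs
        g <- non_mito[seq_len(min(500, length(non_mito)))]
        lq[g, j] <- ceiling(70500 / length(g))
      } else if (length(idx_mito)) {  # excessive mitochondrial fraction
        g <- non_mito[seq_len(min(300, length(non_mito)))]
        lq[g, j] <- 3            # e.g. 900 UMI at 10% mito
        gm <- idx_mito[seq_len(min(10, length(idx_mito)))]
        lq[gm, j] <- ceiling(3 * length(g) / 9 / length(gm))
      } else {                    # no mito genes: violate the UMI floor
        g <- non_mito[seq_len(min(100, length(non_mito)))]
        lq[g, j] <- 1
      }
    }
    counts <- cbind(counts, lq)
    labels <- c(labels, rep_len(paste0("C", seq_len(K)), nl))
  }
  barcodes <- sprintf("CELL%05d", seq_len(ncol(counts)))
  lowq_ids <- if (nl > 0) barcodes[n_cells + seq_len(nl)] else character()
  dimnames(counts) <- list(ids, barcodes)

  terms <- sprintf("TERM%02d", 1:20)
  ann <- lapply(seq_len(G), function(g)
    sample(terms, sample.int(3, 1)))
  names(ann) <- ids
  for (k in seq_len(K))
    for (g in marker_map[[k]])
      ann[[g]] <- unique(c(ann[[g]], sprintf("CLUSTER%02d_PROGRAM", k)))

  m <- umi_matrix(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                  mito_genes = ids[idx_mito])
  structure(list(
    matrix = m,
    clusters = setNames(labels, barcodes),
    truth = list(marker_map = marker_map,
                 pairs = data.frame(gene_a = ids[idx_pair_a],
                                    gene_b = ids[idx_pair_b],
                                    rho = config$rho_per_pair,
                                    stringsAsFactors = FALSE),
                 lowq_cell_ids = lowq_ids,
                 annotation = ann,
                 cluster_means = M,
                 config = config)),
    class = "sim_atlas")
}

#' @export
print.sim_atlas <- function(x, ...) {
  cat(sprintf(
    "sim_atlas: %d cells (%d planted low-quality) x %d genes, %d clusters, %d pairs\n",
    nrow(x$matrix$counts), length(x$truth$lowq_cell_ids),
    ncol(x$matrix$counts), x$truth$config$n_clusters,
    nrow(x$truth$pairs)))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' All fields must be explicit in the file; unknown fields are an error.
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config field '%s'", bad[1]))
  do.call(sim_config, vals)
}
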