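#' Configuration for the end-to-end pipeline
#'
#' Collects every stage parameter with defaults equal to the standard
#' workflow values: genes kept when detected in >= 3 cells; cells kept
#' with 200-9000 detected genes, 500-70,000 UMIs and <= 5% mitochondrial
#' fraction; marker calling at `min_pct` 0.25 and natural-log fold change
#' 0.58; binarization at >= 1 UMI; pair prevalence filter 1%; cluster
#' overlap at > 25%; candidate rule top 10% of Jaccard with 1-2
#' overlapping clusters. Every default is overridable and the effective
#' values are echoed to the run manifest.
#'
#' @param out_dir Output directory for all stage outputs.
#' @param simulate Generate inputs with [simulate_atlas()] (default TRUE).
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param omega_per_pair Nonsynonymous acceptance per simulated pair; the
#'   default couples it inversely to the pair's co-expression mixing
#'   weight (`1 - 0.9 * rho`), so sequence divergence rises as expression
#'   redundancy falls.
#' @param inputs Named list of paths (`matrix`, `barcodes`, `features`,
#'   `labels`, `pairs`, optionally `fasta`, `annotation`) used when
#'   `simulate = FALSE`.
#' @param min_cells,min_genes,max_genes,min_umi,max_umi,max_mito QC
#'   thresholds (see [run_qc()]).
#' @param min_pct,logfc_threshold,alpha Marker-calling thresholds (see
#'   [call_enriched()]).
#' @param binarize_min_umi,min_prevalence Co-expression thresholds (see
#'   [binarize()], [prevalence_filter()]).
#' @param overlap_threshold,top_fraction,min_overlap,max_overlap
#'   Redundancy-classification thresholds (see [overlap_clusters()],
#'   [call_candidates()]).
#' @param n_codons,mutation_rate Codon-simulation parameters (see
#'   [simulate_codon_pairs()]).
#' @param seed Integer master seed for the run (background-pair sampling
#'   and, when simulating, the atlas and sequences).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, sim = sim_config(seed = seed),
                       omega_per_pair = NULL, inputs = list(),
                       min_cells = 3, min_genes = 200, max_genes = 9000,
                       min_umi = 500, max_umi = 70000, max_mito = 0.05,
                       min_pct = 0.25, logfc_threshold = 0.58, alpha = 0.05,
                       binarize_min_umi = 1, min_prevalence = 0.01,
                       overlap_threshold = 0.25, top_fraction = 0.10,
                       min_overlap = 1, max_overlap = 2,
                       n_codons = 200, mutation_rate = 0.6, seed = 1) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (!simulate) {
    need <- c("matrix", "barcodes", "features", "labels", "pairs")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop(sprintf("missing input path '%s' with simulate = FALSE", miss[1]))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments; the
#'   `sim` key, if present, is a mapping of [sim_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sim)) vals$sim <- do.call(sim_config, vals$sim)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop(sprintf("unknown config field '%s'", bad[1]))
  do.call(run_config, vals)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order -- simulate (or load), qc, markers,
#' coexpr, redundancy, dnds, enrich -- writing every intermediate as a
#' TSV under `config$out_dir` and a deterministic JSON run manifest
#' (`manifest.json`) recording the effective parameters, seed, per-stage
#' row counts and output files (relative to `out_dir`, so identical
#' configurations yield byte-identical outputs regardless of where they
#' are written). A stage failure aborts with the stage name and cause and
#' leaves a `FAILED` marker file.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", out))
  unlink(file.path(out, "FAILED"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("scwgd")),
    seed = config$seed, stages = list())
  manifest$parameters <-
    config[setdiff(names(config), c("sim", "inputs", "out_dir"))]
  if (config$simulate)
    manifest$sim_config <- unclass(config$sim)
  rel <- function(p) {
    p <- unlist(p, use.names = FALSE)
    as.list(ifelse(startsWith(p, paste0(out, "/")),
                   substring(p, nchar(out) + 2), p))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate or load -------------------------------------------------
  fasta_path <- NULL
  ann <- NULL
  stage("simulate", {
    if (config$simulate) {
      atlas <- simulate_atlas(config$sim)
      rho <- atlas$truth$pairs$rho
      omega <- if (is.null(config$omega_per_pair)) 1 - 0.9 * rho
               else rep_len(config$omega_per_pair, length(rho))
      seqs <- simulate_codon_pairs(atlas$truth$pairs, omega,
                                   n_codons = config$n_codons,
                                   mutation_rate = config$mutation_rate,
                                   seed = config$seed + 1000L)
      files <- write_fixture_bundle(file.path(out, "input"), atlas, seqs)
      m <- atlas$matrix
      clusters <- atlas$clusters
      pairs <- atlas$truth$pairs[, c("gene_a", "gene_b")]
      pairs$origin <- "wgd"
      ann <- list(gene2terms = atlas$truth$annotation,
                  term_labels = character())
      fasta_path <- unname(files[["fasta"]])
      manifest$stages$simulate <- list(
        files = rel(files),
        n_cells = nrow(m$counts), n_genes = ncol(m$counts))
    } else {
      inp <- config$inputs
      for (f in c("matrix", "barcodes", "features", "labels", "pairs"))
        if (!file.exists(inp[[f]]))
          stop(sprintf("missing input file '%s' (%s)", inp[[f]], f))
      m <- read_mtx_bundle(inp$matrix, inp$barcodes, inp$features,
                           mito_prefix = "MT-")
      clusters <- read_cluster_labels(inp$labels)
      pairs <- read_gene_pairs(inp$pairs)
      if (!is.null(inp$fasta)) {
        if (!file.exists(inp$fasta))
          stop(sprintf("missing input file '%s' (fasta)", inp$fasta))
        fasta_path <- inp$fasta
      }
      if (!is.null(inp$annotation))
        ann <- read_annotation(inp$annotation)
      manifest$stages$simulate <- list(
        files = rel(inp), n_cells = nrow(m$counts),
        n_genes = ncol(m$counts))
    }
  })

  # --- qc ---------------------------------------------------------------
  stage("qc", {
    qc <- run_qc(m, min_genes = config$min_genes,
                 max_genes = config$max_genes, min_umi = config$min_umi,
                 max_umi = config$max_umi, max_mito = config$max_mito,
                 min_cells = config$min_cells)
    write_tsv(qc$profiles, file.path(out, "qc_profiles.tsv"))
    write_tsv(qc$report, file.path(out, "qc_report.tsv"))
    filtered <- qc$matrix
    manifest$stages$qc <- list(
      files = list("qc_profiles.tsv", "qc_report.tsv"),
      cells_retained = nrow(qc$matrix$counts),
      genes_retained = ncol(qc$matrix$counts))
  })
  clusters_f <- clusters[rownames(filtered$counts)]

  # --- markers ----------------------------------------------------------
  stage("markers", {
    norm <- log_normalize(filtered)
    rec <- call_enriched(norm, clusters_f, min_pct = config$min_pct,
                         logfc_threshold = config$logfc_threshold,
                         alpha = config$alpha)
    rec <- call_specific(rec)
    write_tsv(rec, file.path(out, "markers.tsv"))
    markers <- rec
    pct_table <- attr(rec, "pct_table")
    manifest$stages$markers <- list(
      files = list("markers.tsv"),
      n_tested = nrow(rec), n_enriched = sum(rec$is_enriched),
      n_specific = sum(rec$is_specific))
  })

  # --- coexpr -----------------------------------------------------------
  stage("coexpr", {
    bin <- binarize(filtered, min_umi = config$binarize_min_umi)
    wgd <- suppressMessages(
      jaccard_pairs(bin, pairs, min_frac = config$min_prevalence))
    write_tsv(wgd, file.path(out, "jaccard_wgd.tsv"))
    wgd_scores <- wgd
    manifest$stages$coexpr <- list(
      files = list("jaccard_wgd.tsv"),
      n_pairs_analyzed = nrow(wgd),
      n_pairs_dropped = attr(wgd, "n_dropped"))
  })

  # --- redundancy -------------------------------------------------------
  stage("redundancy", {
    retained <- prevalence_filter(bin, config$min_prevalence)
    bg_pairs <- sample_background_pairs(retained, wgd_scores,
                                        n = nrow(wgd_scores),
                                        seed = config$seed + 2000L)
    bg <- suppressMessages(
      jaccard_pairs(bin, bg_pairs, min_frac = config$min_prevalence))
    comp <- compare_to_background(wgd_scores$jaccard, bg$jaccard,
                                  paired = TRUE)
    scores <- overlap_clusters(wgd_scores, pct_table,
                               threshold = config$overlap_threshold)
    scores <- call_candidates(scores, top_fraction = config$top_fraction,
                              min_overlap = config$min_overlap,
                              max_overlap = config$max_overlap)
    write_tsv(bg, file.path(out, "jaccard_background.tsv"))
    write_tsv(comp, file.path(out, "background_comparison.tsv"))
    write_tsv(scores, file.path(out, "pair_scores.tsv"))
    pair_scores <- scores
    manifest$stages$redundancy <- list(
      files = list("jaccard_background.tsv", "background_comparison.tsv",
                   "pair_scores.tsv"),
      n_pairs = nrow(scores), n_candidates = sum(scores$is_candidate),
      signed_rank_p = comp$p_value)
  })

  # --- dnds -------------------------------------------------------------
  stage("dnds", {
    if (is.null(fasta_path)) {
      manifest$stages$dnds <- list(skipped = "no sequences supplied")
    } else {
      div <- suppressMessages(divergence_table(fasta_path, pair_scores))
      write_tsv(div, file.path(out, "divergence.tsv"))
      sc <- pair_scores
      sc$dnds_ratio <- div$dnds_ratio
      trend <- jaccard_dnds_trend(sc)
      write_tsv(trend$bins, file.path(out, "dnds_trend_bins.tsv"))
      manifest$stages$dnds <- list(
        files = list("divergence.tsv", "dnds_trend_bins.tsv"),
        n_pairs = trend$n_pairs, n_excluded = trend$n_excluded,
        spearman_rho = trend$spearman_rho)
    }
  })

  # --- enrich -----------------------------------------------------------
  stage("enrich", {
    if (is.null(ann)) {
      manifest$stages$enrich <- list(skipped = "no annotation supplied")
    } else {
      study <- unique(c(pair_scores$gene_a[pair_scores$is_candidate],
                        pair_scores$gene_b[pair_scores$is_candidate]))
      background <- prevalence_filter(bin, config$min_prevalence)
      study <- intersect(study, background)
      if (!length(intersect(study, names(ann$gene2terms)))) {
        enr <- data.frame(term = character(), label = character(),
                          k = integer(), n = integer(), K = integer(),
                          M = integer(), p_value = numeric(),
                          p_adjusted = numeric())
      } else {
        enr <- fisher_enrichment(study, background, ann)
      }
      write_tsv(enr, file.path(out, "enrichment.tsv"))
      manifest$stages$enrich <- list(
        files = list("enrichment.tsv"),
        n_study = length(study), n_terms = nrow(enr))
    }
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
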