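small_cfg <- function(seed = 7, ...) {
  sim_config(n_clusters = 3, cells_per_cluster = rep(100L, 3),
             n_genes = 500, n_mito_genes = 10, markers_per_cluster = 5,
             n_wgd_pairs = 10, rho_per_pair = rep(0.5, 10),
             n_lowq_cells = 0, seed = seed, ...)
}

test_that("atlas dimensions and labels are forced by the configuration", {
  a <- simulate_atlas(small_cfg())
  expect_equal(dim(a$matrix), c(300L, 500L))
  expect_equal(unname(table(a$clusters)), rep(100L, 3), ignore_attr = TRUE)
  expect_equal(nlevels(factor(a$clusters)), 3L)
  expect_length(a$matrix$mito_genes, 10L)
  # planted markers and pair genes all exist in the matrix
  expect_true(all(unlist(a$truth$marker_map) %in% colnames(a$matrix$counts)))
  pg <- c(a$truth$pairs$gene_a, a$truth$pairs$gene_b)
  expect_true(all(pg %in% colnames(a$matrix$counts)))
  expect_false(any(duplicated(pg)))        # pair genes disjoint across pairs
})

test_that("generation is bit-reproducible under a fixed seed", {
  a1 <- simulate_atlas(small_cfg(seed = 42))
  a2 <- simulate_atlas(small_cfg(seed = 42))
  expect_identical(as.matrix(a1$matrix$counts), as.matrix(a2$matrix$counts))
  expect_identical(a1$truth$marker_map, a2$truth$marker_map)
  a3 <- simulate_atlas(small_cfg(seed = 43))
  expect_false(identical(as.matrix(a1$matrix$counts),
                         as.matrix(a3$matrix$counts)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_clusters = 3, cells_per_cluster = c(10, 10)),
               "cells_per_cluster")
  expect_error(sim_config(n_wgd_pairs = 5, rho_per_pair = c(0.5, 1.7)),
               "rho_per_pair")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(marker_fold = 1), "marker_fold")
  expect_error(sim_config(n_genes = 100), "n_genes")
})

test_that("planted low-quality cells each violate a QC rule", {
  a <- simulate_atlas(sim_config(n_clusters = 3,
                                 cells_per_cluster = rep(50L, 3),
                                 n_genes = 600, n_mito_genes = 10,
                                 markers_per_cluster = 5, n_wgd_pairs = 5,
                                 rho_per_pair = rep(0.5, 5),
                                 n_lowq_cells = 6, seed = 2))
  prof <- qc_profile(a$matrix)
  lowq <- prof[prof$barcode %in% a$truth$lowq_cell_ids, ]
  violates <- lowq$n_genes < 200 | lowq$n_genes > 9000 |
    lowq$n_umi < 500 | lowq$n_umi > 70000 | lowq$mito_fraction > 0.05
  expect_true(all(violates))
  expect_equal(nrow(lowq), 6L)
  # labels cover the planted cells too
  expect_true(all(a$truth$lowq_cell_ids %in% names(a$clusters)))
})

test_that("higher mixing weight yields higher pair Jaccard", {
  diffs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_clusters = 4, cells_per_cluster = rep(80L, 4),
                      n_genes = 600, n_mito_genes = 10,
                      markers_per_cluster = 5, n_wgd_pairs = 40,
                      rho_per_pair = rep(c(0.9, 0.1), each = 20),
                      n_lowq_cells = 0, seed = s)
    a <- simulate_atlas(cfg)
    j <- suppressWarnings(suppressMessages(
      jaccard_pairs(binarize(a$matrix), a$truth$pairs)))
    mean(j$jaccard[j$rho > 0.5]) - mean(j$jaccard[j$rho < 0.5])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("codon simulation respects omega and the no-mutation limit", {
  pairs <- data.frame(gene_a = "pA", gene_b = "pB")
  s0 <- simulate_codon_pairs(pairs, omega = 0.5, n_codons = 50,
                             mutation_rate = 0, seed = 1)
  expect_identical(s0$seq_a, s0$seq_b)     # no proposals, both = ancestor
  expect_error(simulate_codon_pairs(pairs, omega = 0), "omega")
  expect_error(simulate_codon_pairs(pairs, omega = 1.2), "omega")
  expect_error(simulate_codon_pairs(pairs, omega = 1, n_codons = 10),
               "n_codons")
  # determinism
  s1 <- simulate_codon_pairs(pairs, 0.3, n_codons = 60, seed = 9)
  s2 <- simulate_codon_pairs(pairs, 0.3, n_codons = 60, seed = 9)
  expect_identical(s1, s2)
  # simulated sequences are stop-free and in frame
  expect_silent(p <- codon_pair("a", "b", s1$seq_a, s1$seq_b))
})

test_that("realized dN/dS increases over an omega grid", {
  grid <- c(0.05, 0.2, 0.5, 1.0)
  meds <- sapply(grid, function(w) {
    ratios <- vapply(1:4, function(s) {
      sc <- simulate_codon_pairs(data.frame(gene_a = "a", gene_b = "b"),
                                 omega = w, n_codons = 200,
                                 mutation_rate = 0.5, seed = s * 13)
      divergence(codon_pair("a", "b", sc$seq_a, sc$seq_b))$dnds_ratio
    }, numeric(1))
    median(ratios)
  })
  expect_true(all(diff(meds) > 0))
})

test_that("neutral simulation recovers dN/dS near one", {
  # the neutral limit carries a small systematic deficit (~10%): proposals
  # creating stop codons are rejected by the simulator, while the
  # estimator counts stop-adjacent changes as nonsynonymous sites; the
  # tolerance below accommodates that documented convention
  ratios <- vapply(1:10, function(s) {
    sc <- simulate_codon_pairs(data.frame(gene_a = "a", gene_b = "b"),
                               omega = 1, n_codons = 500,
                               mutation_rate = 0.3, seed = s)
    divergence(codon_pair("a", "b", sc$seq_a, sc$seq_b))$dnds_ratio
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.15)
  expect_gt(mean(ratios), 0.8)
})

test_that("fixture bundle round-trips and lists every input file", {
  d <- withr::local_tempdir()
  a <- simulate_atlas(small_cfg(seed = 5))
  seqs <- simulate_codon_pairs(a$truth$pairs, omega = 0.5, n_codons = 60,
                               seed = 6)
  manifest <- write_fixture_bundle(d, a, seqs)
  expect_setequal(names(manifest), c("matrix", "barcodes", "features",
                                     "labels", "pairs", "annotation",
                                     "fasta"))
  expect_true(all(file.exists(manifest)))
  back <- read_mtx_bundle(manifest["matrix"], manifest["barcodes"],
                          manifest["features"], mito_prefix = "MT-")
  expect_identical(as.matrix(back$counts), as.matrix(a$matrix$counts))
  expect_identical(back$mito_genes, a$matrix$mito_genes)
  labels <- read_cluster_labels(manifest["labels"])
  expect_identical(labels, a$clusters)
  pairs <- read_gene_pairs(manifest["pairs"])
  expect_identical(pairs$gene_a, a$truth$pairs$gene_a)

  # empty pair set -> header-only TSV
  a0 <- simulate_atlas(sim_config(n_clusters = 2,
                                  cells_per_cluster = c(20L, 20L),
                                  n_genes = 200, n_mito_genes = 5,
                                  markers_per_cluster = 2, n_wgd_pairs = 0,
                                  rho_per_pair = numeric(),
                                  n_lowq_cells = 0, seed = 1))
  m0 <- write_fixture_bundle(file.path(d, "empty"), a0)
  expect_equal(readLines(m0["pairs"]), "gene_a\tgene_b")
})
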