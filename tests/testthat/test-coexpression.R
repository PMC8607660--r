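test_that("binarization codes presence at the UMI threshold", {
  mat <- cbind(a = c(0, 1, 7), b = c(0, 0, 0), c = c(1, 1, 2))
  um <- make_umi(mat)
  bin <- binarize(um)
  expect_equal(as.numeric(bin$presence[, "a"]), c(0, 1, 1))
  expect_equal(unname(bin$prevalence["b"]), 0)
  # non-default threshold: a count of 1 is below 2
  bin2 <- binarize(um, min_umi = 2)
  expect_equal(as.numeric(bin2$presence[, "a"]), c(0, 0, 1))
  expect_equal(unname(bin2$prevalence["c"]), 1 / 3)
})

test_that("prevalence filter boundary is inclusive", {
  mat <- matrix(0, nrow = 200, ncol = 3)
  mat[1:2, 1] <- 1      # 1% exactly -> retained
  mat[1, 2] <- 1        # 0.5% -> excluded
  mat[, 3] <- 1
  bin <- binarize(make_umi(mat))
  expect_setequal(prevalence_filter(bin, 0.01), c("G001", "G003"))
  expect_setequal(prevalence_filter(bin, 0), c("G001", "G002", "G003"))
})

test_that("Jaccard of pairs matches direct set counting", {
  mat <- cbind(a = c(1, 1, 0, 1, 0), b = c(1, 0, 0, 1, 1),
               c = c(1, 1, 0, 1, 0), d = c(0, 0, 1, 0, 1))
  bin <- binarize(make_umi(mat))
  pairs <- data.frame(gene_a = c("a", "a", "a"),
                      gene_b = c("b", "c", "d"))
  j <- jaccard_pairs(bin, pairs)
  expect_equal(j$n_both, c(2L, 3L, 0L))
  expect_equal(j$n_either, c(4L, 3L, 5L))
  expect_equal(j$jaccard, c(0.5, 1, 0))    # identical -> 1, disjoint -> 0
  expect_error(jaccard_pairs(bin, data.frame(gene_a = "a", gene_b = "zz")),
               "unknown gene id 'zz'")
})

test_that("pairs failing prevalence are dropped and counted", {
  mat <- matrix(0, nrow = 300, ncol = 3)
  mat[1:50, 1] <- 1
  mat[1:50, 2] <- 1
  mat[1, 3] <- 1                       # 0.33% -> fails 1% filter
  bin <- binarize(make_umi(mat))
  pairs <- data.frame(gene_a = c("G001", "G001"), gene_b = c("G002", "G003"))
  expect_message(j <- jaccard_pairs(bin, pairs), "dropping 1 pair")
  expect_equal(nrow(j), 1L)
  expect_equal(attr(j, "n_dropped"), 1L)
})

test_that("Jaccard agrees with brute force on random sparse fixtures", {
  set.seed(202)
  n_cells <- 60; n_genes <- 40
  mat <- matrix(rbinom(n_cells * n_genes, 1, 0.3) *
                  (1 + rpois(n_cells * n_genes, 2)), nrow = n_cells)
  bin <- binarize(make_umi(mat))
  genes <- prevalence_filter(bin, 0.01)
  idx <- t(replicate(200, sample(genes, 2)))
  pairs <- data.frame(gene_a = idx[, 1], gene_b = idx[, 2])
  j <- suppressMessages(jaccard_pairs(bin, pairs))
  brute <- vapply(seq_len(nrow(j)), function(i) {
    sa <- which(mat[, match(j$gene_a[i], colnames(bin$presence))] >= 1)
    sb <- which(mat[, match(j$gene_b[i], colnames(bin$presence))] >= 1)
    length(intersect(sa, sb)) / length(union(sa, sb))
  }, numeric(1))
  expect_equal(j$jaccard, brute, tolerance = 1e-12)
  # symmetry and bounds
  jswap <- suppressMessages(jaccard_pairs(
    bin, data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a)))
  expect_equal(j$jaccard, jswap$jaccard)
  expect_true(all(j$jaccard >= 0 & j$jaccard <= 1))
})

test_that("corrupting k of m positive cells gives Jaccard (m-k)/(m+k)", {
  n_cells <- 100; m <- 30
  for (k in c(0, 5, 15)) {
    mat <- matrix(0, nrow = n_cells, ncol = 2,
                  dimnames = list(NULL, c("orig", "corrupt")))
    mat[1:m, "orig"] <- 1
    mat[1:m, "corrupt"] <- 1
    if (k > 0) {
      mat[seq_len(k), "corrupt"] <- 0          # move k positives ...
      mat[m + seq_len(k), "corrupt"] <- 1      # ... to new cells
    }
    bin <- binarize(make_umi(mat))
    j <- jaccard_pairs(bin, data.frame(gene_a = "orig", gene_b = "corrupt"))
    expect_equal(j$jaccard, (m - k) / (m + k))
  }
})

test_that("prevalence after binarization is invariant to cell permutation", {
  set.seed(11)
  mat <- matrix(rpois(50 * 20, 0.4), nrow = 50)
  bin <- binarize(make_umi(mat))
  perm <- sample(50)
  mat_p <- mat[perm, ]
  bin_p <- binarize(make_umi(mat_p))
  expect_equal(bin$prevalence, bin_p$prevalence)
  expect_setequal(prevalence_filter(bin, 0.05),
                  prevalence_filter(bin_p, 0.05))
})

test_that("one-vs-all profile excludes the gene itself and conserves counts", {
  set.seed(33)
  mat <- matrix(rbinom(80 * 25, 1, 0.4), nrow = 80)
  bin <- binarize(make_umi(mat))
  retained <- prevalence_filter(bin, 0.01)
  prof <- jaccard_profile(bin, "G001")
  expect_false("G001" %in% names(prof$values))
  expect_equal(length(prof$values), length(retained) - 1)
  expect_equal(sum(prof$histogram$count),
               sum(!is.na(prof$values)))
  expect_error(jaccard_profile(bin, "nope"), "unknown gene")
})

test_that("Pearson network handles duplicates, bounds and zero variance", {
  set.seed(44)
  mat <- cbind(a = rpois(30, 5), flat = rep(2, 30))
  mat <- cbind(mat, b = mat[, "a"])        # duplicate of a
  mat <- cbind(mat, pad = rpois(30, 50) + 1)
  um <- make_umi(mat)
  # equalize cell totals so duplicated counts give duplicated values
  norm <- structure(list(values = Matrix::Matrix(mat, sparse = TRUE),
                         scale = 1), class = "normalized_matrix")
  expect_message(edges <- pearson_network(norm, c("a", "b", "flat"), 0.9),
                 "zero-variance")
  expect_equal(attr(edges, "n_zero_variance"), 1L)
  dup <- edges[edges$gene_a == "a" & edges$gene_b == "b", ]
  expect_equal(dup$r, 1, tolerance = 1e-12)
  # an impossible threshold yields no edges
  expect_equal(nrow(pearson_network(norm, c("a", "b"), 1.01)), 0L)
})
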