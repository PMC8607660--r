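test_that("expression_pct counts expressing cells per cluster", {
  mat <- matrix(0, nrow = 7, ncol = 3)
  rownames(mat) <- sprintf("BC%03d", 1:7)
  mat[1:3, 1] <- 1          # gene 1 in 3 of 4 cells of cluster A
  mat[, 3] <- 2             # gene 3 in every cell
  um <- make_umi(mat)
  cl <- setNames(c(rep("A", 4), rep("B", 3)), rownames(mat))
  pct <- expression_pct(um, cl)
  expect_equal(pct["G001", "A"], 0.75)
  expect_equal(pct["G001", "B"], 0)
  expect_equal(unname(pct["G002", ]), c(0, 0))       # all-zero gene
  expect_equal(unname(pct["G003", ]), c(1, 1))       # ubiquitous gene
  expect_equal(sum(attr(pct, "cluster_sizes")), 7L)
})

test_that("cluster log fold change follows the expm1-mean convention", {
  # craft normalized values directly via known counts
  mat <- matrix(1, nrow = 8, ncol = 3)
  dimnames(mat) <- list(sprintf("BC%03d", 1:8), c("flat", "up", "pad"))
  mat[, "pad"] <- 97                      # cell total 99 with flat+up at 1
  um <- make_umi(mat)
  norm <- log_normalize(um, scale = 99)   # value = log(1 + count)
  cl <- setNames(c(rep("in", 4), rep("out", 4)), rownames(mat))
  # identical distributions -> 0
  expect_equal(cluster_log_fc(norm, cl, "flat", "in"), 0, tolerance = 1e-12)
  # antisymmetry
  expect_equal(cluster_log_fc(norm, cl, "up", "in"),
               -cluster_log_fc(norm, cl, "up", "out"), tolerance = 1e-12)

  # in-cluster mean expm1 = 4, out = 0 -> ln 5
  mat2 <- matrix(0, nrow = 8, ncol = 2)
  dimnames(mat2) <- list(sprintf("BC%03d", 1:8), c("gene", "pad"))
  mat2[1:4, "gene"] <- 4
  mat2[, "pad"] <- c(rep(95, 4), rep(99, 4))
  um2 <- make_umi(mat2)
  norm2 <- log_normalize(um2, scale = 99)
  cl2 <- setNames(c(rep("in", 4), rep("out", 4)), rownames(mat2))
  expect_equal(cluster_log_fc(norm2, cl2, "gene", "in"), log(5),
               tolerance = 1e-12)
})

test_that("rank-sum p-values agree with complete-enumeration oracle", {
  set.seed(101)
  for (i in 1:30) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    # heavy ties on purpose: integer values from a small support
    x <- sample(0:3, n1, replace = TRUE)
    y <- sample(0:3, n2, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12,
                 info = sprintf("case %d", i))
  }
})

test_that("marker screening honors min.pct and log-FC thresholds", {
  set.seed(7)
  n <- 40                                  # 20 cells per cluster
  mat <- matrix(0, nrow = n, ncol = 4)
  dimnames(mat) <- list(sprintf("BC%03d", 1:n),
                        c("marker", "lowpct", "lowfc", "pad"))
  mat[1:20, "marker"] <- 5                                # clean separation
  mat[c(1:4, 21:22), "lowpct"] <- 8                       # pct .20 / .10
  mat[, "lowfc"] <- rpois(n, 20)                          # no real change
  mat[, "pad"] <- 50
  um <- make_umi(mat)
  cl <- setNames(rep(c("c1", "c2"), each = 20), rownames(mat))
  norm <- log_normalize(um)
  rec <- call_enriched(norm, cl)
  expect_true(any(rec$gene == "marker" & rec$cluster == "c1" &
                    rec$is_enriched))
  expect_false("lowpct" %in% rec$gene)      # fails min.pct screen
  expect_false("lowfc" %in% rec$gene)       # fails log-FC screen
  # screened-in records all satisfy the thresholds
  expect_true(all(pmax(rec$pct_in, rec$pct_rest) >= 0.25))
  expect_true(all(rec$log_fc >= 0.58))
})

test_that("small-sample marker p-values are exact", {
  # complete separation, 4 cells per cluster: exact rank-sum enumeration
  mat <- matrix(0, nrow = 8, ncol = 2)
  dimnames(mat) <- list(sprintf("BC%03d", 1:8), c("marker", "pad"))
  mat[1:4, "marker"] <- 3
  mat[, "pad"] <- 10
  um <- make_umi(mat)
  cl <- setNames(rep(c("c1", "c2"), each = 4), rownames(mat))
  rec <- call_enriched(log_normalize(um), cl)
  row <- rec[rec$gene == "marker" & rec$cluster == "c1", ]
  x <- as.numeric(log_normalize(um)$values[1:4, "marker"])
  y <- as.numeric(log_normalize(um)$values[5:8, "marker"])
  expect_equal(row$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
  expect_equal(row$p_value, 2 / choose(8, 4), tolerance = 1e-12)
})

test_that("cluster-specific rule: inclusive inside, strict outside", {
  rec <- data.frame(gene = c("g1", "g2", "g3"), cluster = "A",
                    pct_in = c(0.30, 0.30, 0.25),
                    max_pct_out = c(0.10, 0.26, 0.24),
                    is_enriched = TRUE)
  pct <- rbind(g1 = c(A = 0.30, B = 0.10, C = 0.05),
               g2 = c(A = 0.30, B = 0.26, C = 0.05),
               g3 = c(A = 0.25, B = 0.24, C = 0.10))
  out <- call_specific(rec, pct_table = pct)
  expect_equal(out$is_specific, c(TRUE, FALSE, TRUE))
  # a non-enriched record can never be specific
  rec$is_enriched <- FALSE
  expect_false(any(call_specific(rec, pct_table = pct)$is_specific))
})

test_that("noise-free planted markers are recovered exactly", {
  k <- 3; per <- 30
  n <- k * per
  genes <- c(sprintf("MK%d_%d", rep(1:k, each = 3), 1:3),
             sprintf("BG%02d", 1:20))
  mat <- matrix(0, nrow = n, ncol = length(genes),
                dimnames = list(sprintf("BC%03d", 1:n), genes))
  mat[, startsWith(genes, "BG")] <- 1
  cl <- setNames(rep(paste0("C", 1:k), each = per), rownames(mat))
  for (ki in 1:k)
    mat[cl == paste0("C", ki), sprintf("MK%d_%d", ki, 1:3)] <- 5
  um <- make_umi(mat)
  rec <- call_specific(call_enriched(log_normalize(um), cl))
  called <- rec[rec$is_specific, c("gene", "cluster")]
  planted <- data.frame(gene = sprintf("MK%d_%d", rep(1:k, each = 3), 1:3),
                        cluster = paste0("C", rep(1:k, each = 3)))
  expect_setequal(paste(called$gene, called$cluster),
                  paste(planted$gene, planted$cluster))
})

test_that("single-cluster input is rejected", {
  um <- make_umi(matrix(1, 4, 3))
  cl <- setNames(rep("only", 4), rownames(um$counts))
  expect_error(call_enriched(log_normalize(um), cl), "two clusters")
})
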