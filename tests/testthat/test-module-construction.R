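test_that("samples and probes merge by mean before per-ROI standardization", {
  raw <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  # s1, s2 -> roi_a; s3 -> roi_b
  merged <- preprocess_expression(raw,
    sample_to_roi = c(s1 = "roi_a", s2 = "roi_a", s3 = "roi_b"),
    normalize = FALSE)
  expect_equal(merged[, "roi_a"], c(p1 = 1.5, p2 = 4.5))
  expect_equal(merged[, "roi_b"], c(p1 = 3, p2 = 6))

  # two probes of one gene average row-wise
  merged2 <- preprocess_expression(raw,
    probe_to_gene = c(p1 = "gene1", p2 = "gene1"), normalize = FALSE)
  expect_equal(unname(merged2["gene1", ]), c(2.5, 3.5, 4.5))
})

test_that("normalization yields population-sd z-scores; constant columns flagged", {
  set.seed(1)
  raw <- matrix(rnorm(40, mean = 5, sd = 3), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("r", 1:5)))
  norm <- preprocess_expression(raw)
  expect_true(all(abs(colMeans(norm)) < 1e-9))
  pop_sd <- sqrt(colMeans(norm^2) - colMeans(norm)^2)
  expect_true(all(abs(pop_sd - 1) < 1e-9))

  raw[, 2] <- 7  # constant ROI column
  norm2 <- preprocess_expression(raw)
  expect_equal(attr(norm2, "constant_cols"), "r2")
  expect_true(all(norm2[, 2] == 0))
})

test_that("correlation dissimilarity matches the hand-computed Pearson oracle", {
  expect_equal(gene_dissimilarity(c(1, 2, 3), c(2, 4, 6)), 0)   # corr +1
  expect_equal(gene_dissimilarity(c(1, 2, 3), c(3, 2, 1)), 1)   # corr -1
  # hand Pearson: cov = 0.5, sds = 1 -> corr = 0.5 -> d = 0.25
  expect_equal(gene_dissimilarity(c(1, 2, 3), c(1, 3, 2)), 0.25)
  expect_equal(roi_dissimilarity(c(1, 2, 3), c(1, 3, 2)), 0.25)
  expect_warning(d <- gene_dissimilarity(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(d, 0.5)

  set.seed(5)
  e <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("g", 1:6),
                                                paste0("r", 1:10)))
  dg <- gene_distance_matrix(e)
  dr <- roi_distance_matrix(e)
  for (d in list(dg, dr)) {
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  expect_equal(dg["g1", "g2"], gene_dissimilarity(e["g1", ], e["g2", ]))
  expect_equal(dr["r1", "r3"], roi_dissimilarity(e[, "r1"], e[, "r3"]))
})

test_that("UPGMA reproduces hand-computed merges and rejects bad input", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  hc <- upgma_cluster(d2)
  expect_equal(hc$height, 0.4)

  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  hc3 <- upgma_cluster(d3)
  expect_equal(hc3$height, c(2, 4))  # (A,B)@2 then ({A,B},C)@avg(4,4)=4

  d0 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(upgma_cluster(d0)$height, c(0, 0))

  dn <- d3; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(upgma_cluster(dn), "NaN")
})

test_that("UPGMA heights match a naive reference and never invert", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 12), n)
    d <- (1 - cor(t(x))) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    hc <- upgma_cluster(d)
    expect_true(!is.unsorted(hc$height))
    expect_equal(hc$height, naive_upgma_heights(d), tolerance = 1e-12)
  }
})

test_that("the half-height cut partitions leaves at 0.5 x root height", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  cl <- cut_half_height(upgma_cluster(d3))
  expect_equal(attr(cl, "cutoff"), 2)
  expect_setequal(vapply(cl, paste, "", collapse = ","), c("A,B", "C"))

  # all merges above the cutoff -> singletons
  d4 <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- 0.7  # root at ~0.8, cutoff ~0.4
  cl4 <- cut_half_height(upgma_cluster(d4))
  expect_equal(lengths(cl4), rep(1L, 4))

  # all merges at height 0 -> one cluster of all leaves
  d0 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  cl0 <- cut_half_height(upgma_cluster(d0))
  expect_equal(lengths(cl0), 4L)

  # property: output is a partition of the leaves
  set.seed(13)
  x <- matrix(rnorm(20 * 8), 20, dimnames = list(paste0("g", 1:20), NULL))
  cl <- cut_half_height(upgma_cluster(gene_distance_matrix(x)))
  expect_setequal(unlist(cl), rownames(x))
  expect_equal(sum(lengths(cl)), 20L)
})

test_that("size filters keep inclusive bounds and stable ids", {
  clusters <- list(paste0("a", 1:5), paste0("b", 1:10), paste0("c", 1:200),
                   paste0("d", 1:201))
  kept <- filter_gene_clusters(clusters)
  expect_equal(lengths(kept), c(GS01 = 10L, GS02 = 200L))
  expect_length(filter_gene_clusters(list()), 0)
  all_ok <- filter_gene_clusters(clusters[2:3])
  expect_equal(length(all_ok), 2L)

  circuits <- filter_roi_clusters(list("r1", c("r1", "r2"), paste0("q", 1:5)))
  expect_equal(lengths(circuits), c(BC01 = 2L, BC02 = 5L))
})
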