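make_snps <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("snp_id", "chrom", "pos", "qt_id", "p_value")
  df
}

test_that("min-p window mapping follows the +/- 20 kb closed-window rule", {
  genes <- data.frame(gene_id = "GENE1", chrom = "1",
                      start = 10000L, end = 11000L)
  # SNP at 15000 is inside [1, 31000]; SNP at 40000 is outside
  snps <- make_snps(c("rs1", "rs2"), "1", c(15000L, 40000L), "QT_A",
                    c(0.01, 1e-8))
  gqm <- map_snps_to_genes(snps, genes, window_bp = 20000)
  expect_equal(gqm$p_values["GENE1", "QT_A"], 0.01)

  # two in-window SNPs -> the minimum
  snps2 <- make_snps(c("rs1", "rs2"), "1", c(10500L, 30000L), "QT_A",
                     c(0.5, 1e-6))
  gqm2 <- map_snps_to_genes(snps2, genes, window_bp = 20000)
  expect_equal(gqm2$p_values["GENE1", "QT_A"], 1e-6)

  # window boundaries are inclusive; one bp outside is excluded
  for (pos in c(31000L, 31001L)) {
    g <- map_snps_to_genes(
      make_snps(c("rs_in", "rs_edge"), "1", c(10500L, pos), "QT_A",
                c(0.5, 1e-9)),
      genes, window_bp = 20000)
    expect_equal(unname(g$p_values["GENE1", "QT_A"]),
                 if (pos == 31000L) 1e-9 else 0.5)
  }
})

test_that("genes with no in-window SNP are dropped or filled per QT", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = c("1", "2"),
                      start = c(100L, 100L), end = c(200L, 200L))
  snps <- make_snps(c("rs1", "rs1", "rs2"), c("1", "1", "1"),
                    c(150L, 150L, 160L), c("QT_A", "QT_B", "QT_A"),
                    c(0.2, 0.3, 0.1))
  gqm <- map_snps_to_genes(snps, genes, window_bp = 0)
  # gene B (chr2, no SNPs) dropped entirely
  expect_equal(gqm$gene_ids, "A")
  expect_equal(gqm$n_qts, 2)
  expect_equal(gqm$universe_size, 2)

  # a gene covered for one QT but not another gets filler p = 1
  snps3 <- make_snps(c("rs1", "rs2"), "1", c(150L, 150L),
                     c("QT_A", "QT_B"), c(0.2, 0.3))
  genes2 <- data.frame(gene_id = c("A", "C"), chrom = "1",
                       start = c(100L, 1000L), end = c(200L, 2000L))
  gqm3 <- map_snps_to_genes(snps3, genes2, window_bp = 900)
  # gene C window [100, 2900] includes pos 150 only via window; both QTs hit A
  expect_true(all(gqm3$p_values <= 1))
  expect_equal(dim(gqm3$p_values), c(2L, 2L))

  # chromosome dialects are normalized before matching
  snps4 <- make_snps("rs1", "chr1", 150L, "QT_A", 0.2)
  gqm4 <- map_snps_to_genes(snps4, genes, window_bp = 0)
  expect_equal(gqm4$gene_ids, "A")

  expect_error(
    map_snps_to_genes(make_snps("rs1", "9", 150L, "QT_A", 0.2), genes, 0),
    "no gene")
})

test_that("mapping agrees with an exhaustive double loop on random inputs", {
  set.seed(7)
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = sample(c("1", "2"), 5, TRUE),
                      start = sample(1000:50000, 5), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:5000, 5)
  qts <- c("b1", "b2")
  snps <- data.frame(snp_id = rep(paste0("rs", 1:50), each = 2),
                     chrom = rep(sample(c("1", "2"), 50, TRUE), each = 2),
                     pos = rep(sample(1:80000, 50), each = 2),
                     qt_id = rep(qts, times = 50),
                     p_value = runif(100), stringsAsFactors = FALSE)
  w <- 3000
  gqm <- map_snps_to_genes(snps, genes, window_bp = w)

  # oracle: brute-force min over the closed window, per gene and QT
  for (g in seq_len(nrow(genes))) for (b in qts) {
    inwin <- snps$chrom == genes$chrom[g] & snps$qt_id == b &
      snps$pos >= max(1, genes$start[g] - w) & snps$pos <= genes$end[g] + w
    expected <- if (any(inwin)) min(snps$p_value[inwin]) else NA
    if (genes$gene_id[g] %in% gqm$gene_ids) {
      got <- gqm$p_values[genes$gene_id[g], b]
      expect_equal(got, if (is.na(expected)) 1 else expected)
    } else {
      # dropped genes must have no in-window SNP for any QT
      expect_true(is.na(expected))
    }
  }
})

test_that("enlarging the window never increases a gene's p-value", {
  set.seed(11)
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "1",
                      start = c(1000L, 30000L, 60000L, 90000L))
  genes$end <- genes$start + 2000L
  snps <- data.frame(snp_id = paste0("rs", 1:40), chrom = "1",
                     pos = sample(1:120000, 40), qt_id = "b1",
                     p_value = runif(40), stringsAsFactors = FALSE)
  prev <- NULL
  for (w in c(0, 5000, 20000, 60000)) {
    gqm <- map_snps_to_genes(snps, genes, window_bp = w)
    cur <- gqm$p_values[, "b1"]
    if (!is.null(prev)) {
      shared <- intersect(names(prev), names(cur))
      expect_true(all(cur[shared] <= prev[shared] + 1e-15))
    }
    prev <- cur
  }
})

test_that("significant pair counts are monotone in the threshold", {
  set.seed(3)
  p <- matrix(runif(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("b", 1:10)))
  gqm <- gene_qt_matrix(p)

  # strict inequality at the threshold
  p2 <- p; p2[1, 1] <- 1e-5
  gqm2 <- gene_qt_matrix(p2)
  s <- significant_pairs(gqm2, 1e-5)
  expect_false(any(s$pairs$gene_id == "g1" & s$pairs$qt_id == "b1"))

  expect_equal(significant_pairs(gqm, 1)$n, 200)  # all entries < 1 a.s.
  expect_equal(significant_pairs(gene_qt_matrix(
    matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))), 1e-5)$n, 0)

  sizes <- vapply(c(1e-4, 1e-2, 0.1, 0.5, 1),
                  function(t) significant_pairs(gqm, t)$n, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
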