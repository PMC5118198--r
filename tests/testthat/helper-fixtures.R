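# Shared fixtures and independent oracles for the test suite.

options(igea.verbose = FALSE)

# Exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws
# of the significant set and count those with >= k module pairs.  Returns
# the whole tail distribution P(X >= k) for k = 0..min(m, n) at once.
enumerate_upper_tail <- function(N, n, m) {
  marked <- seq_len(m)                    # wlog the first m items are marked
  if (n == 0) {
    tails <- c(1, rep(0, 0))
    return(function(k) if (k == 0) 1 else 0)
  }
  draws <- utils::combn(N, n)
  overlap <- colSums(matrix(draws %in% marked, nrow = n))
  function(k) mean(overlap >= k)
}

# Naive O(n^3) UPGMA reference: merge closest pair, inter-cluster distance
# is the unweighted mean over all cross pairs.  Returns merge heights and
# final cluster compositions for comparison with hclust.
naive_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 1, 2)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dist_ij < best[1]) best <- c(dist_ij, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Small deterministic expression fixture with planted structure used by
# several module-construction tests: one 20-gene x 6-ROI block at rho.
planted_spec <- function(seed, rho = 0.9, a = 0.05,
                         n_genes = 200, n_rois = 30) {
  synthetic_spec(n_genes, n_rois, n_rois,
    expr_blocks = list(list(genes = 1:20, rois = 1:6, rho = rho)),
    pval_blocks = list(list(genes = 1:20, qts = 1:6, a = a)),
    seed = seed)
}

# Jaccard index between two id sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Write a small long-format SNP TSV and return its path.
write_snp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  names(df) <- c("SNP", "CHR", "BP", "QT", "P")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
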