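#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts module pairs among the significant draws:
#' from a universe of `N` gene-QT pairs of which `m` belong to the module,
#' `n` are drawn (the significant pairs) and at least `k` hit the module:
#' `sum_{i >= k} C(m, i) C(N - m, n - i) / C(N, n)`.  Computed with
#' [stats::phyper()] (survival function), which is numerically stable.
#'
#' @param N universe size.
#' @param n number of significant pairs (draws).
#' @param m module pairs in the universe (marked items).
#' @param k observed significant module pairs; `0 <= k <= min(m, n)`.
#' @return upper-tail p-value in [0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3)  # 55/210
hypergeom_upper_tail <- function(N, n, m, k) {
  stopifnot(length(N) == 1, N >= 0, m >= 0, m <= N, n >= 0, n <= N,
            k >= 0, k <= pmin(m, n))
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Overlap of a GS-BC module with the gene x QT universe
#'
#' The testable block of a module is
#' `T = {(g, b) : g in G_d intersect G_k, b in B_d intersect B_k}` where
#' `G_d`/`B_d` are the GWAS universe axes and `G_k`/`B_k` the module
#' members; `m = |T|` and `k` is the number of significant pairs inside
#' `T`.  Modules with an empty intersection on either axis are untestable
#' (`m = 0`) and flagged.
#'
#' @param genes character vector of module gene ids (`G_k`).
#' @param rois character vector of module ROI/QT ids (`B_k`).
#' @param matrix a [gene_qt_matrix()].
#' @param sig a [significant_pairs()] object on the same universe.
#' @return list with `m`, `k`, `n_genes_overlap`, `n_qts_overlap`,
#'   `testable`.
#' @export
compute_overlap <- function(genes, rois, matrix, sig) {
  stopifnot(inherits(matrix, "gene_qt_matrix"),
            inherits(sig, "significant_pairs"),
            identical(dim(sig$sig), dim(matrix$p_values)))
  gi <- which(matrix$gene_ids %in% genes)
  bi <- which(matrix$qt_ids %in% rois)
  m <- length(gi) * length(bi)
  k <- if (m == 0) 0L else sum(sig$sig[gi, bi])
  list(m = m, k = as.integer(k),
       n_genes_overlap = length(gi), n_qts_overlap = length(bi),
       testable = m > 0)
}

# Precompute per-module universe indices once; reused heavily by the
# permutation evaluation.
module_overlap_index <- function(modules, matrix) {
  tab <- modules$modules
  list(
    gi = lapply(tab$gs_id, function(g)
      which(matrix$gene_ids %in% modules$gene_sets[[g]])),
    bi = lapply(tab$bc_id, function(b)
      which(matrix$qt_ids %in% modules$circuits[[b]])))
}

# Vectorized enrichment over precomputed indices and a logical sig matrix.
enrich_from_index <- function(idx, sigmat, N, alpha, n_tests = NULL) {
  m <- lengths(idx$gi) * lengths(idx$bi)
  k <- mapply(function(gi, bi)
    if (length(gi) && length(bi)) sum(sigmat[gi, bi]) else 0L,
    idx$gi, idx$bi)
  n <- sum(sigmat)
  testable <- m > 0
  p_raw <- rep(1, length(m))
  p_raw[testable] <- stats::phyper(k[testable] - 1, m[testable],
                                   N - m[testable], n, lower.tail = FALSE)
  if (is.null(n_tests)) n_tests <- sum(testable)
  p_corrected <- pmin(1, p_raw * max(n_tests, 1L))
  p_corrected[!testable] <- 1
  list(N = N, n = n, m = m, k = as.integer(k), testable = testable,
       p_raw = p_raw, p_corrected = p_corrected, n_tests = n_tests,
       significant = testable & (p_corrected < alpha))
}

#' Enrichment test of every module against the GWAS finding list
#'
#' Applies the hypergeometric upper-tail test to each module's block of
#' the gene x QT universe and Bonferroni-corrects over the testable
#' modules of the supplied set (`p_corrected = min(1, p_raw * n_tests)`).
#' Untestable modules (empty overlap) are excluded from `n_tests` and
#' reported with `p_raw = 1`, never significant.
#'
#' @param modules a `gsbc_modules` object (typically one strategy's
#'   selection from [select_top_fraction()]).
#' @param matrix a [gene_qt_matrix()].
#' @param sig a [significant_pairs()] object on the same universe.
#' @param alpha significance level for the corrected p (default 0.05).
#' @param correction multiple-testing correction; only `"bonferroni"`.
#' @param n_tests override for the correction count (e.g. the union count
#'   when correcting across strategy sets); default = number of testable
#'   modules in `modules`.
#' @return data.frame of class `igea_results` with one row per module:
#'   ids, overlap sizes, `N`, `n`, `m`, `k`, `p_raw`, `p_corrected`,
#'   `testable`, `significant`; attributes `n_tests` and `alpha`.
#' @export
enrich_all <- function(modules, matrix, sig, alpha = 0.05,
                       correction = "bonferroni", n_tests = NULL) {
  stopifnot(inherits(modules, "gsbc_modules"),
            identical(correction, "bonferroni"),
            alpha > 0, alpha <= 1)
  if (nrow(modules$modules) == 0) stop("empty module list")
  idx <- module_overlap_index(modules, matrix)
  e <- enrich_from_index(idx, sig$sig, matrix$universe_size, alpha, n_tests)
  out <- cbind(modules$modules[c("module_id", "gs_id", "bc_id",
                                 "n_genes", "n_rois")],
               data.frame(n_genes_overlap = lengths(idx$gi),
                          n_qts_overlap = lengths(idx$bi),
                          N = e$N, n = e$n, m = e$m, k = e$k,
                          p_raw = e$p_raw, p_corrected = e$p_corrected,
                          testable = e$testable, significant = e$significant))
  row.names(out) <- NULL
  attr(out, "n_tests") <- e$n_tests
  attr(out, "alpha") <- alpha
  class(out) <- c("igea_results", "data.frame")
  out
}
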