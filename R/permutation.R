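#' Permute a gene x QT p-value matrix
#'
#' The default (`mode = "rows"`) permutes the assignment of gene labels to
#' p-value rows: each gene keeps a complete row of p-values (preserving
#' the within-gene co-occurrence pattern across QTs) but the
#' gene-to-module correspondence is broken.  `mode = "columns"` instead
#' permutes each QT column independently, destroying within-gene structure
#' as well.  Both keep the multiset of p-values and the universe size.
#'
#' @param matrix a [gene_qt_matrix()].
#' @param seed optional integer seed; when supplied the permutation is
#'   reproducible and the caller's RNG state is restored afterwards.
#' @param mode `"rows"` (default) or `"columns"`.
#' @return a permuted [gene_qt_matrix()] with the same dimnames.
#' @export
permute_gwas <- function(matrix, seed = NULL, mode = c("rows", "columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "gene_qt_matrix"))
  p <- matrix$p_values
  with_seed(seed, {
    if (mode == "rows") {
      p <- p[sample(nrow(p)), , drop = FALSE]
      rownames(p) <- matrix$gene_ids
    } else {
      p <- apply(p, 2, sample)
      rownames(p) <- matrix$gene_ids
    }
  })
  gene_qt_matrix(p)
}

#' Proportion of significant modules in an enrichment result
#'
#' @param results an `igea_results` data.frame from [enrich_all()].
#' @return count of significant modules divided by count of testable
#'   modules.
#' @export
proportion_significant <- function(results) {
  stopifnot(inherits(results, "igea_results"))
  n_testable <- sum(results$testable)
  if (n_testable == 0) stop("zero testable modules")
  sum(results$significant) / n_testable
}

#' Permutation p-value for the observed proportion of significant modules
#'
#' Compares the observed proportion with the permutation distribution via
#' a Student-t upper tail with `n - 1` degrees of freedom:
#' `t = (prop_orig - mu_perm) / (sqrt(1 + 1/n) * sigma_perm)` where
#' `mu_perm` and `sigma_perm` are the sample mean and sample standard
#' deviation (divisor `n - 1`) of the permuted proportions.  One-sided:
#' large observed proportions give small p.
#'
#' @param prop_orig observed proportion of significant modules.
#' @param props_perm numeric vector of permuted proportions, length >= 2.
#' @return list with `t_stat` and `p_value`.
#' @export
#' @examples
#' permutation_pvalue(0.05, rep(c(0.01, 0.03), 25))  # n = 50
permutation_pvalue <- function(prop_orig, props_perm) {
  n <- length(props_perm)
  stopifnot(n >= 2, all(props_perm >= 0 & props_perm <= 1),
            prop_orig >= 0, prop_orig <= 1)
  mu <- mean(props_perm)
  sigma <- stats::sd(props_perm)
  if (sigma == 0) stop("degenerate permutation distribution (sigma = 0)")
  t_stat <- (prop_orig - mu) / (sqrt(1 + 1 / n) * sigma)
  list(t_stat = t_stat,
       p_value = stats::pt(t_stat, df = n - 1, lower.tail = FALSE))
}

#' Permutation evaluation of the IGEA result count
#'
#' Runs the full enrichment on the observed gene x QT matrix and on
#' `n_perm` permuted matrices, and tests whether the observed proportion
#' of significant modules exceeds the permutation distribution (see
#' [permutation_pvalue()]).
#'
#' @param modules a `gsbc_modules` object (one strategy's selected set).
#' @param matrix the observed [gene_qt_matrix()].
#' @param threshold gene-QT significance threshold (default 1e-5).
#' @param alpha module significance level after Bonferroni (default 0.05).
#' @param n_perm number of permutations (default 50).
#' @param seed optional integer seed (caller RNG state restored).
#' @param mode permutation mode, see [permute_gwas()].
#' @param n_tests optional Bonferroni count override, see [enrich_all()].
#' @return object of class `permutation_evaluation`: list with `n_perm`,
#'   `props_perm`, `prop_orig`, `mu_perm`, `sigma_perm`, `t_stat`,
#'   `p_value`.
#' @export
evaluate_permutation <- function(modules, matrix, threshold = 1e-5,
                                 alpha = 0.05, n_perm = 50, seed = NULL,
                                 mode = c("rows", "columns"),
                                 n_tests = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(modules, "gsbc_modules"),
            inherits(matrix, "gene_qt_matrix"), n_perm >= 2)
  sig <- significant_pairs(matrix, threshold)
  idx <- module_overlap_index(modules, matrix)
  N <- matrix$universe_size

  prop_of <- function(sigmat) {
    e <- enrich_from_index(idx, sigmat, N, alpha, n_tests)
    if (!any(e$testable)) stop("zero testable modules")
    sum(e$significant) / sum(e$testable)
  }
  prop_orig <- prop_of(sig$sig)
  props_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sp <- if (mode == "rows") sig$sig[sample(nrow(sig$sig)), , drop = FALSE]
          else apply(sig$sig, 2, sample)
    prop_of(sp)
  }, numeric(1)))

  pv <- permutation_pvalue(prop_orig, props_perm)
  structure(list(n_perm = n_perm, props_perm = props_perm,
                 prop_orig = prop_orig, mu_perm = mean(props_perm),
                 sigma_perm = stats::sd(props_perm),
                 t_stat = pv$t_stat, p_value = pv$p_value),
            class = "permutation_evaluation")
}

#' @export
print.permutation_evaluation <- function(x, ...) {
  cat("permutation_evaluation:", x$n_perm, "permutations\n",
      " prop_orig =", signif(x$prop_orig, 4),
      " mu_perm =", signif(x$mu_perm, 4),
      " sigma_perm =", signif(x$sigma_perm, 4), "\n",
      " t =", signif(x$t_stat, 5), " p =", signif(x$p_value, 5), "\n")
  invisible(x)
}
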