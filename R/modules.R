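#' Fisher z-transformation of a correlation coefficient
#'
#' `z(c) = arctanh(c) = 0.5 * log((1 + c) / (1 - c))`, the
#' variance-stabilizing transform of a Pearson correlation.  The transform
#' diverges at |c| = 1, so `c` is first clamped to
#' `[-1 + clamp, 1 - clamp]`; this keeps module scores finite and
#' order-preserving.
#'
#' @param c correlation value(s) in [-1, 1].
#' @param clamp clamping margin (default 1e-12).
#' @return Fisher z value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5493061...
fisher_z <- function(c, clamp = 1e-12) {
  if (any(abs(c) > 1 + 1e-8, na.rm = TRUE)) stop("|c| > 1")
  if (anyNA(c)) stop("NA correlation")
  atanh(clamp_correlation(c, clamp))
}

# Mean Fisher z over the upper triangle of a correlation matrix.
mean_fisher_z <- function(r, clamp = 1e-12) {
  mean(fisher_z(r[upper.tri(r)], clamp))
}

#' Gene-based average Fisher z of a module submatrix
#'
#' Mean of `z(corr)` over all n(n-1)/2 unordered pairs of gene rows of the
#' module submatrix, with correlations computed across the module's ROIs
#' only.
#'
#' @param x module submatrix (n genes x m ROIs), n >= 2, m >= 2.
#' @param clamp correlation clamp forwarded to [fisher_z()].
#' @return the gene-based co-expression score, finite.
#' @export
module_z_gene <- function(x, clamp = 1e-12) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) stop("module needs >= 2 genes")
  if (ncol(x) < 2) stop("module needs >= 2 ROIs")
  mean_fisher_z(cor_safe(t(x)), clamp)
}

#' ROI-based average Fisher z of a module submatrix
#'
#' Mean of `z(corr)` over all m(m-1)/2 unordered pairs of ROI columns,
#' with correlations computed across the module's genes only.
#'
#' @inheritParams module_z_gene
#' @return the ROI-based co-expression score, finite.
#' @export
module_z_roi <- function(x, clamp = 1e-12) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("module needs >= 2 ROIs")
  if (nrow(x) < 2) stop("module needs >= 2 genes")
  mean_fisher_z(cor_safe(x), clamp)
}

#' Combine gene sets and brain circuits into candidate GS-BC modules
#'
#' Forms the full Cartesian product of gene sets and circuits and scores
#' each module's co-expression both ways on its expression submatrix.
#'
#' @param gene_sets named list of gene-id vectors (see
#'   [filter_gene_clusters()]).
#' @param circuits named list of ROI-id vectors (see
#'   [filter_roi_clusters()]).
#' @param expr normalized gene x ROI expression matrix containing all
#'   member genes and ROIs.
#' @return object of class `gsbc_modules`: list with
#'   * `modules`: data.frame (`module_id`, `gs_id`, `bc_id`, `n_genes`,
#'     `n_rois`, `z_gene`, `z_roi`), one row per module,
#'   * `gene_sets`, `circuits`: the membership lists.
#' @export
combine_modules <- function(gene_sets, circuits, expr) {
  if (length(gene_sets) == 0) stop("no gene sets")
  if (length(circuits) == 0) stop("no circuits")
  stopifnot(is.matrix(expr))
  missing_g <- setdiff(unique(unlist(gene_sets)), rownames(expr))
  if (length(missing_g)) stop("gene(s) absent from expression: ", missing_g[1])
  missing_r <- setdiff(unique(unlist(circuits)), colnames(expr))
  if (length(missing_r)) stop("ROI(s) absent from expression: ", missing_r[1])

  grid <- expand.grid(bc_id = names(circuits), gs_id = names(gene_sets),
                      stringsAsFactors = FALSE)[, c("gs_id", "bc_id")]
  z <- t(mapply(function(gs, bc) {
    x <- expr[gene_sets[[gs]], circuits[[bc]], drop = FALSE]
    c(module_z_gene(x), module_z_roi(x))
  }, grid$gs_id, grid$bc_id))
  tab <- data.frame(module_id = make_ids("M", nrow(grid)),
                    gs_id = grid$gs_id, bc_id = grid$bc_id,
                    n_genes = lengths(gene_sets)[grid$gs_id],
                    n_rois = lengths(circuits)[grid$bc_id],
                    z_gene = z[, 1], z_roi = z[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(modules = tab, gene_sets = gene_sets, circuits = circuits),
            class = "gsbc_modules")
}

#' @export
print.gsbc_modules <- function(x, ...) {
  cat("gsbc_modules:", nrow(x$modules), "modules (",
      length(x$gene_sets), "gene sets x", length(x$circuits), "circuits )\n")
  invisible(x)
}

#' Number of modules
#' @param modules a `gsbc_modules` object.
#' @return integer count.
#' @export
n_modules <- function(modules) nrow(modules$modules)

# Deterministic top-ceil(fraction*M) module ids by one score.
top_ids_by <- function(tab, score, fraction) {
  keep <- ceiling(fraction * nrow(tab))
  ord <- order(-score, tab$module_id)
  tab$module_id[ord][seq_len(keep)]
}

#' Select the top co-expressed fraction of modules
#'
#' Ranks modules by the gene-based or ROI-based average Fisher z score
#' (descending) and keeps the top `ceiling(fraction * M)`; the
#' `gene_and_roi` strategy keeps the intersection of the two single-score
#' selections.  Ties at the selection boundary are broken by `module_id`
#' ascending so the selection is deterministic.
#'
#' @param modules a `gsbc_modules` object.
#' @param fraction fraction to keep, in (0, 1] (default 0.2).
#' @param strategy `"gene_based"`, `"roi_based"` or `"gene_and_roi"`.
#' @return a `gsbc_modules` object restricted to the selected modules
#'   (module order preserved); attributes `"strategy"` and `"fraction"`.
#' @export
select_top_fraction <- function(modules, fraction = 0.2,
                                strategy = c("gene_based", "roi_based",
                                             "gene_and_roi")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(modules, "gsbc_modules"), fraction > 0, fraction <= 1)
  tab <- modules$modules
  if (nrow(tab) == 0) stop("empty module list")
  ids <- switch(strategy,
    gene_based = top_ids_by(tab, tab$z_gene, fraction),
    roi_based = top_ids_by(tab, tab$z_roi, fraction),
    gene_and_roi = intersect(top_ids_by(tab, tab$z_gene, fraction),
                             top_ids_by(tab, tab$z_roi, fraction)))
  sub <- tab[tab$module_id %in% ids, , drop = FALSE]
  row.names(sub) <- NULL
  out <- structure(list(modules = sub,
                        gene_sets = modules$gene_sets[unique(sub$gs_id)],
                        circuits = modules$circuits[unique(sub$bc_id)]),
                   class = "gsbc_modules")
  attr(out, "strategy") <- strategy
  attr(out, "fraction") <- fraction
  out
}

#' Add per-strategy selection flags to the module table
#'
#' Convenience wrapper computing all three selections at once and adding
#' logical columns `sel_gene`, `sel_roi`, `sel_both` to `modules$modules`.
#'
#' @inheritParams select_top_fraction
#' @return the `gsbc_modules` object with flag columns added.
#' @export
annotate_selection <- function(modules, fraction = 0.2) {
  tab <- modules$modules
  g <- top_ids_by(tab, tab$z_gene, fraction)
  r <- top_ids_by(tab, tab$z_roi, fraction)
  modules$modules$sel_gene <- tab$module_id %in% g
  modules$modules$sel_roi <- tab$module_id %in% r
  modules$modules$sel_both <- tab$module_id %in% intersect(g, r)
  modules
}
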