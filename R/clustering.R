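#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Classic UPGMA (average linkage): the closest pair of clusters is merged
#' repeatedly, with inter-cluster distance the unweighted mean of all
#' cross-cluster pairwise dissimilarities and merge height equal to that
#' distance.  UPGMA heights are monotone non-decreasing; this is asserted
#' on every run.
#'
#' @param dist symmetric numeric matrix with zero diagonal and
#'   non-negative finite entries (labels in dimnames), or a [stats::dist]
#'   object.
#' @return an [stats::hclust] dendrogram.
#' @export
upgma_cluster <- function(dist) {
  if (!inherits(dist, "dist")) {
    stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
    if (anyNA(dist)) stop("NaN/NA in dissimilarity matrix")
    if (any(dist < 0)) stop("negative dissimilarity")
    if (max(abs(dist - t(dist))) > 1e-8) stop("dissimilarity matrix not symmetric")
    if (any(abs(diag(dist)) > 1e-12)) stop("dissimilarity diagonal must be 0")
    dist <- stats::as.dist(dist)
  }
  if (anyNA(dist)) stop("NaN/NA in dissimilarity matrix")
  hc <- stats::hclust(dist, method = "average")
  if (is.unsorted(hc$height + 1e-12 * cummax(abs(hc$height))))
    stop("UPGMA height inversion detected") # cannot happen for average linkage
  hc
}

#' Cut a dendrogram at half of its height
#'
#' The dendrogram height is its root (final) merge height; the cutoff is
#' half of that, and clusters are the maximal groups whose internal merges
#' all sit at heights less than or equal to the cutoff.
#'
#' @param dend an [stats::hclust] object (e.g. from [upgma_cluster()]).
#' @return list of character vectors of leaf labels, a partition of the
#'   leaves, ordered by first leaf appearance; attribute `"cutoff"` holds
#'   the cut height.
#' @export
cut_half_height <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  cutoff <- 0.5 * max(dend$height)
  grp <- stats::cutree(dend, h = cutoff)
  out <- split(names(grp), grp)           # cutree numbers groups by appearance
  names(out) <- NULL
  structure(out, cutoff = cutoff)
}

#' Filter clusters into gene sets by size
#'
#' Keeps clusters whose size lies in `[min_size, max_size]` (inclusive)
#' and assigns stable gene-set ids in input order.  The default 10-200
#' range is the conventional pathway-size constraint of gene-set
#' enrichment analyses.
#'
#' @param clusters list of character vectors (e.g. from
#'   [cut_half_height()]).
#' @param min_size,max_size inclusive size bounds (defaults 10 and 200).
#' @param prefix id prefix (default `"GS"`).
#' @return named list of gene sets (`GS01`, `GS02`, ...).
#' @export
filter_gene_clusters <- function(clusters, min_size = 10, max_size = 200,
                                 prefix = "GS") {
  stopifnot(min_size >= 2)
  kept <- clusters[lengths(clusters) >= min_size & lengths(clusters) <= max_size]
  names(kept) <- make_ids(prefix, length(kept))
  kept
}

#' Filter clusters into brain circuits by size
#'
#' A circuit needs at least 2 ROIs (the ROI-based co-expression score is
#' a pairwise average); no upper bound is imposed by default.
#'
#' @param clusters list of character vectors.
#' @param min_size,max_size inclusive size bounds (defaults 2 and Inf).
#' @param prefix id prefix (default `"BC"`).
#' @return named list of circuits (`BC01`, `BC02`, ...).
#' @export
filter_roi_clusters <- function(clusters, min_size = 2, max_size = Inf,
                                prefix = "BC") {
  stopifnot(min_size >= 2)
  kept <- clusters[lengths(clusters) >= min_size & lengths(clusters) <= max_size]
  names(kept) <- make_ids(prefix, length(kept))
  kept
}
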