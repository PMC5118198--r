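#' Aggregate and normalize a raw expression table
#'
#' Reproduces the standard atlas preprocessing chain: sample columns are
#' merged to ROI columns by the arithmetic mean, probe rows are merged to
#' gene rows by the arithmetic mean, and each ROI column is then
#' standardized to mean 0 and standard deviation 1 (population sd, divisor
#' n).  Constant columns cannot be standardized; they are set to all zeros
#' and flagged.
#'
#' @param samples numeric matrix, rows = probes (or genes), columns =
#'   samples (or ROIs), with dimnames.
#' @param sample_to_roi named character vector mapping sample column names
#'   to ROI ids, or NULL when columns already are ROIs.  Samples without a
#'   mapping are dropped with a message; ROIs that end up with zero mapped
#'   samples simply do not appear.
#' @param probe_to_gene named character vector mapping probe row names to
#'   gene ids, or NULL when rows already are genes.
#' @param normalize standardize ROI columns (default TRUE).
#' @return gene x ROI numeric matrix; attribute `"constant_cols"` lists
#'   flagged constant ROI columns.
#' @export
preprocess_expression <- function(samples, sample_to_roi = NULL,
                                  probe_to_gene = NULL, normalize = TRUE) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("expression values must be finite")
  x <- samples

  if (!is.null(sample_to_roi)) {
    roi <- unname(sample_to_roi[colnames(x)])
    unmapped <- is.na(roi)
    if (any(unmapped)) {
      igea_log(sum(unmapped), " sample column(s) without ROI mapping dropped")
      x <- x[, !unmapped, drop = FALSE]
      roi <- roi[!unmapped]
    }
    if (ncol(x) == 0) stop("no sample column has an ROI mapping")
    grp <- rowsum(t(x), group = roi)            # sums per ROI
    x <- t(grp / as.vector(table(roi)[rownames(grp)]))
  }

  if (!is.null(probe_to_gene)) {
    gene <- unname(probe_to_gene[rownames(x)])
    unmapped <- is.na(gene)
    if (any(unmapped)) {
      igea_log(sum(unmapped), " probe row(s) without gene mapping dropped")
      x <- x[!unmapped, , drop = FALSE]
      gene <- gene[!unmapped]
    }
    if (nrow(x) == 0) stop("no probe row has a gene mapping")
    grp <- rowsum(x, group = gene)
    x <- grp / as.vector(table(gene)[rownames(grp)])
  }

  constant <- character(0)
  if (normalize) {
    n <- nrow(x)
    mu <- colMeans(x)
    sd_pop <- sqrt(colMeans(x^2) - mu^2)
    constant <- colnames(x)[sd_pop < .Machine$double.eps^0.5 * (1 + abs(mu))]
    sd_safe <- ifelse(sd_pop > 0, sd_pop, 1)
    x <- sweep(sweep(x, 2, mu, "-"), 2, sd_safe, "/")
    if (length(constant)) {
      x[, constant] <- 0
      igea_log(length(constant), " constant ROI column(s) zeroed: ",
               paste(constant, collapse = ", "))
    }
  }
  structure(x, constant_cols = constant)
}

# Pearson correlation with the package's zero-variance convention:
# undefined correlations are set to 0 (dissimilarity 1/2) with a warning.
cor_safe <- function(x) {
  r <- suppressWarnings(stats::cor(x))
  if (anyNA(r)) {
    warning("zero-variance vector(s): correlation set to 0")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  r
}

#' Correlation-based dissimilarity between two expression profiles
#'
#' `d = (1 - corr(a, b)) / 2`, mapping perfect correlation to 0 and
#' perfect anti-correlation to 1.  If either profile has zero variance the
#' correlation is taken as 0 (d = 1/2) with a warning.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return dissimilarity in [0, 1].
#' @export
#' @examples
#' gene_dissimilarity(c(1, 2, 3), c(1, 3, 2))  # 0.25
gene_dissimilarity <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  r <- cor_safe(cbind(a, b))[1, 2]
  (1 - r) / 2
}

#' @rdname gene_dissimilarity
#' @export
roi_dissimilarity <- function(a, b) gene_dissimilarity(a, b)

#' Pairwise gene (row) dissimilarity matrix
#'
#' @param expr gene x ROI numeric matrix.
#' @return symmetric matrix of `(1 - Pearson)/2` dissimilarities between
#'   rows, zero diagonal.
#' @export
gene_distance_matrix <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  d <- (1 - cor_safe(t(expr))) / 2
  diag(d) <- 0
  d
}

#' Pairwise ROI (column) dissimilarity matrix
#'
#' @param expr gene x ROI numeric matrix.
#' @return symmetric matrix of `(1 - Pearson)/2` dissimilarities between
#'   columns, zero diagonal.
#' @export
roi_distance_matrix <- function(expr) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  d <- (1 - cor_safe(expr)) / 2
  diag(d) <- 0
  d
}
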