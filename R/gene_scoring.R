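#' Construct a gene x QT p-value matrix object
#'
#' The gene x QT matrix is the finding universe of the two-dimensional
#' enrichment test: `N = N_G x N_B` gene-QT pairs, each carrying the
#' gene-level GWAS p-value for that QT.
#'
#' @param p numeric matrix in (0, 1], rows = genes, columns = QTs, with
#'   duplicate-free dimnames.
#' @return object of class `gene_qt_matrix`: a list with `p_values`,
#'   `gene_ids`, `qt_ids`, `n_genes`, `n_qts` and `universe_size`.
#' @export
#' @examples
#' gqm <- gene_qt_matrix(matrix(runif(6), 2, 3,
#'   dimnames = list(c("g1", "g2"), c("b1", "b2", "b3"))))
#' gqm$universe_size  # 6
gene_qt_matrix <- function(p) {
  stopifnot(is.matrix(p), is.numeric(p))
  if (is.null(rownames(p)) || is.null(colnames(p)))
    stop("gene_qt_matrix needs gene and QT dimnames")
  if (anyDuplicated(rownames(p))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(p))) stop("duplicate QT ids")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  structure(list(p_values = p,
                 gene_ids = rownames(p),
                 qt_ids = colnames(p),
                 n_genes = nrow(p),
                 n_qts = ncol(p),
                 universe_size = nrow(p) * ncol(p)),
            class = "gene_qt_matrix")
}

#' @export
print.gene_qt_matrix <- function(x, ...) {
  cat("gene_qt_matrix:", x$n_genes, "genes x", x$n_qts, "QTs (",
      format(x$universe_size, big.mark = ","), "gene-QT pairs )\n")
  invisible(x)
}

#' Map SNP-level GWAS p-values to gene-level p-values
#'
#' For each gene and QT, the gene-level p-value is the smallest p-value of
#' all SNPs located within `window_bp` base pairs of the gene body (closed
#' interval `[max(1, start - window_bp), end + window_bp]`, strand
#' ignored).  Genes with no in-window SNP for a given QT receive a filler
#' p of 1 for that QT (keeping the universe rectangular); genes with no
#' in-window SNP for any QT are dropped, as are QTs with no SNP records.
#'
#' Chromosome labels are compared after [normalize_chrom()].
#'
#' @param snps data.frame from [read_snp_associations()].
#' @param genes data.frame from [read_gene_annotation()].
#' @param window_bp non-negative flank size in bp (default 20000).
#' @return a [gene_qt_matrix()] over the retained genes and QTs.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 20000) {
  stopifnot(window_bp >= 0, nrow(snps) >= 1, nrow(genes) >= 1)
  qt_ids <- sort(unique(snps$qt_id))

  loci <- unique(snps[c("snp_id", "chrom", "pos")])
  if (anyDuplicated(loci$snp_id))
    stop("SNP id maps to more than one position: ",
         loci$snp_id[duplicated(loci$snp_id)][1])
  snp_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(loci$chrom),
    ranges = IRanges::IRanges(start = loci$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(genes$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - window_bp),
                              end = genes$end + window_bp))
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(gene_gr, snp_gr),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(hits) == 0) stop("no gene received any SNP")

  map <- data.table::data.table(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    snp_id = loci$snp_id[S4Vectors::subjectHits(hits)])
  long <- data.table::as.data.table(snps[c("snp_id", "qt_id", "p_value")])
  joined <- merge(map, long, by = "snp_id", allow.cartesian = TRUE)
  if (nrow(joined) == 0) stop("no gene received any SNP")
  p_value <- NULL # appease R CMD check
  best <- joined[, list(p = min(p_value)), by = c("gene_id", "qt_id")]

  kept_genes <- genes$gene_id[genes$gene_id %in% best$gene_id]
  n_drop <- nrow(genes) - length(kept_genes)
  if (n_drop > 0)
    igea_log(n_drop, " gene(s) without any in-window SNP dropped")
  m <- matrix(1, nrow = length(kept_genes), ncol = length(qt_ids),
              dimnames = list(kept_genes, qt_ids))
  m[cbind(match(best$gene_id, kept_genes), match(best$qt_id, qt_ids))] <- best$p
  gene_qt_matrix(m)
}

#' Threshold the gene x QT matrix into the significant pair set
#'
#' A gene-QT pair is significant when its p-value is strictly below
#' `threshold`.
#'
#' @param matrix a [gene_qt_matrix()].
#' @param threshold significance threshold in (0, 1] (default 1e-5).
#' @return object of class `significant_pairs`: list with `threshold`,
#'   `pairs` (data.frame of gene_id/qt_id), `n` (the count) and `sig`
#'   (a logical gene x QT indicator matrix).
#' @export
significant_pairs <- function(matrix, threshold = 1e-5) {
  stopifnot(inherits(matrix, "gene_qt_matrix"),
            threshold > 0, threshold <= 1)
  sig <- matrix$p_values < threshold
  idx <- which(sig, arr.ind = TRUE)
  pairs <- data.frame(gene_id = matrix$gene_ids[idx[, 1]],
                      qt_id = matrix$qt_ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  structure(list(threshold = threshold, pairs = pairs,
                 n = nrow(pairs), sig = sig),
            class = "significant_pairs")
}

#' @export
print.significant_pairs <- function(x, ...) {
  cat("significant_pairs:", x$n, "gene-QT pairs with p <", x$threshold, "\n")
  invisible(x)
}
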