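#' Specification of a synthetic imaging-genetics test bed
#'
#' Describes the seeded synthetic inputs used to exercise the pipeline
#' without restricted imaging-genetics data: a gene x ROI expression
#' matrix with planted co-expression blocks, and a gene x QT p-value
#' matrix with planted blocks of enriched (stochastically small)
#' p-values.  QTs are labelled one-to-one with ROIs by default, mirroring
#' the design where each imaging QT is a per-ROI measurement.
#'
#' @param n_genes,n_rois,n_qts dimensions; `n_qts` defaults to `n_rois`
#'   (QT ids then equal ROI ids).
#' @param expr_blocks list of planted co-expression blocks, each a list
#'   with integer index vectors `genes` and `rois` and a correlation
#'   target `rho` in (0, 1).  Blocks must be disjoint on both axes.
#' @param pval_blocks list of planted enrichment blocks, each a list with
#'   integer index vectors `genes` and `qts` and a Beta shape `a` in
#'   (0, 1]; block p-values are drawn Beta(a, 1) (`a = 1` is uniform,
#'   smaller `a` is stronger signal).
#' @param seed integer seed; every `simulate_*` call is deterministic
#'   given the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, n_rois, n_qts = n_rois,
                           expr_blocks = list(), pval_blocks = list(),
                           seed = 1) {
  stopifnot(n_genes >= 2, n_rois >= 2, n_qts >= 1)
  for (b in expr_blocks) {
    stopifnot(all(b$genes >= 1 & b$genes <= n_genes),
              all(b$rois >= 1 & b$rois <= n_rois),
              length(b$rho) == 1, b$rho > 0, b$rho < 1)
  }
  if (length(expr_blocks) > 1) {
    g <- unlist(lapply(expr_blocks, `[[`, "genes"))
    r <- unlist(lapply(expr_blocks, `[[`, "rois"))
    if (anyDuplicated(g) || anyDuplicated(r))
      stop("planted expression blocks overlap")
  }
  for (b in pval_blocks) {
    stopifnot(all(b$genes >= 1 & b$genes <= n_genes),
              all(b$qts >= 1 & b$qts <= n_qts),
              length(b$a) == 1, b$a > 0, b$a <= 1)
  }
  gene_ids <- make_ids("G", n_genes)
  roi_ids <- make_ids("R", n_rois)
  qt_ids <- if (n_qts == n_rois) roi_ids else make_ids("Q", n_qts)
  structure(list(n_genes = n_genes, n_rois = n_rois, n_qts = n_qts,
                 expr_blocks = expr_blocks, pval_blocks = pval_blocks,
                 seed = seed, gene_ids = gene_ids, roi_ids = roi_ids,
                 qt_ids = qt_ids),
            class = "synthetic_spec")
}

#' Simulate a gene x ROI expression matrix with planted blocks
#'
#' Background entries are i.i.d. standard normal.  Each planted block is
#' generated by a two-sided latent-factor model: the block's genes share a
#' latent expression profile `f` over all ROIs with loading `sqrt(rho)`,
#' and the block's ROIs share a latent profile `u` over all genes with
#' loading `sqrt(rho)`; the residual standard deviation is reduced
#' accordingly (floored at `sqrt(0.05)` inside the gene x ROI overlap).
#' Consequences: within the block, gene-gene correlations across the
#' block's ROIs and ROI-ROI correlations across the block's genes are both
#' approximately `rho`, and both full-axis dendrograms can recover the
#' planted gene set and circuit.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` (gene x ROI matrix, dimnames from the
#'   spec) and `truth` (planted memberships as id vectors).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    nG <- spec$n_genes; nR <- spec$n_rois
    sigma2 <- matrix(1, nG, nR)
    signal <- matrix(0, nG, nR)
    for (b in spec$expr_blocks) {
      f <- rnorm(nR)   # gene-side factor: profile over all ROIs
      u <- rnorm(nG)   # ROI-side factor: profile over all genes
      signal[b$genes, ] <- signal[b$genes, ] +
        sqrt(b$rho) * matrix(f, length(b$genes), nR, byrow = TRUE)
      signal[, b$rois] <- signal[, b$rois] +
        sqrt(b$rho) * matrix(u, nG, length(b$rois))
      sigma2[b$genes, ] <- sigma2[b$genes, ] - b$rho
      sigma2[, b$rois] <- sigma2[, b$rois] - b$rho
    }
    sigma2 <- pmax(sigma2, 0.05)
    e <- signal + sqrt(sigma2) * matrix(rnorm(nG * nR), nG, nR)
    dimnames(e) <- list(spec$gene_ids, spec$roi_ids)
    truth <- lapply(spec$expr_blocks, function(b)
      list(genes = spec$gene_ids[b$genes], rois = spec$roi_ids[b$rois],
           rho = b$rho))
    list(expression = e, truth = truth)
  })
}

#' Simulate a gene x QT p-value matrix with planted enriched blocks
#'
#' Background p-values are i.i.d. Uniform(0, 1); entries inside each
#' planted block are drawn Beta(a, 1) with `a <= 1`, i.e. stochastically
#' small (the significance rate at threshold `t` is `t^a`).
#'
#' @param spec a [synthetic_spec()].
#' @return a [gene_qt_matrix()]; attribute `"truth"` holds the planted
#'   block memberships as id vectors.
#' @export
simulate_gene_qt_pvalues <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    p <- matrix(runif(spec$n_genes * spec$n_qts), spec$n_genes, spec$n_qts,
                dimnames = list(spec$gene_ids, spec$qt_ids))
    for (b in spec$pval_blocks)
      p[b$genes, b$qts] <- rbeta(length(b$genes) * length(b$qts), b$a, 1)
    p <- pmax(p, .Machine$double.xmin)  # keep strictly in (0, 1]
    out <- gene_qt_matrix(p)
    attr(out, "truth") <- lapply(spec$pval_blocks, function(b)
      list(genes = spec$gene_ids[b$genes], qts = spec$qt_ids[b$qts], a = b$a))
    out
  })
}

#' Simulate SNP-level associations consistent with a gene-level target
#'
#' Lays the spec's genes on one synthetic chromosome (gene `i` spans
#' `[(i-1)*1e5 + 1, (i-1)*1e5 + 1e4]`, so +/- 20 kb windows never touch),
#' draws 1-10 SNPs inside each gene's window plus one decoy SNP exactly
#' one bp outside it, and assigns per-SNP p-values so that the minimum
#' over a gene's in-window SNPs equals the gene-level target from
#' [simulate_gene_qt_pvalues()] for every QT.
#'
#' @param spec a [synthetic_spec()].
#' @param window_bp the mapping window the decoys sit just outside
#'   (default 20000).
#' @return list with `snps` (long association data.frame), `genes`
#'   (annotation data.frame) and `target` (the gene x QT matrix whose
#'   values [map_snps_to_genes()] should reproduce).
#' @export
simulate_snp_level <- function(spec, window_bp = 20000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  target <- simulate_gene_qt_pvalues(spec)
  with_seed(spec$seed + 2L, {
    nG <- spec$n_genes
    start <- (seq_len(nG) - 1L) * 100000L + 1L
    end <- start + 9999L
    genes <- data.frame(gene_id = spec$gene_ids, chrom = "1",
                        start = start, end = end, stringsAsFactors = FALSE)
    snps <- vector("list", nG)
    for (i in seq_len(nG)) {
      n_in <- sample(1:10, 1)
      lo <- max(1L, start[i] - window_bp)
      pos <- sample(seq(lo, end[i] + window_bp), n_in)
      pos <- c(pos, end[i] + window_bp + 1L)   # decoy just outside
      ids <- paste0("rs", i, "_", seq_along(pos))
      tgt <- target$p_values[i, ]
      pv <- matrix(runif(length(pos) * spec$n_qts), length(pos))
      pv <- tgt[col(pv)] + pv * (1 - tgt[col(pv)])  # >= target everywhere
      carrier <- sample(n_in, 1)
      pv[carrier, ] <- tgt                          # min over in-window = target
      pv[length(pos), ] <- runif(spec$n_qts)        # decoy: unconstrained
      snps[[i]] <- data.frame(
        snp_id = rep(ids, times = spec$n_qts),
        chrom = "1",
        pos = rep(pos, times = spec$n_qts),
        qt_id = rep(spec$qt_ids, each = length(pos)),
        p_value = as.vector(pv), stringsAsFactors = FALSE)
    }
    list(snps = do.call(rbind, snps), genes = genes, target = target)
  })
}
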