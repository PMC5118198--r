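#' Read SNP-level GWAS association records
#'
#' Parses SNP-level summary statistics for one or many quantitative traits
#' (QTs) into the long record format used throughout the package.  Two
#' dialects are supported: a single long-format TSV with header columns
#' `SNP, CHR, BP, QT, P`, and a set of per-QT whitespace-delimited files in
#' the style of PLINK `--assoc`/`--linear` output (header must contain
#' `SNP`, `CHR`, `BP` and `P`; the QT id is the file name stem).
#'
#' Rows whose p-value field is missing (`NA`, `NaN` or empty) are skipped;
#' the number of skipped rows is reported via a message and stored in the
#' `"skipped"` attribute.  Any other malformed field is an error naming the
#' offending line.
#'
#' @param path file path (long dialect) or character vector of file paths
#'   (per-QT dialect).
#' @param dialect `"long_tsv"` or `"per_qt_qassoc"`.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `qt_id`,
#'   `p_value`, one row per (SNP, QT) record; attribute `"skipped"` holds
#'   the count of rows dropped for missing p.
#' @export
read_snp_associations <- function(path, dialect = c("long_tsv", "per_qt_qassoc")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    stopifnot(length(path) == 1L)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
    need <- c("SNP", "CHR", "BP", "QT", "P")
    if (!all(need %in% names(raw)))
      stop("long_tsv header must contain columns ", paste(need, collapse = ", "))
    out <- parse_snp_rows(raw$SNP, raw$CHR, raw$BP, raw$QT, raw$P, path)
  } else {
    pieces <- lapply(path, function(f) {
      if (!file.exists(f)) stop("file not found: ", f)
      raw <- utils::read.table(f, header = TRUE, colClasses = "character",
                               check.names = FALSE)
      need <- c("SNP", "CHR", "BP", "P")
      if (!all(need %in% names(raw)))
        stop("per-QT file ", f, " header must contain columns ",
             paste(need, collapse = ", "))
      qt <- sub("\\.[^.]*$", "", basename(f))
      parse_snp_rows(raw$SNP, raw$CHR, raw$BP, rep(qt, nrow(raw)), raw$P, f)
    })
    out <- do.call(rbind, pieces)
    attr(out, "skipped") <- sum(vapply(pieces, attr, 0L, "skipped"))
  }
  dup <- duplicated(out[c("snp_id", "qt_id")])
  if (any(dup))
    stop("duplicate (SNP, QT) records, e.g. ",
         out$snp_id[dup][1], " / ", out$qt_id[dup][1])
  out
}

# Shared row validator for both SNP dialects; keeps 1-based file line numbers
# (header = line 1) in error messages.
parse_snp_rows <- function(snp, chrom, bp, qt, p, path) {
  line <- seq_along(snp) + 1L
  missing_p <- is.na(p) | p %in% c("NA", "NaN", "nan", "")
  n_skip <- sum(missing_p)
  if (n_skip > 0) igea_log(n_skip, " row(s) with missing p skipped in ", path)
  keep <- !missing_p
  pos <- suppressWarnings(as.numeric(bp[keep]))
  pval <- suppressWarnings(as.numeric(p[keep]))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad))
    stop("malformed BP field at line ", line[keep][bad[1]], " of ", path)
  badp <- which(is.na(pval))
  if (length(badp))
    stop("malformed P field at line ", line[keep][badp[1]], " of ", path)
  oob <- which(pval <= 0 | pval > 1 | pos < 1)
  if (length(oob))
    stop("p-value outside (0, 1] or position < 1 at line ",
         line[keep][oob[1]], " of ", path)
  out <- data.frame(snp_id = snp[keep], chrom = as.character(chrom[keep]),
                    pos = as.integer(pos), qt_id = qt[keep], p_value = pval,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- n_skip
  out
}

#' Read gene annotation
#'
#' Reads a 4-column gene annotation in either BED (0-based half-open,
#' headerless, columns chrom/start/end/name) or 1-based TSV dialect
#' (header `GENE, CHR, START, END`, both ends inclusive).  BED intervals
#' are converted to the internal 1-based inclusive convention
#' (`start + 1`, `end`), so interval lengths are preserved.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv_1based"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotation <- function(path, format = c("bed", "tsv_1based")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("feature", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    need <- c("GENE", "CHR", "START", "END")
    if (!all(need %in% names(raw)))
      stop("tsv_1based header must contain columns ",
           paste(need, collapse = ", "))
    out <- data.frame(gene_id = raw$GENE, chrom = as.character(raw$CHR),
                      start = as.integer(raw$START), end = as.integer(raw$END),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-integer coordinates in ", path)
  if (any(out$start > out$end))
    stop("gene interval with start > end after conversion: ",
         out$gene_id[which(out$start > out$end)[1]])
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation: ",
         out$gene_id[duplicated(out$gene_id)][1])
  out
}

#' Read an expression matrix from TSV
#'
#' First column = row labels (probes or genes), header = column labels
#' (samples or ROIs), cells numeric.
#'
#' @param path file path.
#' @param row_kind `"gene"` or `"probe"`; duplicate row labels are an error
#'   for genes and allowed for probes (they are merged later).
#' @param col_kind `"roi"` or `"sample"` (annotation only).
#' @return numeric matrix with dimnames, attributes `row_kind`/`col_kind`.
#' @export
read_expression_matrix <- function(path, row_kind = c("gene", "probe"),
                                   col_kind = c("roi", "sample")) {
  row_kind <- match.arg(row_kind)
  col_kind <- match.arg(col_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) stop("expression TSV needs row labels plus >= 1 column")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row '", ids[bad[1]],
         "', column '", colnames(vals)[bad[2]], "'")
  }
  if (row_kind == "gene" && anyDuplicated(ids))
    stop("duplicate gene row id: ", ids[duplicated(ids)][1])
  dimnames(num) <- list(ids, colnames(vals))
  structure(num, row_kind = row_kind, col_kind = col_kind)
}

#' Write a labelled numeric matrix as TSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces doubles exactly.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param id_col header label for the row-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_col = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  df <- data.frame(rownames(x), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x QT p-value matrix written by [write_gene_qt_matrix()]
#'
#' @param path TSV path (rows = genes, columns = QTs).
#' @return a [gene_qt_matrix()] object.
#' @export
read_gene_qt_matrix <- function(path) {
  m <- read_expression_matrix(path, row_kind = "gene", col_kind = "roi")
  attr(m, "row_kind") <- NULL
  attr(m, "col_kind") <- NULL
  gene_qt_matrix(m)
}

#' Write a gene x QT p-value matrix as TSV
#'
#' @param gqm a [gene_qt_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_qt_matrix <- function(gqm, path) {
  stopifnot(inherits(gqm, "gene_qt_matrix"))
  write_expression_matrix(gqm$p_values, path, id_col = "gene")
}

#' Write GS-BC modules as TSV tables
#'
#' Writes `<prefix>_modules.tsv` (one row per module: ids, sizes, z scores
#' and, when present, selection flags), `<prefix>_gene_sets.tsv`
#' (gs_id/gene pairs) and `<prefix>_circuits.tsv` (bc_id/roi pairs).
#'
#' @param modules a `gsbc_modules` object (see [combine_modules()]).
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
write_modules <- function(modules, prefix) {
  stopifnot(inherits(modules, "gsbc_modules"))
  f1 <- paste0(prefix, "_modules.tsv")
  f2 <- paste0(prefix, "_gene_sets.tsv")
  f3 <- paste0(prefix, "_circuits.tsv")
  utils::write.table(modules$modules, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gs <- data.frame(
    gs_id = rep(names(modules$gene_sets), lengths(modules$gene_sets)),
    gene_id = unlist(modules$gene_sets, use.names = FALSE))
  bc <- data.frame(
    bc_id = rep(names(modules$circuits), lengths(modules$circuits)),
    roi_id = unlist(modules$circuits, use.names = FALSE))
  utils::write.table(gs, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bc, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
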