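#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix (any case) and case-folds, so annotation in
#' "chr1" dialect matches summary statistics in "1" dialect.
#'
#' @param x character vector of chromosome labels.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "ChrX", "x"))
normalize_chrom <- function(x) {
  tolower(sub("^chr", "", as.character(x), ignore.case = TRUE))
}

# data.table is used via :: qualification.
.datatable.aware <- TRUE

# Clamp correlations away from +/-1 before the Fisher transform.
clamp_correlation <- function(c, margin = 1e-12) {
  pmin(pmax(c, -1 + margin), 1 - margin)
}

# message() wrapper honouring options(igea.verbose = FALSE)
igea_log <- function(...) {
  if (isTRUE(getOption("igea.verbose", TRUE))) message("igea: ", ...)
  invisible(NULL)
}

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable zero-padded id sequences: "GS01", "M0007", ...
make_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"), seq_len(n))
}
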