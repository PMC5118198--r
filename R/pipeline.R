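#' Assemble a pipeline configuration
#'
#' Collects inputs and tuning parameters for [run_igea()].  Inputs may be
#' in-memory objects or file paths (paths are read with the package's
#' readers).  Either `gene_qt` or both `snps` and `genes` must be given.
#'
#' @param expr gene x ROI expression matrix (already preprocessed /
#'   normalized), or a TSV path.
#' @param gene_qt a [gene_qt_matrix()] or TSV path; alternative to
#'   SNP-level input.
#' @param snps SNP association data.frame or long-TSV path.
#' @param genes gene annotation data.frame or TSV path (1-based dialect).
#' @param window_bp SNP-to-gene mapping window (default 20000).
#' @param threshold gene-QT significance threshold (default 1e-5).
#' @param min_gs,max_gs gene-set size bounds (defaults 10, 200).
#' @param min_bc circuit minimum size (default 2).
#' @param top_fraction selection fraction (default 0.2).
#' @param strategies selection strategies to evaluate.
#' @param alpha module significance level (default 0.05).
#' @param correction_scope `"strategy"` (Bonferroni within each selected
#'   set, the default) or `"union"` (correct by the number of testable
#'   modules in the union of the selected sets).
#' @param n_perm permutations for the evaluation stage (default 50);
#'   set `do_permutation = FALSE` to skip.
#' @param do_permutation run the permutation evaluation (default TRUE).
#' @param seed integer seed for the permutation stage.
#' @param out_dir optional directory for checkpoint TSVs and the JSON
#'   report.
#' @return list of class `igea_config`.
#' @export
igea_config <- function(expr, gene_qt = NULL, snps = NULL, genes = NULL,
                        window_bp = 20000, threshold = 1e-5,
                        min_gs = 10, max_gs = 200, min_bc = 2,
                        top_fraction = 0.2,
                        strategies = c("gene_based", "roi_based",
                                       "gene_and_roi"),
                        alpha = 0.05,
                        correction_scope = c("strategy", "union"),
                        n_perm = 50, do_permutation = TRUE, seed = 17,
                        out_dir = NULL) {
  correction_scope <- match.arg(correction_scope)
  strategies <- match.arg(strategies, several.ok = TRUE)
  stopifnot(window_bp >= 0, threshold > 0, threshold <= 1,
            min_gs >= 2, max_gs >= min_gs, min_bc >= 2,
            top_fraction > 0, top_fraction <= 1,
            alpha > 0, alpha <= 1, n_perm >= 2)
  if (is.null(gene_qt) && (is.null(snps) || is.null(genes)))
    stop("provide either gene_qt or both snps and genes")
  structure(list(expr = expr, gene_qt = gene_qt, snps = snps, genes = genes,
                 window_bp = window_bp, threshold = threshold,
                 min_gs = min_gs, max_gs = max_gs, min_bc = min_bc,
                 top_fraction = top_fraction, strategies = strategies,
                 alpha = alpha, correction_scope = correction_scope,
                 n_perm = n_perm, do_permutation = do_permutation,
                 seed = seed, out_dir = out_dir),
            class = "igea_config")
}

# Wrap a stage so failures name the stage.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x)
  } else x
}

#' Run the full IGEA pipeline
#'
#' Executes gene scoring, module construction, enrichment and (optionally)
#' the permutation evaluation from one [igea_config()], writing checkpoint
#' TSVs and a JSON report when `out_dir` is set.
#'
#' @param config an [igea_config()].
#' @return list of class `igea_run` with `report` (all counts: universe
#'   axes and size, significant pair count, cluster counts before/after
#'   size filtering, module count, per-strategy selected / testable /
#'   significant counts and permutation statistics) plus the stage objects
#'   (`gene_qt`, `sig`, `modules`, `selection`, `enrichment`,
#'   `permutation`).
#' @export
run_igea <- function(config) {
  stopifnot(inherits(config, "igea_config"))

  ## ---- gene scoring -------------------------------------------------
  gqm <- run_stage("gene_scoring", {
    if (!is.null(config$gene_qt)) {
      resolve_input(config$gene_qt, read_gene_qt_matrix)
    } else {
      snps <- resolve_input(config$snps, read_snp_associations)
      genes <- resolve_input(config$genes,
                             function(p) read_gene_annotation(p, "tsv_1based"))
      map_snps_to_genes(snps, genes, config$window_bp)
    }
  })
  sig <- run_stage("gene_scoring", significant_pairs(gqm, config$threshold))

  ## ---- module construction ------------------------------------------
  expr <- run_stage("module_construction",
                    resolve_input(config$expr, read_expression_matrix))
  mods <- run_stage("module_construction", {
    gene_clusters <- cut_half_height(upgma_cluster(gene_distance_matrix(expr)))
    roi_clusters <- cut_half_height(upgma_cluster(roi_distance_matrix(expr)))
    gene_sets <- filter_gene_clusters(gene_clusters, config$min_gs,
                                      config$max_gs)
    circuits <- filter_roi_clusters(roi_clusters, config$min_bc)
    counts <- list(gene_clusters = length(gene_clusters),
                   gene_sets = length(gene_sets),
                   roi_clusters = length(roi_clusters),
                   circuits = length(circuits))
    if (length(gene_sets) == 0 || length(circuits) == 0) {
      igea_log("no gene set or no circuit survived filtering; ",
               "no candidate modules")
      list(modules = NULL, counts = counts)
    } else {
      list(modules = annotate_selection(
             combine_modules(gene_sets, circuits, expr),
             config$top_fraction),
           counts = counts)
    }
  })
  counts <- mods$counts
  modules <- mods$modules

  selection <- list(); enrichment <- list(); permutation <- list()
  if (!is.null(modules)) {
    for (s in config$strategies)
      selection[[s]] <- run_stage("module_construction",
        select_top_fraction(modules, config$top_fraction, s))

    ## ---- enrichment --------------------------------------------------
    n_tests_override <- NULL
    if (config$correction_scope == "union") {
      union_ids <- unique(unlist(lapply(selection, function(m)
        m$modules$module_id)))
      sub <- modules$modules[modules$modules$module_id %in% union_ids, ]
      testable <- vapply(seq_len(nrow(sub)), function(i) {
        compute_overlap(modules$gene_sets[[sub$gs_id[i]]],
                        modules$circuits[[sub$bc_id[i]]], gqm, sig)$testable
      }, logical(1))
      n_tests_override <- sum(testable)
    }
    for (s in config$strategies) {
      enrichment[[s]] <- run_stage("igea_enrichment",
        if (nrow(selection[[s]]$modules) > 0)
          enrich_all(selection[[s]], gqm, sig, config$alpha,
                     n_tests = n_tests_override)
        else NULL)
    }

    ## ---- permutation evaluation -------------------------------------
    if (config$do_permutation) {
      for (s in config$strategies) {
        permutation[[s]] <- run_stage("permutation_evaluation",
          if (!is.null(enrichment[[s]]) && any(enrichment[[s]]$testable))
            evaluate_permutation(selection[[s]], gqm, config$threshold,
                                 config$alpha, config$n_perm,
                                 seed = config$seed,
                                 n_tests = n_tests_override)
          else NULL)
      }
    }
  }

  report <- list(
    n_genes = gqm$n_genes, n_qts = gqm$n_qts,
    universe_size = gqm$universe_size,
    universe_consistent = gqm$universe_size == gqm$n_genes * gqm$n_qts,
    n_significant_pairs = sig$n, threshold = config$threshold,
    gene_clusters = counts$gene_clusters, gene_sets = counts$gene_sets,
    roi_clusters = counts$roi_clusters, circuits = counts$circuits,
    n_modules = if (is.null(modules)) 0L else n_modules(modules),
    selected = lapply(selection, function(m) nrow(m$modules)),
    significant_modules = lapply(enrichment, function(e)
      if (is.null(e)) 0L else sum(e$significant)),
    permutation_p = lapply(permutation, function(p)
      if (is.null(p)) NA_real_ else p$p_value),
    parameters = config[c("window_bp", "threshold", "min_gs", "max_gs",
                          "min_bc", "top_fraction", "alpha",
                          "correction_scope", "n_perm", "seed")])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_qt_matrix(gqm, file.path(config$out_dir, "gene_qt.tsv"))
    if (!is.null(modules))
      write_modules(modules, file.path(config$out_dir, "igea"))
    for (s in names(enrichment)) if (!is.null(enrichment[[s]]))
      utils::write.table(enrichment[[s]],
                         file.path(config$out_dir,
                                   paste0("enrichment_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(report = report, gene_qt = gqm, sig = sig,
                 modules = modules, selection = selection,
                 enrichment = enrichment, permutation = permutation),
            class = "igea_run")
}

#' @export
print.igea_run <- function(x, ...) {
  r <- x$report
  cat("igea_run:", r$n_genes, "genes x", r$n_qts, "QTs;",
      r$n_significant_pairs, "significant pairs at p <", r$threshold, "\n",
      r$n_modules, "candidate modules;",
      "selected:", paste(names(r$selected),
                         unlist(r$selected), collapse = ", "), "\n",
      "significant:", paste(names(r$significant_modules),
                            unlist(r$significant_modules), collapse = ", "),
      "\n")
  invisible(x)
}
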