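#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults encode the
#' workflow's standard settings: screening Bonferroni over the supplied
#' risk-locus count with FDR 0.20, a 1 Mb cis window, a 10 Mb trans
#' exclusion zone measured from the cis gene, expression PCs at the 1%
#' variance rule, OR-symmetrized neighborhood selection with StARS
#' (instability 0.1, 20 subsamples), and Bonferroni at alpha 0.05 for both
#' peak-cis and trio significance (denominators recomputed from the run).
#'
#' @param n_loci number of original risk loci for the screening Bonferroni;
#'   `NULL` (default) uses the number of variants in the input.
#' @param fdr_level screening FDR level.
#' @param cis_window,trans_exclusion distance rules in bp.
#' @param compute_pcs add expression PCs to the covariates. With desk-scale
#'   gene counts and observed confounders, set this to `FALSE` and supply
#'   the confounders as covariates (see [compute_expression_pcs()]).
#' @param pc_min_var minimum variance fraction for a PC to be kept.
#' @param max_pcs cap on the number of PCs added (default unlimited).
#' @param residualize_network residualize expression on the covariates
#'   before network estimation.
#' @param n_lambda,lambda_min_ratio,sym_rule,n_subsamples,subsample_ratio,instability_threshold
#'   network-stage parameters, see [neighborhood_selection_path()] and
#'   [select_graph()].
#' @param cis_alpha,trio_alpha Bonferroni family-wise levels.
#' @param B_cond4 component-4 permutations per trio.
#' @param B_perm outer permutations for the robustness test (0 = skip).
#' @param measure_trans_from `"cis_gene"` (default) or `"variant"`.
#' @param sensitivity_budget pair-count guard for [sensitivity_scan()].
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_loci = NULL, fdr_level = 0.2,
                            cis_window = 1e6, trans_exclusion = 1e7,
                            compute_pcs = TRUE, pc_min_var = 0.01,
                            max_pcs = Inf,
                            residualize_network = TRUE,
                            n_lambda = 10, lambda_min_ratio = 0.1,
                            sym_rule = "OR", n_subsamples = 20,
                            subsample_ratio = NULL,
                            instability_threshold = 0.1,
                            cis_alpha = 0.05, trio_alpha = 0.05,
                            B_cond4 = 1000, B_perm = 0,
                            measure_trans_from = c("cis_gene", "variant"),
                            sensitivity_budget = 200000, seed = 1L) {
  measure_trans_from <- match.arg(measure_trans_from)
  stopifnot(fdr_level > 0, fdr_level < 1, cis_window > 0,
            trans_exclusion > 0, pc_min_var >= 0, pc_min_var <= 1,
            cis_alpha > 0, cis_alpha < 1, trio_alpha > 0, trio_alpha < 1,
            instability_threshold > 0, B_cond4 >= 1, B_perm >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

.config_lines <- function(config) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "NULL" else paste(format(v), collapse = ","), "")
  paste0(names(config), ": ", vals)
}

#' Construct candidate cis-mediator trios from graph neighborhoods
#'
#' For every significant (variant, cis-gene) pair, the cis gene's graph
#' neighbors that are trans-eligible with respect to that pair become
#' candidate (L, C, T) trios. The list is deduplicated and ordered by
#' (variant, cis gene, trans gene). A cis gene absent from the graph
#' contributes no trios (recorded in the `log` attribute).
#'
#' @param cis_pairs data.frame with `variant_id`, `gene_id` (significant
#'   peak cis pairs, e.g. the significant rows of [peak_cis_selection()]).
#' @param graph a `coexpression_graph`.
#' @param genes gene annotation (`id`, `chrom`, `start`, `end`).
#' @param variants variant annotation (`id`, `chrom`, `pos`).
#' @param cis_window,trans_exclusion distance rules in bp.
#' @param measure_from `"cis_gene"` or `"variant"`.
#' @return data.frame with `variant_id`, `cis_gene`, `trans_gene`.
#' @export
build_trios <- function(cis_pairs, graph, genes, variants,
                        cis_window = 1e6, trans_exclusion = 1e7,
                        measure_from = c("cis_gene", "variant")) {
  measure_from <- match.arg(measure_from)
  out <- list()
  log <- character(0)
  for (r in seq_len(NROW(cis_pairs))) {
    vid <- cis_pairs$variant_id[r]
    cg <- cis_pairs$gene_id[r]
    if (!cg %in% graph$nodes) {
      log <- c(log, paste0("cis gene ", cg, " absent from graph"))
      next
    }
    nb <- neighbors(graph, cg)
    if (!length(nb)) next
    vrow <- variants[variants$id == vid, ]
    crow <- genes[genes$id == cg, ]
    for (tg in nb) {
      trow <- genes[genes$id == tg, ]
      rel <- classify_relation(vrow, trow, cis_window, trans_exclusion,
                               cis_gene = if (measure_from == "cis_gene")
                                 crow else NULL,
                               measure_from = measure_from)
      if (rel == "trans")
        out[[length(out) + 1L]] <- data.frame(
          variant_id = vid, cis_gene = cg, trans_gene = tg,
          stringsAsFactors = FALSE)
    }
  }
  trios <- if (length(out)) unique(do.call(rbind, out))
           else data.frame(variant_id = character(0),
                           cis_gene = character(0),
                           trans_gene = character(0),
                           stringsAsFactors = FALSE)
  trios <- trios[order(trios$variant_id, trios$cis_gene, trios$trans_gene), ]
  rownames(trios) <- NULL
  attr(trios, "log") <- log
  trios
}

# run cit_test for each trio; returns a Table-1-style results data.frame
.mediate_trios <- function(trios, genotypes, expression, covariates,
                           config, cis_records = NULL) {
  cols <- data.frame(variant_id = character(0), chr_pos = character(0),
                     alleles = character(0), cis_gene = character(0),
                     beta_C = numeric(0), p_C = numeric(0),
                     trans_gene = character(0), beta_T = numeric(0),
                     p_T = numeric(0), p1 = numeric(0), p2 = numeric(0),
                     p3 = numeric(0), p4 = numeric(0),
                     mediation_p = numeric(0), beta_Tadj = numeric(0),
                     M = numeric(0), stringsAsFactors = FALSE)
  if (NROW(trios) == 0) return(cols)
  res <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    vid <- trios$variant_id[i]; cg <- trios$cis_gene[i]
    tg <- trios$trans_gene[i]
    L <- genotypes$dosage[, vid]
    Cg <- expression$values[, cg]
    Tg <- expression$values[, tg]
    ct <- cit_test(L, Cg, Tg, covariates, B_cond4 = config$B_cond4,
                   seed = config$seed + i)
    vrow <- genotypes$variants[genotypes$variants$id == vid, ]
    cisrec <- if (!is.null(cis_records)) {
      hit <- cis_records[cis_records$variant_id == vid &
                           cis_records$gene_id == cg, ]
      if (nrow(hit)) hit[1, ] else NULL
    } else NULL
    res[[i]] <- data.frame(
      variant_id = vid,
      chr_pos = paste0(vrow$chrom, ":", vrow$pos),
      alleles = paste0(vrow$ref %||% "?", "/", vrow$alt %||% "?"),
      cis_gene = cg,
      beta_C = if (!is.null(cisrec)) cisrec$beta else NA_real_,
      p_C = if (!is.null(cisrec)) cisrec$p else NA_real_,
      trans_gene = tg, beta_T = ct$beta_T, p_T = ct$p1,
      p1 = ct$p1, p2 = ct$p2, p3 = ct$p3, p4 = ct$p4,
      mediation_p = ct$p_omnibus, beta_Tadj = ct$beta_Tadj, M = ct$M,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Run the full cis-mediation pipeline
#'
#' Executes the analytical stages end to end: expression-PC covariates,
#' covariate-adjusted eQTL scan, transcript screening, co-expression graph
#' estimation on the screened transcripts, peak-cis selection, trio
#' construction from graph neighborhoods, per-trio mediation testing,
#' Bonferroni significance over the realized trio count, and (optionally)
#' the genotype-stratified permutation robustness test. A rerun with the
#' same inputs and config is bit-identical.
#'
#' When fewer than three transcripts pass screening the graphical model is
#' degenerate; the pipeline then uses the complete graph on the screened
#' set (logged in the manifest).
#'
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()] (same samples, same order).
#' @param covariates optional [covariate_set()] of technical covariates.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; stage outputs are written there as
#'   TSVs with the config echoed in `#` header lines.
#' @return object of class `cismed_run`: `manifest`, `scan`, `screen`,
#'   `graph`, `cis_peaks`, `trios`, `results`, `perm`, `config`.
#' @export
run_pipeline <- function(genotypes, expression, covariates = NULL,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  samples <- rownames(genotypes$dosage)
  .check_aligned(samples, rownames(expression$values), "expression")

  # stage 1: covariates (+ expression PCs)
  pcs <- NULL
  if (config$compute_pcs)
    pcs <- compute_expression_pcs(expression, config$pc_min_var,
                                  config$max_pcs)
  covs <- if (!is.null(covariates) && !is.null(pcs))
    cbind_covariates(covariates, pcs)
  else if (!is.null(pcs)) pcs else covariates
  n_pcs <- if (is.null(pcs)) 0L else ncol(pcs$covariates)

  # stage 2: eQTL scan
  scan <- eqtl_scan(genotypes, expression, covs,
                    cis_window = config$cis_window,
                    trans_exclusion = config$trans_exclusion)

  # stage 3: transcript screening
  n_loci <- config$n_loci %||% ncol(genotypes$dosage)
  screen <- screen_transcripts(scan, n_loci, config$fdr_level)
  screened <- screen$gene_id[screen$selected]

  # stage 4: co-expression graph on screened transcripts
  if (length(screened) >= 3) {
    sub <- expression$values[, screened, drop = FALSE]
    if (config$residualize_network && !is.null(covs)) {
      qz <- .design_qr(.cov_matrix(covs, samples), nrow(sub))
      sub <- qr.resid(qz, sub)
    }
    path <- neighborhood_selection_path(sub, config$n_lambda,
                                        config$lambda_min_ratio,
                                        rule = config$sym_rule)
    graph <- select_graph(path, subsample_ratio = config$subsample_ratio,
                          n_subsamples = config$n_subsamples,
                          instability_threshold = config$instability_threshold,
                          seed = config$seed)
  } else {
    warnings_log <- c(warnings_log, paste0(
      "only ", length(screened),
      " transcript(s) screened; using complete graph fallback"))
    edges <- if (length(screened) == 2)
      data.frame(a = min(screened), b = max(screened),
                 selected_by = "both", lambda = NA_real_,
                 stringsAsFactors = FALSE)
    else data.frame(a = character(0), b = character(0),
                    selected_by = character(0), lambda = numeric(0),
                    stringsAsFactors = FALSE)
    graph <- structure(list(nodes = screened, edges = edges,
                            lambda = NA_real_, lambda_index = NA_integer_,
                            instability = NULL, rule = config$sym_rule,
                            seed = config$seed),
                       class = "coexpression_graph")
  }

  # stage 5: peak cis selection
  cis_records <- scan[scan$relation == "cis", , drop = FALSE]
  n_cis_tests <- nrow(cis_records)
  cis_peaks <- peak_cis_selection(cis_records, config$cis_alpha,
                                  n_cis_tests, genotypes$variants)
  sig_pairs <- cis_peaks[cis_peaks$significant, , drop = FALSE]

  # stage 6: trios from graph neighborhoods
  trios <- build_trios(sig_pairs, graph, expression$genes,
                       genotypes$variants, config$cis_window,
                       config$trans_exclusion, config$measure_trans_from)
  warnings_log <- c(warnings_log, attr(trios, "log"))

  # stage 7: mediation testing + Bonferroni over realized trio count
  results <- .mediate_trios(trios, genotypes, expression, covs, config,
                            cis_records)
  n_trios <- nrow(results)
  threshold <- if (n_trios > 0)
    bonferroni_threshold(config$trio_alpha, n_trios) else NA_real_
  results$significant <- if (n_trios > 0)
    results$mediation_p < threshold else logical(0)

  # stage 8 (optional): permutation robustness
  results$perm_p <- rep(NA_real_, n_trios)
  results$perm_B <- rep(NA_integer_, n_trios)
  if (config$B_perm > 0 && n_trios > 0) {
    for (i in seq_len(n_trios)) {
      pr <- permutation_robustness(
        genotypes$dosage[, results$variant_id[i]],
        expression$values[, results$cis_gene[i]],
        expression$values[, results$trans_gene[i]],
        covs, p_observed = results$mediation_p[i], B = config$B_perm,
        B_cond4 = config$B_cond4, seed = config$seed + 500000L + i)
      results$perm_p[i] <- pr$p_perm
      results$perm_B[i] <- as.integer(pr$B)
    }
  }

  manifest <- list(
    n_samples = length(samples),
    n_variants = ncol(genotypes$dosage),
    n_genes = ncol(expression$values),
    n_covariates = if (is.null(covs)) 0L else ncol(covs$covariates),
    n_pcs = n_pcs,
    n_loci = n_loci,
    n_genes_screened = length(screened),
    n_edges = nrow(graph$edges),
    n_cis_tests = n_cis_tests,
    n_sig_cis_pairs = nrow(sig_pairs),
    n_trios = n_trios,
    n_sig_trios = sum(results$significant),
    trio_threshold = threshold,
    seed = config$seed,
    package_version = as.character(packageVersion("cismediatr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    warnings = warnings_log)
  run <- structure(list(manifest = manifest, scan = scan, screen = screen,
                        graph = graph, cis_peaks = cis_peaks, trios = trios,
                        results = results, config = config),
                   class = "cismed_run")
  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .config_lines(run$config)
  write_eqtl_tsv(run$scan, file.path(outdir, "eqtl_scan.tsv"), hdr)
  write_eqtl_tsv(run$screen, file.path(outdir, "screen.tsv"), hdr)
  write_graph_tsv(run$graph, file.path(outdir, "graph.tsv"))
  write_eqtl_tsv(run$cis_peaks, file.path(outdir, "cis_peaks.tsv"), hdr)
  write_results_tsv(run$results, file.path(outdir, "mediation_results.tsv"),
                    run$config)
  mf <- run$manifest
  writeLines(paste0(names(mf), "=",
                    vapply(mf, function(v) paste(format(v), collapse = ";"),
                           "")),
             file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' Write a Table-1-style mediation results TSV
#'
#' @param results results data.frame from [run_pipeline()] or
#'   [sensitivity_scan()].
#' @param file path.
#' @param config optional [pipeline_config()] echoed into `#` header lines.
#' @export
write_results_tsv <- function(results, file, config = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(paste0("# ", .config_lines(config)), con)
  write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.cismed_run <- function(x, ...) {
  m <- x$manifest
  cat("cismed_run:", m$n_samples, "samples,", m$n_variants, "variants,",
      m$n_genes, "genes\n")
  cat("  screened:", m$n_genes_screened, "| edges:", m$n_edges,
      "| significant cis pairs:", m$n_sig_cis_pairs, "\n")
  cat("  trios:", m$n_trios, "| significant trios:", m$n_sig_trios,
      "(threshold", signif(m$trio_threshold, 3), ")\n")
  invisible(x)
}

#' Network-agnostic sensitivity mediation scan
#'
#' Applies the same mediation machinery to every trans-eligible gene for
#' each significant cis pair, regardless of graph connectivity. Guarded by
#' a pair-count budget: exceeding it without `override = TRUE` aborts.
#'
#' @param cis_pairs data.frame with `variant_id`, `gene_id`.
#' @param genotypes,expression,covariates pipeline inputs (covariates
#'   should already include the expression PCs used for the main scan).
#' @param config a [pipeline_config()].
#' @param budget maximum candidate pair count (default from config).
#' @param override run anyway when the budget is exceeded.
#' @return results data.frame as in [run_pipeline()], with a
#'   `network_agnostic` column set to `TRUE`.
#' @export
sensitivity_scan <- function(cis_pairs, genotypes, expression,
                             covariates = NULL,
                             config = pipeline_config(),
                             budget = config$sensitivity_budget,
                             override = FALSE) {
  genes <- expression$genes
  cand <- list()
  for (r in seq_len(NROW(cis_pairs))) {
    vid <- cis_pairs$variant_id[r]
    cg <- cis_pairs$gene_id[r]
    vrow <- genotypes$variants[genotypes$variants$id == vid, ]
    crow <- genes[genes$id == cg, ]
    for (g in setdiff(genes$id, cg)) {
      trow <- genes[genes$id == g, ]
      rel <- classify_relation(vrow, trow, config$cis_window,
                               config$trans_exclusion,
                               cis_gene = if (config$measure_trans_from ==
                                              "cis_gene") crow else NULL,
                               measure_from = config$measure_trans_from)
      if (rel == "trans")
        cand[[length(cand) + 1L]] <- data.frame(
          variant_id = vid, cis_gene = cg, trans_gene = g,
          stringsAsFactors = FALSE)
    }
  }
  trios <- if (length(cand)) unique(do.call(rbind, cand))
           else data.frame(variant_id = character(0),
                           cis_gene = character(0),
                           trans_gene = character(0))
  if (nrow(trios) > budget && !override)
    stop("sensitivity scan budget exceeded (", nrow(trios), " > ", budget,
         "); set override = TRUE to proceed")
  trios <- trios[order(trios$variant_id, trios$cis_gene, trios$trans_gene), ]
  rownames(trios) <- NULL
  res <- .mediate_trios(trios, genotypes, expression, covariates, config)
  if (nrow(res)) res$network_agnostic <- TRUE
  else res$network_agnostic <- logical(0)
  res
}

#' Summarize mediation results
#'
#' Sorts by mediation p-value (ties broken by trio identifiers, stable),
#' flags significance against the Bonferroni threshold and a suggestive
#' level, and cross-checks the counts against the manifest.
#'
#' @param results results data.frame from [run_pipeline()].
#' @param manifest the run manifest (for count cross-checks).
#' @param threshold Bonferroni significance threshold (default: from
#'   manifest).
#' @param suggestive suggestive mediation p level (default 1e-3).
#' @param allow_empty permit an empty results table.
#' @return object of class `cismed_report`: `table` (sorted, starred) and
#'   `summary` (character lines).
#' @export
report <- function(results, manifest, threshold = NULL,
                   suggestive = 1e-3, allow_empty = FALSE) {
  if (NROW(results) == 0 && !allow_empty)
    stop("empty results; pass allow_empty = TRUE for an empty report")
  if (NROW(results) != manifest$n_trios)
    stop("inconsistent manifest: results rows (", NROW(results),
         ") != manifest n_trios (", manifest$n_trios, ")")
  threshold <- threshold %||% manifest$trio_threshold
  tab <- as.data.frame(results)
  if (nrow(tab)) {
    ord <- order(tab$mediation_p, tab$variant_id, tab$cis_gene,
                 tab$trans_gene)
    tab <- tab[ord, ]
    tab$signif <- ifelse(tab$mediation_p < threshold, "*",
                         ifelse(tab$mediation_p < suggestive, ".", ""))
    rownames(tab) <- NULL
  } else {
    tab$signif <- character(0)
  }
  n_sig <- sum(tab$signif == "*")
  if (!is.na(manifest$n_sig_trios) && n_sig != manifest$n_sig_trios)
    stop("inconsistent manifest: recomputed significant count differs")
  n_sugg <- sum(tab$signif == ".")
  summary <- c(
    sprintf("%d trio(s) tested; Bonferroni threshold %.3g", nrow(tab),
            threshold),
    sprintf("%d significant, %d suggestive (p < %.3g)", n_sig, n_sugg,
            suggestive))
  structure(list(table = tab, summary = summary), class = "cismed_report")
}

#' @export
print.cismed_report <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  if (nrow(x$table)) {
    show <- x$table[, intersect(c("variant_id", "cis_gene", "trans_gene",
                                  "beta_T", "mediation_p", "beta_Tadj",
                                  "M", "signif"), names(x$table))]
    print(utils::head(show, 20))
  }
  invisible(x)
}
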