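#' Distance between a variant and a transcript
#'
#' Zero when the position falls inside the transcript, otherwise the gap to
#' the nearest transcript boundary. Coordinates are 1-based inclusive.
#'
#' @param pos variant position.
#' @param start,end transcript boundaries.
#' @return distance in bp (vectorized).
#' @export
variant_gene_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0, pmin(abs(pos - start), abs(pos - end)))
}

#' Distance between two transcripts
#'
#' Zero when they overlap, otherwise the gap between nearest boundaries.
#'
#' @param start1,end1,start2,end2 transcript boundaries.
#' @return distance in bp (vectorized).
#' @export
gene_gene_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

#' Classify a variant-gene relation as cis, trans, or other
#'
#' A pair is `cis` when variant and transcript share a chromosome and the
#' variant lies within `cis_window` of the transcript (boundary inclusive;
#' distance 0 inside the transcript). A gene is trans-eligible when it lies
#' at least `trans_exclusion` away from the reference locus — the cis gene
#' when one is supplied, otherwise the variant itself — with a different
#' chromosome always eligible. Everything else is `other` (too distant to be
#' cis, too close to be a safe trans call given long-range LD).
#'
#' @param variant one-row data.frame/list with `chrom`, `pos`.
#' @param gene one-row data.frame/list with `chrom`, `start`, `end`.
#' @param cis_window cis distance in bp (default 1e6).
#' @param trans_exclusion minimum trans distance in bp (default 1e7).
#' @param cis_gene optional one-row data.frame/list with `chrom`, `start`,
#'   `end`: the significant cis gene from which the trans exclusion zone is
#'   measured.
#' @param measure_from `"cis_gene"` (default; falls back to the variant when
#'   `cis_gene` is `NULL`) or `"variant"`.
#' @return `"cis"`, `"trans"`, or `"other"`.
#' @export
classify_relation <- function(variant, gene, cis_window = 1e6,
                              trans_exclusion = 1e7, cis_gene = NULL,
                              measure_from = c("cis_gene", "variant")) {
  measure_from <- match.arg(measure_from)
  vchrom <- as.character(variant$chrom[1]); vpos <- variant$pos[1]
  gchrom <- as.character(gene$chrom[1])
  if (identical(vchrom, gchrom) &&
      variant_gene_distance(vpos, gene$start[1], gene$end[1]) <= cis_window)
    return("cis")
  use_cis_gene <- measure_from == "cis_gene" && !is.null(cis_gene)
  if (use_cis_gene) {
    rchrom <- as.character(cis_gene$chrom[1])
    if (!identical(rchrom, gchrom)) return("trans")
    dd <- gene_gene_distance(cis_gene$start[1], cis_gene$end[1],
                             gene$start[1], gene$end[1])
  } else {
    if (!identical(vchrom, gchrom)) return("trans")
    dd <- variant_gene_distance(vpos, gene$start[1], gene$end[1])
  }
  if (dd >= trans_exclusion) "trans" else "other"
}

#' Expression principal components for covariate adjustment
#'
#' Column-centers the expression matrix, decomposes it, and returns the
#' leading principal-component score vectors whose variance fraction meets
#' `min_variance_fraction` (default 1% of total variance), ordered by
#' variance explained. These emulate latent technical/biological factors.
#'
#' With transcriptome-scale gene counts the variance rule retains a handful
#' of components; with only tens of genes nearly every component passes it
#' and adjustment would absorb the signal of interest, so `max_pcs` can cap
#' the count (desk-scale analyses with observed confounders should adjust
#' for those directly instead).
#'
#' @param expression an [expression_matrix()] (or plain samples x genes
#'   matrix).
#' @param min_variance_fraction keep PCs explaining at least this fraction.
#' @param max_pcs upper bound on the number of PCs returned (default
#'   unlimited).
#' @return A [covariate_set()] of PC scores named `PC1`, `PC2`, ...; zero
#'   columns (with a warning) when the expression matrix is constant.
#' @export
compute_expression_pcs <- function(expression, min_variance_fraction = 0.01,
                                   max_pcs = Inf) {
  E <- if (inherits(expression, "expression_matrix")) expression$values
       else as.matrix(expression)
  if (nrow(E) < 2) stop("need at least 2 samples")
  vars <- apply(E, 2, var)
  if (all(vars == 0)) {
    warning("constant expression matrix: no principal components")
    return(covariate_set(matrix(0, nrow(E), 0,
                                dimnames = list(rownames(E), NULL))))
  }
  pc <- prcomp(E, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(frac >= min_variance_fraction)
  if (length(keep) > max_pcs) keep <- keep[seq_len(max_pcs)]
  scores <- pc$x[, keep, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_along(keep))
  out <- covariate_set(scores)
  attr(out, "variance_fraction") <- frac
  out
}

# internal: build intercept+covariate design, QR, and rank check that names
# the first offending (linearly dependent) column.
.design_qr <- function(X, n) {
  Z <- cbind(`(Intercept)` = rep(1, n), X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("rank-deficient covariates: column ", bad[1],
         " is linearly dependent")
  }
  qz
}

#' Covariate-adjusted linear-model eQTL scan
#'
#' For every (variant, gene) pair, fits ordinary least squares of expression
#' on dosage with an intercept and the supplied covariates, and reports the
#' dosage slope, its standard error, t statistic, and two-sided p-value on
#' `n - k - 2` residual degrees of freedom (k covariates). The
#' implementation residualizes both dosages and expression on the covariates
#' once and scans via cross-products; by the Frisch-Waugh-Lovell theorem
#' this equals the per-pair fit exactly.
#'
#' Monomorphic variants (zero dosage variance) yield a record with `p = 1`,
#' missing estimates, and `note = "monomorphic"`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expression an [expression_matrix()] with identical sample order.
#' @param covariates optional [covariate_set()] / matrix (same samples).
#' @param pairs `"all"` (default) or a data.frame with columns `variant_id`,
#'   `gene_id` restricting the scan.
#' @param cis_window,trans_exclusion distance rules passed to
#'   [classify_relation()] (the trans call here is measured from the
#'   variant; trio construction re-checks eligibility against the cis gene).
#' @return data.frame of class `eqtl_records` with columns `variant_id`,
#'   `gene_id`, `relation`, `beta`, `se`, `stat`, `p`, `note`.
#' @export
eqtl_scan <- function(genotypes, expression, covariates = NULL,
                      pairs = "all", cis_window = 1e6,
                      trans_exclusion = 1e7) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"))
  G <- genotypes$dosage
  E <- expression$values
  .check_aligned(rownames(G), rownames(E), "expression")
  X <- .cov_matrix(covariates, rownames(G))
  n <- nrow(G)
  k <- ncol(X)
  qz <- .design_qr(X, n)
  df <- n - k - 2
  if (df < 1) stop("not enough samples for the covariate set")
  mono <- apply(G, 2, var) == 0
  Gr <- qr.resid(qz, G)
  Er <- qr.resid(qz, E)
  xx <- colSums(Gr^2)
  yy <- colSums(Er^2)
  cp <- crossprod(Gr, Er)                       # variants x genes
  beta <- cp / xx
  rss <- pmax(outer(rep(1, length(xx)), yy) - beta^2 * xx, 0)
  se <- sqrt(rss / df / xx)
  stat <- beta / se
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)

  vg <- expand.grid(vi = seq_len(ncol(G)), gi = seq_len(ncol(E)))
  if (!identical(pairs, "all")) {
    pairs <- as.data.frame(pairs)
    vi <- match(pairs$variant_id, colnames(G))
    gi <- match(pairs$gene_id, colnames(E))
    if (anyNA(vi) || anyNA(gi)) stop("unknown variant or gene id in pairs")
    vg <- data.frame(vi = vi, gi = gi)
  }
  idx <- cbind(vg$vi, vg$gi)
  rel <- character(nrow(vg))
  for (r in seq_len(nrow(vg))) {
    rel[r] <- classify_relation(genotypes$variants[vg$vi[r], ],
                                expression$genes[vg$gi[r], ],
                                cis_window, trans_exclusion,
                                cis_gene = NULL)
  }
  out <- data.frame(
    variant_id = colnames(G)[vg$vi],
    gene_id = colnames(E)[vg$gi],
    relation = rel,
    beta = beta[idx], se = se[idx], stat = stat[idx], p = p[idx],
    note = "", stringsAsFactors = FALSE)
  is_mono <- mono[vg$vi]
  if (any(is_mono)) {
    out$beta[is_mono] <- NA_real_
    out$se[is_mono] <- NA_real_
    out$stat[is_mono] <- NA_real_
    out$p[is_mono] <- 1
    out$note[is_mono] <- "monomorphic"
  }
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min_(j >= i) m * p_(j) / j`, capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(m * pvalues[o] / seq(m, 1)))
  q[order(o)]
}

#' Transcriptome-wide eQTL screening for network inclusion
#'
#' Takes the smallest association p-value per transcript across all tested
#' variants, Bonferroni-adjusts it for the number of risk loci, converts the
#' adjusted values to Benjamini-Hochberg q-values across transcripts, and
#' selects transcripts with q below the (deliberately permissive) FDR level.
#'
#' @param records an `eqtl_records` data.frame (needs `gene_id`, `p`).
#' @param n_loci number of original risk loci used for the Bonferroni
#'   adjustment of each transcript's minimum p-value.
#' @param fdr_level FDR selection level (default 0.20).
#' @return data.frame of class `screen_result`: `gene_id`, `min_p`,
#'   `adj_p`, `q`, `selected`.
#' @export
screen_transcripts <- function(records, n_loci, fdr_level = 0.2) {
  if (NROW(records) == 0)
    return(structure(data.frame(gene_id = character(0), min_p = numeric(0),
                                adj_p = numeric(0), q = numeric(0),
                                selected = logical(0)),
                     class = c("screen_result", "data.frame")))
  min_p <- tapply(records$p, records$gene_id, min)
  out <- data.frame(gene_id = names(min_p), min_p = as.numeric(min_p),
                    stringsAsFactors = FALSE)
  out$adj_p <- pmin(1, out$min_p * n_loci)
  out$q <- bh_fdr(out$adj_p)
  out$selected <- out$q < fdr_level
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Peak cis-eQTL selection with Bonferroni significance
#'
#' For each gene, takes the cis variant with the smallest association
#' p-value (ties broken by position, then variant id) and retains the
#' (variant, gene) pair when that p-value falls below
#' `alpha / n_cis_tests` — a Bonferroni threshold over all cis association
#' tests performed in the run.
#'
#' @param records cis-relation `eqtl_records` rows.
#' @param alpha family-wise error level (default 0.05).
#' @param n_cis_tests total number of cis tests in this run (defaults to
#'   `nrow(records)`).
#' @param variants optional variant annotation data.frame (`id`, `pos`)
#'   used for the positional tie-break.
#' @return data.frame with one row per gene: `gene_id`, `variant_id`, `p`,
#'   `threshold`, `significant`.
#' @export
peak_cis_selection <- function(records, alpha = 0.05,
                               n_cis_tests = nrow(records),
                               variants = NULL) {
  if (NROW(records) == 0)
    return(data.frame(gene_id = character(0), variant_id = character(0),
                      p = numeric(0), threshold = numeric(0),
                      significant = logical(0)))
  records <- as.data.frame(records)
  pos <- if (!is.null(variants))
    variants$pos[match(records$variant_id, variants$id)]
  else rep(0, nrow(records))
  ord <- order(records$gene_id, records$p, pos, records$variant_id)
  records <- records[ord, ]
  peak <- records[!duplicated(records$gene_id), ]
  thr <- alpha / n_cis_tests
  out <- data.frame(gene_id = peak$gene_id, variant_id = peak$variant_id,
                    p = peak$p, threshold = thr,
                    significant = peak$p < thr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bonferroni threshold helper
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Permutation p-value floor
#'
#' The `(count + 1) / (B + 1)` estimator cannot fall below `1 / (B + 1)`;
#' this is the smallest reportable permutation p-value at `B` permutations.
#'
#' @param B number of permutations.
#' @return `1 / (B + 1)`.
#' @export
perm_p_floor <- function(B) {
  if (B < 1) stop("B must be >= 1")
  1 / (B + 1)
}
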