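#' Build a sparse precision matrix with known graph structure
#'
#' Constructs the precision (inverse covariance) matrix used to generate
#' background genes. Off-diagonal entries of magnitude `v` are placed on the
#' edges of a chain, hub (star), or Erdos-Renyi random adjacency, and the
#' diagonal is inflated to `|lambda_min| + 0.1 + u` so the matrix is
#' positive definite — the convention of the reference generator for this
#' family of graphical-model simulators.
#'
#' @param p number of genes (nodes).
#' @param structure `"chain"`, `"hub"`, or `"random"`.
#' @param v off-diagonal edge magnitude (default 0.3).
#' @param u additional diagonal inflation (default 0.1).
#' @param prob edge probability for `structure = "random"`.
#' @param seed RNG seed (used only for `"random"`).
#' @return A `p x p` precision matrix with an `"adjacency"` attribute
#'   (logical matrix of true edges).
#' @export
make_precision <- function(p, structure = c("chain", "hub", "random"),
                           v = 0.3, u = 0.1, prob = 0.1, seed = NULL) {
  structure <- match.arg(structure)
  if (p < 2) stop("need at least 2 genes")
  A <- matrix(FALSE, p, p)
  if (structure == "chain") {
    idx <- cbind(seq_len(p - 1), seq(2, p))
    A[idx] <- TRUE
  } else if (structure == "hub") {
    A[1, 2:p] <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    up <- upper.tri(A)
    A[up] <- stats::runif(sum(up)) < prob
  }
  A <- A | t(A)
  omega <- v * A
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  diag(omega) <- abs(min(ev)) + 0.1 + u
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) stop("singular or indefinite precision structure")
  attr(omega, "adjacency") <- A
  omega
}

# Draw n samples from N(0, solve(omega)) via the Cholesky factor of omega.
.rmvnorm_precision <- function(n, omega) {
  R <- chol(omega) # omega = t(R) %*% R
  z <- matrix(rnorm(n * ncol(omega)), ncol(omega), n)
  t(backsolve(R, z))
}

#' Simulate additive genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each sample's dosage at each variant is drawn as Binomial(2, MAF),
#' yielding integer 0/1/2 alternate-allele counts.
#'
#' @param n_samples number of samples.
#' @param variant_specs data.frame with columns `id`, `chrom`, `pos`, `maf`
#'   (and optionally `ref`, `alt`).
#' @param seed RNG seed; the same seed reproduces the matrix bit-identically.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, variant_specs, seed = NULL) {
  if (length(n_samples) != 1L || n_samples <= 0)
    stop("n_samples must be a positive count")
  specs <- as.data.frame(variant_specs, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos", "maf") %in% names(specs)))
    stop("variant_specs needs columns id, chrom, pos, maf")
  bad <- which(specs$maf <= 0 | specs$maf > 0.5)
  if (length(bad))
    stop("MAF outside (0, 0.5] for variant ", specs$id[bad[1]])
  if (!is.null(seed)) set.seed(seed)
  dosage <- vapply(specs$maf, function(f) rbinom(n_samples, 2L, f),
                   numeric(n_samples))
  dosage <- matrix(as.double(dosage), nrow = n_samples,
                   dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                                   as.character(specs$id)))
  if (is.null(specs$ref)) specs$ref <- "A"
  if (is.null(specs$alt)) specs$alt <- "G"
  genotype_matrix(dosage, specs)
}

#' Describe a trio simulation scenario
#'
#' Encodes the generative model for a (variant L, cis-gene C, trans-gene T)
#' trio: `C = a*L + conf_C'U + tech_C'W + e_C` and
#' `T = b*C + d*L + conf_T'U + tech_T'W + e_T`, where `U` are latent
#' confounders (the stand-in for hidden expression factors), `W` two generic
#' technical covariates, and the residuals are Gaussian. Background genes are
#' drawn from a zero-mean multivariate normal with the sparse precision
#' matrix of [make_precision()]. The scenario label is derived from the
#' effect pattern: mediated (a != 0, b != 0, d = 0), direct (d != 0, b = 0),
#' independent (a = b = d = 0), reverse (generation direction flipped,
#' L -> T -> C), otherwise mixed.
#'
#' Defaults mirror the study conditions of the motivating design: 471
#' samples, common variant (MAF 0.3), unit residual scales, moderate
#' cis and mediation effects.
#'
#' @param n_samples samples to generate.
#' @param maf minor-allele frequency of L, in (0, 0.5].
#' @param a L -> C effect per dosage unit.
#' @param b C -> T effect per expression unit.
#' @param d direct L -> T effect per dosage unit.
#' @param sigma_C,sigma_T residual standard deviations (> 0).
#' @param n_confounders number of shared latent confounders.
#' @param conf_loadings_C,conf_loadings_T confounder loadings on C and T.
#' @param tech_loadings_C,tech_loadings_T loadings of the two technical
#'   covariates on C and T.
#' @param n_background_genes background genes drawn from the graphical model.
#' @param background_structure,background_v,background_u,background_prob
#'   arguments passed to [make_precision()].
#' @param reverse if `TRUE`, generate T from L and C from T (reverse
#'   causal direction).
#' @param seed RNG seed for the expression draw.
#' @return An object of class `trio_scenario`.
#' @export
trio_scenario <- function(n_samples = 471, maf = 0.3, a = 0.5, b = 0.8,
                          d = 0, sigma_C = 1, sigma_T = 1,
                          n_confounders = 2,
                          conf_loadings_C = rep(0.5, n_confounders),
                          conf_loadings_T = rep(0.5, n_confounders),
                          tech_loadings_C = c(0.2, 0.2),
                          tech_loadings_T = c(0.2, 0.2),
                          n_background_genes = 30,
                          background_structure = "chain",
                          background_v = 0.3, background_u = 0.1,
                          background_prob = 0.1,
                          reverse = FALSE, seed = 1L) {
  if (sigma_C <= 0 || sigma_T <= 0) stop("sigma_C and sigma_T must be > 0")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  stopifnot(length(conf_loadings_C) == n_confounders,
            length(conf_loadings_T) == n_confounders,
            length(tech_loadings_C) == 2, length(tech_loadings_T) == 2)
  sc <- structure(as.list(environment()), class = "trio_scenario")
  sc$label <- scenario_label(sc)
  sc
}

#' @rdname trio_scenario
#' @param scenario a `trio_scenario`.
#' @export
scenario_label <- function(scenario) {
  with(scenario, {
    if (isTRUE(reverse)) "reverse"
    else if (a == 0 && b == 0 && d == 0) "independent"
    else if (d != 0 && b == 0) "direct"
    else if (a != 0 && b != 0 && d == 0) "mediated"
    else "mixed"
  })
}

#' Simulate trio + background expression from a scenario
#'
#' Generates the cis-gene, trans-gene, latent confounders, technical
#' covariates, and background genes for an existing genotype matrix, and
#' assigns genomic coordinates so that the cis gene lies within the cis
#' window of the anchor variant and every other gene is trans-eligible
#' (different chromosome). Returns the ground truth alongside the data.
#'
#' @param genotypes a [genotype_matrix()] containing the anchor variant.
#' @param scenario a [trio_scenario()].
#' @param variant_id anchor variant (default: first variant).
#' @param return_confounders include the latent confounders in the returned
#'   covariate set (default `TRUE`); set `FALSE` to withhold them and
#'   exercise principal-component-based recovery.
#' @return A list with `expression` ([expression_matrix()]), `covariates`
#'   ([covariate_set()]), and `truth` (list: variant, cis/trans gene ids,
#'   true effects, scenario label, true edge list including the background
#'   adjacency).
#' @export
simulate_trio_expression <- function(genotypes, scenario,
                                     variant_id = NULL,
                                     return_confounders = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(scenario, "trio_scenario"))
  variant_id <- variant_id %||% genotypes$variants$id[1]
  if (!variant_id %in% genotypes$variants$id)
    stop("variant ", variant_id, " not present in genotypes")
  L <- genotypes$dosage[, variant_id]
  n <- length(L)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  K <- scenario$n_confounders
  U <- matrix(rnorm(n * K), n, K)
  W <- matrix(rnorm(n * 2), n, 2)
  eC <- rnorm(n, sd = scenario$sigma_C)
  eT <- rnorm(n, sd = scenario$sigma_T)
  confC <- if (K > 0) drop(U %*% scenario$conf_loadings_C) else 0
  confT <- if (K > 0) drop(U %*% scenario$conf_loadings_T) else 0
  techC <- drop(W %*% scenario$tech_loadings_C)
  techT <- drop(W %*% scenario$tech_loadings_T)
  if (isTRUE(scenario$reverse)) {
    Tg <- scenario$a * L + confT + techT + eT
    Cg <- scenario$b * Tg + scenario$d * L + confC + techC + eC
  } else {
    Cg <- scenario$a * L + confC + techC + eC
    Tg <- scenario$b * Cg + scenario$d * L + confT + techT + eT
  }
  p_bg <- scenario$n_background_genes
  bg_adj <- NULL
  if (p_bg >= 2) {
    omega <- make_precision(p_bg, scenario$background_structure,
                            v = scenario$background_v,
                            u = scenario$background_u,
                            prob = scenario$background_prob,
                            seed = if (!is.null(scenario$seed))
                              scenario$seed + 104729L else NULL)
    BG <- .rmvnorm_precision(n, omega)
    bg_adj <- attr(omega, "adjacency")
  } else if (p_bg == 1) {
    BG <- matrix(rnorm(n), n, 1)
  } else {
    BG <- matrix(0, n, 0)
  }
  bg_ids <- if (p_bg > 0) sprintf("bg%03d", seq_len(p_bg)) else character(0)
  values <- cbind(cisg = Cg, transg = Tg, BG)
  colnames(values) <- c("cisg", "transg", bg_ids)
  rownames(values) <- rownames(genotypes$dosage)

  genes <- data.frame(id = colnames(values), chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  anchor <- genotypes$variants[genotypes$variants$id == variant_id, ]
  genes <- assign_coordinates(genes, anchor, cis_gene_id = "cisg",
                              trans_gene_ids = setdiff(genes$id, "cisg"))
  covs <- W
  colnames(covs) <- c("tech1", "tech2")
  if (return_confounders && K > 0) {
    colnames(U) <- paste0("conf", seq_len(K))
    covs <- cbind(covs, U)
  }
  rownames(covs) <- rownames(values)

  edges <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  if (scenario$b != 0)
    edges <- rbind(edges, data.frame(a = "cisg", b = "transg"))
  if (!is.null(bg_adj)) {
    idx <- which(bg_adj & upper.tri(bg_adj), arr.ind = TRUE)
    if (nrow(idx))
      edges <- rbind(edges, data.frame(a = bg_ids[idx[, 1]],
                                       b = bg_ids[idx[, 2]]))
  }
  truth <- list(variant = variant_id, cis_gene = "cisg",
                trans_gene = "transg", a = scenario$a, b = scenario$b,
                d = scenario$d, label = scenario$label, edges = edges,
                background_adjacency = bg_adj)
  list(expression = expression_matrix(values, genes),
       covariates = covariate_set(covs),
       truth = truth)
}

#' Assign genomic coordinates for a simulated gene set
#'
#' Places the cis gene so its nearest transcript boundary lies within the
#' cis window of the anchor variant, and every trans/background gene on a
#' different chromosome from the anchor (hence trivially at least 10 Mb
#' from the cis gene). Placement is deterministic.
#'
#' @param genes data.frame with at least an `id` column; `chrom`, `start`,
#'   `end` are (re)filled.
#' @param anchor_variant one-row data.frame or list with `chrom` and `pos`.
#' @param cis_gene_id id of the gene to place near the anchor.
#' @param trans_gene_ids ids to place on other chromosomes; remaining genes
#'   are treated the same way.
#' @param cis_offset distance (bp) from the anchor position to the cis
#'   gene's start (default 50 kb; must keep the gene within 1 Mb).
#' @param gene_length transcript length in bp (default 10 kb).
#' @return The `genes` data.frame with coordinates filled in.
#' @export
assign_coordinates <- function(genes, anchor_variant, cis_gene_id,
                               trans_gene_ids = NULL,
                               cis_offset = 50000L, gene_length = 10000L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!cis_gene_id %in% genes$id) stop("cis gene id not found")
  trans_gene_ids <- trans_gene_ids %||% setdiff(genes$id, cis_gene_id)
  if (!all(trans_gene_ids %in% genes$id)) stop("unknown trans gene id")
  anchor_chrom <- as.character(anchor_variant$chrom[1])
  anchor_pos <- as.integer(anchor_variant$pos[1])
  genes$chrom <- as.character(genes$chrom)
  ci <- match(cis_gene_id, genes$id)
  genes$chrom[ci] <- anchor_chrom
  genes$start[ci] <- anchor_pos + as.integer(cis_offset)
  genes$end[ci] <- genes$start[ci] + as.integer(gene_length) - 1L
  others <- setdiff(genes$id, cis_gene_id)
  chroms <- setdiff(as.character(1:22), anchor_chrom)
  for (k in seq_along(others)) {
    gi <- match(others[k], genes$id)
    genes$chrom[gi] <- chroms[((k - 1L) %% length(chroms)) + 1L]
    genes$start[gi] <- 1000000L + ((k - 1L) %/% length(chroms)) * 2000000L
    genes$end[gi] <- genes$start[gi] + as.integer(gene_length) - 1L
  }
  genes
}
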