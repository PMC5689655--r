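# shared fixture builders (all data generated in code)

h_variant_specs <- function(maf = 0.3) {
  data.frame(id = "rs11263762", chrom = "17", pos = 36101926, maf = maf,
             ref = "G", alt = "A", stringsAsFactors = FALSE)
}

# one-variant trio dataset; background genes optional
h_trio_data <- function(n, a = 0.5, b = 0.8, d = 0, seed = 1,
                        n_background_genes = 0, maf = 0.3, ...) {
  gt <- simulate_genotypes(n, h_variant_specs(maf), seed = seed)
  sc <- trio_scenario(n_samples = n, maf = maf, a = a, b = b, d = d,
                      n_background_genes = n_background_genes,
                      seed = seed + 7L, ...)
  sim <- simulate_trio_expression(gt, sc)
  list(gt = gt, sim = sim,
       L = gt$dosage[, 1],
       C = sim$expression$values[, "cisg"],
       T = sim$expression$values[, "transg"],
       X = sim$covariates)
}

# O(m^2) brute-force Benjamini-Hochberg step-up definition
h_bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  q
}

# precision/recall of an estimated edge set against a true adjacency
h_edge_pr <- function(graph, adjacency, ids) {
  tr <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  tset <- paste(ids[tr[, 1]], ids[tr[, 2]])
  eset <- paste(graph$edges$a, graph$edges$b)
  c(precision = if (length(eset)) mean(eset %in% tset) else NA_real_,
    recall = if (length(tset)) mean(tset %in% eset) else NA_real_)
}

# draw from a precision-matrix Gaussian (independent of package internals)
h_rprec <- function(n, omega) {
  ev <- eigen(omega, symmetric = TRUE)
  sigma_half <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  matrix(rnorm(n * ncol(omega)), n) %*% sigma_half
}
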