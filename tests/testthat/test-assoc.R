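# small helper: scan fixture with several variants/genes and covariates
h_scan_fixture <- function(n = 200, n_var = 5, n_gene = 8, n_cov = 3,
                           seed = 1) {
  set.seed(seed)
  specs <- data.frame(id = sprintf("v%02d", seq_len(n_var)), chrom = "1",
                      pos = seq(1e6, by = 5e6, length.out = n_var),
                      maf = runif(n_var, 0.1, 0.5))
  gt <- simulate_genotypes(n, specs, seed = seed + 1)
  vals <- matrix(rnorm(n * n_gene), n,
                 dimnames = list(rownames(gt$dosage),
                                 sprintf("g%02d", seq_len(n_gene))))
  genes <- data.frame(id = colnames(vals), chrom = "2",
                      start = seq(1e6, by = 2e6, length.out = n_gene))
  genes$end <- genes$start + 10000
  X <- matrix(rnorm(n * n_cov), n,
              dimnames = list(rownames(gt$dosage),
                              paste0("c", seq_len(n_cov))))
  list(gt = gt, expr = expression_matrix(vals, genes),
       X = covariate_set(X))
}

test_that("fast-path scan equals the per-pair OLS fit", {
  fx <- h_scan_fixture(n = 200, n_var = 5, n_gene = 4, n_cov = 5, seed = 2)
  scan <- eqtl_scan(fx$gt, fx$expr, fx$X)
  expect_equal(nrow(scan), 20L)
  for (r in seq_len(nrow(scan))) {
    y <- fx$expr$values[, scan$gene_id[r]]
    g <- fx$gt$dosage[, scan$variant_id[r]]
    fit <- summary(lm(y ~ g + fx$X$covariates))$coefficients["g", ]
    expect_equal(scan$beta[r], fit[["Estimate"]], tolerance = 1e-10)
    expect_equal(scan$se[r], fit[["Std. Error"]], tolerance = 1e-10)
    expect_equal(scan$p[r], fit[["Pr(>|t|)"]], tolerance = 1e-10)
  }
})

test_that("perfect fits and monomorphic variants are handled", {
  fx <- h_scan_fixture(n = 50, n_var = 2, n_gene = 2, seed = 3)
  # make gene 1 an exact copy of variant 1's dosage
  fx$expr$values[, 1] <- fx$gt$dosage[, 1]
  # make variant 2 monomorphic
  fx$gt$dosage[, 2] <- 0
  scan <- eqtl_scan(fx$gt, fx$expr, covariates = NULL)
  hit <- scan[scan$variant_id == "v01" & scan$gene_id == "g01", ]
  expect_equal(hit$beta, 1.0, tolerance = 1e-12)
  expect_lt(hit$p, 1e-100)
  mono <- scan[scan$variant_id == "v02", ]
  expect_true(all(mono$p == 1))
  expect_true(all(mono$note == "monomorphic"))
  expect_true(all(is.na(mono$beta)))
})

test_that("null scan p-values are uniform with nominal type-I error", {
  fx <- h_scan_fixture(n = 300, n_var = 50, n_gene = 20, n_cov = 2,
                       seed = 4)
  scan <- eqtl_scan(fx$gt, fx$expr, fx$X) # all pairs null: 1000 records
  expect_equal(nrow(scan), 1000L)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  frac <- mean(scan$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("scan is shift-invariant and beta scales inversely with dosage", {
  fx <- h_scan_fixture(n = 120, n_var = 2, n_gene = 2, seed = 5)
  base <- eqtl_scan(fx$gt, fx$expr, fx$X)
  shifted <- fx
  shifted$expr$values <- shifted$expr$values + 5
  s1 <- eqtl_scan(shifted$gt, shifted$expr, fx$X)
  expect_equal(s1$beta, base$beta, tolerance = 1e-9)
  expect_equal(s1$p, base$p, tolerance = 1e-9)
  # halve the dosage scale (keep within [0,2]) -> beta doubles
  scaled <- fx
  scaled$gt$dosage <- scaled$gt$dosage / 2
  s2 <- eqtl_scan(scaled$gt, scaled$expr, fx$X)
  expect_equal(s2$beta, 2 * base$beta, tolerance = 1e-9)
  expect_equal(s2$p, base$p, tolerance = 1e-9)
})

test_that("rank-deficient covariates are rejected with the column named", {
  fx <- h_scan_fixture(n = 60, seed = 6)
  X <- fx$X$covariates
  X <- cbind(X, dup = X[, 1])
  expect_error(eqtl_scan(fx$gt, fx$expr, covariate_set(X)), "dup")
})

test_that("relation classification honors distance boundaries", {
  v <- list(chrom = "1", pos = 1000000)
  gene_at <- function(start, chrom = "1", len = 9999)
    list(chrom = chrom, start = start, end = start + len)
  # exactly 1 Mb away: cis (boundary inclusive)
  expect_identical(classify_relation(v, gene_at(2000000)), "cis")
  # inside the transcript: distance zero
  expect_identical(classify_relation(v, gene_at(999000)), "cis")
  # other chromosome: trans-eligible
  expect_identical(classify_relation(v, gene_at(1e6, chrom = "9")), "trans")
  # measured from the cis gene: 10 Mb inclusive, 1 bp short is "other"
  cisg <- gene_at(1050000)
  far <- gene_at(cisg$end + 10000000)
  near <- gene_at(cisg$end + 9999999)
  expect_identical(classify_relation(v, far, cis_gene = cisg), "trans")
  expect_identical(classify_relation(v, near, cis_gene = cisg), "other")
  # without a cis gene the exclusion zone is measured from the variant
  expect_identical(classify_relation(v, gene_at(11000001)), "trans")
  expect_identical(classify_relation(v, gene_at(5000000)), "other")
})

test_that("transcript screening applies the locus Bonferroni and BH", {
  rec <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                    p = c(1e-4, 0.5, 0.01, 2e-4))
  out <- screen_transcripts(rec, n_loci = 202, fdr_level = 0.2)
  expect_equal(out$adj_p[out$gene_id == "gA"], 0.0202)
  expect_equal(out$adj_p[out$gene_id == "gB"], 1.0) # capped
  expect_true(all(out$adj_p >= out$min_p - 1e-15))
  expect_identical(out$selected, out$q < 0.2)
  expect_equal(nrow(screen_transcripts(rec[0, ], 202)), 0L)
  # BH worked example
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
})

test_that("bh_fdr matches the brute-force step-up oracle exactly", {
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (r in 1:100) {
    p <- runif(sample(3:100, 1))
    expect_identical(bh_fdr(p), h_bh_oracle(p))
  }
  # independent reference: stats::p.adjust
  p <- runif(200)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("peak cis selection applies the Bonferroni rule and tie-breaks", {
  expect_equal(signif(bonferroni_threshold(0.05, 144628), 2), 3.5e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  rec <- data.frame(variant_id = c("v2", "v1", "v3"),
                    gene_id = c("g", "g", "g"),
                    p = c(1e-9, 1e-9, 0.5))
  variants <- data.frame(id = c("v1", "v2", "v3"),
                         pos = c(200, 100, 300))
  out <- peak_cis_selection(rec, alpha = 0.05, n_cis_tests = 3,
                            variants = variants)
  expect_identical(out$variant_id, "v2") # tie broken by smaller position
  expect_true(out$significant)
  out2 <- peak_cis_selection(rec, alpha = 0.05, n_cis_tests = 1e9)
  expect_false(out2$significant)
})

test_that("the planted cis pair is recovered as a significant peak", {
  hits <- replicate(100, {
    s <- sample.int(2^30, 1)
    dat <- h_trio_data(500, a = 0.5, b = 0, d = 0, seed = s,
                       n_background_genes = 4)
    scan <- eqtl_scan(dat$gt, dat$sim$expression, dat$X)
    cis <- scan[scan$relation == "cis", ]
    peak <- peak_cis_selection(cis, 0.05, nrow(cis), dat$gt$variants)
    nrow(peak) == 1 && peak$gene_id == "cisg" && peak$significant
  })
  expect_gte(mean(hits), 0.95)
})

test_that("expression PCs capture dominant latent structure", {
  # rank-1: second gene an exact copy of the first
  set.seed(8)
  v <- rnorm(100)
  E <- cbind(g1 = v, g2 = v)
  rownames(E) <- paste0("s", 1:100)
  pcs <- compute_expression_pcs(E)
  expect_equal(ncol(pcs$covariates), 1L)
  expect_equal(attr(pcs, "variance_fraction")[1], 1.0)
  # variance fractions sum to one
  E2 <- matrix(rnorm(500 * 50), 500, 50,
               dimnames = list(paste0("s", 1:500), paste0("g", 1:50)))
  pcs2 <- compute_expression_pcs(E2, min_variance_fraction = 0)
  expect_equal(sum(attr(pcs2, "variance_fraction")), 1.0)
  # a strong confounder loading on 40% of genes dominates PC1
  n <- 1000; p <- 50
  u <- rnorm(n)
  load <- c(rep(1, 20), rep(0, 30))
  E3 <- outer(u, load) + matrix(rnorm(n * p), n, p)
  dimnames(E3) <- list(paste0("s", 1:n), paste0("g", 1:p))
  pcs3 <- compute_expression_pcs(E3)
  expect_gt(abs(cor(pcs3$covariates[, "PC1"], u)), 0.9)
  # constant matrix: zero PCs with a warning
  E4 <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  expect_warning(pcs4 <- compute_expression_pcs(E4), "constant")
  expect_equal(ncol(pcs4$covariates), 0L)
  # cap
  expect_equal(ncol(compute_expression_pcs(E2, 0, max_pcs = 3)$covariates),
               3L)
})
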