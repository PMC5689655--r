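# --- causal inference test machinery -------------------------------------
#
# Component tests are partial F tests in nested OLS models. Everything is
# computed in the residual space of the intercept + covariate design
# (Frisch-Waugh-Lovell), which makes the permutation loops cheap: only
# cross-products change between permutations.

# genotype classes from (possibly imputed) dosages
.geno_classes <- function(L, strict = FALSE, tol = 1e-6) {
  cls <- pmin(pmax(round(L), 0), 2)
  if (strict && any(abs(L - cls) > tol))
    stop("non-integer dosages with strict_dosage = TRUE")
  factor(cls, levels = sort(unique(cls)))
}

# n x B matrix of permutation indices, shuffling only within genotype
# classes; classes with < 2 members are left unpermuted (recorded in attr).
.strata_perm_idx <- function(cls, B) {
  n <- length(cls)
  idx <- matrix(rep(seq_len(n), B), n, B)
  skipped <- character(0)
  for (lev in levels(cls)) {
    members <- which(cls == lev)
    if (length(members) < 2) {
      skipped <- c(skipped, lev)
      next
    }
    for (b in seq_len(B))
      idx[members, b] <- members[sample.int(length(members))]
  }
  attr(idx, "unpermuted_classes") <- skipped
  idx
}

# partial F test for a single column w added to y ~ Z (Z includes intercept)
.partial_f <- function(y, Z, w) {
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  rw <- qr.resid(qz, w)
  sww <- sum(rw^2)
  df <- length(y) - qz$rank - 1
  beta <- sum(rw * ry) / sww
  rss0 <- sum(ry^2)
  rss1 <- max(rss0 - beta^2 * sww, 0)
  Fst <- (rss0 - rss1) / (rss1 / df)
  list(beta = beta, se = sqrt((rss1 / df) / sww), F = Fst,
       p = pf(Fst, 1, df, lower.tail = FALSE), df = df)
}

# F statistic for v2 in y ~ v1 + v2, all inputs already residualized on the
# covariate design; vectorized over columns of the cross-product inputs.
.f_second <- function(stt, s11, s22, s12, s1t, s2t, df) {
  rss0 <- stt - s1t^2 / s11
  det <- s11 * s22 - s12^2
  b1 <- (s22 * s1t - s12 * s2t) / det
  b2 <- (s11 * s2t - s12 * s1t) / det
  rss1 <- pmax(stt - (b1 * s1t + b2 * s2t), 0)
  (rss0 - rss1) / (rss1 / df)
}

#' Four-component intersection-union causal mediation test
#'
#' Tests the causal chain `L -> C -> T` for a (variant, cis-gene,
#' trans-gene) trio with a conservative omnibus intersection-union test:
#' the omnibus p-value is the maximum of four component p-values, so the
#' chain is supported only when every component rejects.
#'
#' * `p1`: F test of L in `T ~ X + L` (marginal trans association);
#' * `p2`: F test of L in `C ~ X + T + L` (L and C associated given T);
#' * `p3`: F test of C in `T ~ X + L + C` (C and T associated given L);
#' * `p4`: equivalence-style permutation test that L carries no information
#'   about T once C is adjusted for. The observed statistic is the F for L
#'   in `T ~ X + C + L`; its permutation reference is built by
#'   residualizing C on the covariates, permuting those residuals within
#'   genotype classes of L (preserving the L-C and X-C relations while
#'   breaking the C-T linkage), and recomputing the F for L with each
#'   perturbed mediator. `p4 = (1 + #\{F*_b <= F_obs\}) / (B_cond4 + 1)` is
#'   small when the observed conditional L-T signal is far below what a
#'   non-mediating surrogate of C would leave behind.
#'
#' The marginal and cis-adjusted trans effects (`beta_T` from `T ~ X + L`,
#' `beta_Tadj` from `T ~ X + C + L`) and the mediated proportion
#' `M = (beta_T - beta_Tadj) / beta_T` are reported alongside.
#'
#' @param L dosage vector (non-constant; genotype classes are formed by
#'   rounding to 0/1/2).
#' @param C,T expression vectors for the cis and trans gene.
#' @param covariates optional [covariate_set()] / matrix / NULL.
#' @param B_cond4 permutations for component 4 (default 1000).
#' @param seed RNG seed; identical seeds reproduce all p-values bit-exactly.
#' @param strict_dosage refuse non-integer dosages instead of rounding.
#' @return An object of class `mediation_result` with `p1`..`p4`,
#'   `p_omnibus`, `beta_T`, `se_T`, `beta_Tadj`, `se_Tadj`, `M`, `B_cond4`,
#'   `n`, and the genotype class table.
#' @export
cit_test <- function(L, C, T, covariates = NULL, B_cond4 = 1000,
                     seed = NULL, strict_dosage = FALSE) {
  n <- length(L)
  stopifnot(length(C) == n, length(T) == n)
  if (var(L) == 0) stop("L is constant")
  if (var(C) == 0 || var(T) == 0) stop("constant C or T")
  cls <- .geno_classes(L, strict = strict_dosage)
  if (nlevels(cls) < 2)
    stop("genotype strata impossible: all samples in one class")
  X <- if (is.null(covariates)) NULL
       else if (inherits(covariates, "covariate_set")) covariates$covariates
       else as.matrix(covariates)
  if (!is.null(X) && nrow(X) != n) stop("covariate rows must match samples")
  Z <- cbind(`(Intercept)` = rep(1, n), X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariates")
  if (!is.null(seed)) set.seed(seed)

  f1 <- .partial_f(T, Z, L)                    # T ~ X + L
  f2 <- .partial_f(C, cbind(Z, T = T), L)      # C ~ X + T + L
  f3 <- .partial_f(T, cbind(Z, L = L), C)      # T ~ X + L + C
  fadj <- .partial_f(T, cbind(Z, C = C), L)    # T ~ X + C + L

  # component 4: permutation reference for the conditional L-T signal
  Q <- qr.Q(qz)
  Lr <- L - Q %*% crossprod(Q, L)
  Tr <- T - Q %*% crossprod(Q, T)
  eC <- C - Q %*% crossprod(Q, C)
  df4 <- n - qz$rank - 2
  sll <- sum(Lr^2); stt <- sum(Tr^2); slt <- sum(Lr * Tr)
  f_obs <- .f_second(stt, sum(eC^2), sll, sum(eC * Lr), sum(eC * Tr), slt,
                     df4)
  idx <- .strata_perm_idx(cls, B_cond4)
  E <- matrix(eC[idx], n, B_cond4)
  E <- E - Q %*% crossprod(Q, E)
  scc <- colSums(E^2)
  scl <- drop(crossprod(E, Lr))
  sct <- drop(crossprod(E, Tr))
  f_star <- .f_second(stt, scc, sll, scl, sct, slt, df4)
  p4 <- (1 + sum(f_star <= f_obs)) / (B_cond4 + 1)

  ps <- c(p1 = f1$p, p2 = f2$p, p3 = f3$p, p4 = p4)
  res <- list(p1 = ps[["p1"]], p2 = ps[["p2"]], p3 = ps[["p3"]],
              p4 = ps[["p4"]], p_omnibus = max(ps),
              beta_T = f1$beta, se_T = f1$se,
              beta_Tadj = fadj$beta, se_Tadj = fadj$se,
              M = mediated_proportion(f1$beta, fadj$beta),
              B_cond4 = B_cond4, n = n, classes = table(cls),
              unpermuted_classes = attr(idx, "unpermuted_classes"))
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (n = %d): p_omnibus = %.3g\n", x$n,
              x$p_omnibus))
  cat(sprintf("  components: p1 = %.3g, p2 = %.3g, p3 = %.3g, p4 = %.3g\n",
              x$p1, x$p2, x$p3, x$p4))
  cat(sprintf("  beta_T = %.4g, beta_Tadj = %.4g, M = %.3g\n",
              x$beta_T, x$beta_Tadj, x$M))
  invisible(x)
}

#' Mediated proportion of a trans-eQTL effect
#'
#' `M = (beta_T - beta_Tadj) / beta_T`: the fraction of the marginal trans
#' effect removed by adjusting for the cis gene. M is unbounded in general
#' and is not clamped; `beta_T = 0` leaves it undefined and returns `NA`
#' (the undefined flag) rather than an error.
#'
#' @param beta_T marginal trans-eQTL slope.
#' @param beta_Tadj trans-eQTL slope after adding the cis gene as a
#'   covariate.
#' @return numeric (vectorized); `NA` where `beta_T == 0`.
#' @export
mediated_proportion <- function(beta_T, beta_Tadj) {
  ifelse(beta_T == 0, NA_real_, (beta_T - beta_Tadj) / beta_T)
}

#' Marginal and cis-adjusted trans-eQTL effects
#'
#' Fits `T ~ X + L` and `T ~ X + C + L` and returns both dosage slopes
#' with standard errors, plus the mediated proportion.
#'
#' @inheritParams cit_test
#' @return list with `beta_T`, `se_T`, `p_T`, `beta_Tadj`, `se_Tadj`,
#'   `p_Tadj`, `M`.
#' @export
trans_effect_attenuation <- function(L, C, T, covariates = NULL) {
  n <- length(L)
  stopifnot(length(C) == n, length(T) == n)
  if (var(L) == 0) stop("L is constant")
  X <- if (is.null(covariates)) NULL
       else if (inherits(covariates, "covariate_set")) covariates$covariates
       else as.matrix(covariates)
  Z <- cbind(`(Intercept)` = rep(1, n), X)
  f1 <- .partial_f(T, Z, L)
  fadj <- .partial_f(T, cbind(Z, C = C), L)
  list(beta_T = f1$beta, se_T = f1$se, p_T = f1$p,
       beta_Tadj = fadj$beta, se_Tadj = fadj$se, p_Tadj = fadj$p,
       M = mediated_proportion(f1$beta, fadj$beta))
}

#' Genotype-stratified permutation robustness test
#'
#' Permutes the trans-gene expression across samples only within genotype
#' classes of L (holding L, C and covariates fixed), recomputes the full
#' omnibus mediation p-value for each permuted dataset, and reports
#' `p_perm = (1 + #\{p*_b <= p_obs\}) / (B + 1)` — the proportion of
#' permuted-data p-values as or more extreme than the observed one, with
#' the add-one estimator giving a floor of `1 / (B + 1)`. The component-4
#' mediator permutations are drawn once and reused across the outer
#' permutations, which keeps the randomization scheme identical for every
#' permuted dataset.
#'
#' @inheritParams cit_test
#' @param p_observed observed omnibus p-value; computed internally when
#'   `NULL`.
#' @param B number of outer permutations (>= 1).
#' @param tie `"leq"` (default: "as or more extreme" counts ties) or
#'   `"lt"` (strict).
#' @param chunk outer permutations processed per block (memory control).
#' @return list of class `perm_robustness`: `p_perm`, `B`, `n_extreme`,
#'   `p_observed`, `unpermuted_classes`.
#' @export
permutation_robustness <- function(L, C, T, covariates = NULL,
                                   p_observed = NULL, B = 1000,
                                   B_cond4 = 1000, seed = NULL,
                                   strict_dosage = FALSE,
                                   tie = c("leq", "lt"), chunk = 500L) {
  tie <- match.arg(tie)
  if (B < 1) stop("B must be >= 1")
  n <- length(L)
  stopifnot(length(C) == n, length(T) == n)
  cls <- .geno_classes(L, strict = strict_dosage)
  if (nlevels(cls) < 2)
    stop("genotype strata impossible: all samples in one class")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p_observed)) {
    obs <- cit_test(L, C, T, covariates, B_cond4 = B_cond4,
                    strict_dosage = strict_dosage)
    p_observed <- obs$p_omnibus
  }
  X <- if (is.null(covariates)) NULL
       else if (inherits(covariates, "covariate_set")) covariates$covariates
       else as.matrix(covariates)
  Z <- cbind(`(Intercept)` = rep(1, n), X)
  qz <- qr(Z)
  k1 <- qz$rank                       # intercept + covariates
  Q <- qr.Q(qz)
  Lr <- drop(L - Q %*% crossprod(Q, L))
  Cr <- drop(C - Q %*% crossprod(Q, C))
  sll <- sum(Lr^2); scc <- sum(Cr^2); slc <- sum(Lr * Cr)
  df1 <- n - k1 - 1
  df2 <- n - k1 - 2
  # inner (component-4) mediator permutations, drawn once
  idx4 <- .strata_perm_idx(cls, B_cond4)
  E <- matrix(Cr[idx4], n, B_cond4)
  E <- E - Q %*% crossprod(Q, E)
  e_cc <- colSums(E^2)
  e_cl <- drop(crossprod(E, Lr))

  n_extreme <- 0L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    idxT <- .strata_perm_idx(cls, nb)
    skipped <- attr(idxT, "unpermuted_classes")
    TM <- matrix(T[idxT], n, nb)
    TM <- TM - Q %*% crossprod(Q, TM)
    stt <- colSums(TM^2)
    slt <- drop(crossprod(TM, Lr))
    sct <- drop(crossprod(TM, Cr))
    # p1: F for L in T* ~ X + L
    b1 <- slt / sll
    rss1 <- pmax(stt - b1^2 * sll, 0)
    F1 <- (stt - rss1) / (rss1 / df1)
    p1 <- pf(F1, 1, df1, lower.tail = FALSE)
    # p2: F for L in C ~ X + T* + L (v1 = T*, v2 = L, y = C)
    F2 <- .f_second(scc, stt, sll, slt, sct, slc, df2)
    p2 <- pf(F2, 1, df2, lower.tail = FALSE)
    # p3: F for C in T* ~ X + L + C (v1 = L, v2 = C, y = T*)
    F3 <- .f_second(stt, sll, scc, slc, slt, sct, df2)
    p3 <- pf(F3, 1, df2, lower.tail = FALSE)
    # p4: observed-vs-reference conditional L signal, per permuted T*
    Fobs4 <- .f_second(stt, scc, sll, slc, sct, slt, df2)
    M4 <- crossprod(E, TM)            # B_cond4 x nb
    Fin <- .f_second(rep(stt, each = B_cond4),
                     e_cc, sll, e_cl, M4, rep(slt, each = B_cond4), df2)
    dim(Fin) <- c(B_cond4, nb)
    cnt4 <- colSums(sweep(Fin, 2, Fobs4, `<=`))
    p4 <- (1 + cnt4) / (B_cond4 + 1)
    p_om <- pmax(p1, p2, p3, p4)
    n_extreme <- n_extreme + if (tie == "leq") sum(p_om <= p_observed)
                             else sum(p_om < p_observed)
    done <- done + nb
  }
  structure(list(p_perm = (1 + n_extreme) / (B + 1), B = B,
                 n_extreme = n_extreme, p_observed = p_observed,
                 unpermuted_classes = attr(idx4, "unpermuted_classes")),
            class = "perm_robustness")
}

#' @export
print.perm_robustness <- function(x, ...) {
  cat(sprintf("permutation robustness: p_perm = %.3g (B = %d, %d as or more extreme; observed p = %.3g)\n",
              x$p_perm, x$B, x$n_extreme, x$p_observed))
  invisible(x)
}
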