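#' Genotype matrix container
#'
#' Bundles a sample-by-variant additive dosage matrix with its variant
#' annotation. Dosages are alternate-allele counts or imputed dosages on the
#' \[0, 2\] scale; missing values are not permitted (readers mean-impute at
#' load, see [read_dosage_tsv()]).
#'
#' @param dosage numeric matrix, samples in rows, variants in columns;
#'   rownames are sample identifiers, colnames variant identifiers.
#' @param variants data.frame with one row per column of `dosage`, columns
#'   `id`, `chrom`, `pos` (1-based), and optionally `ref`, `alt`, `maf`.
#' @return An object of class `genotype_matrix` with elements `dosage` and
#'   `variants`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(rownames(dosage))) stop("dosage must have sample rownames")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (!all(c("id", "chrom", "pos") %in% names(variants)))
    stop("variants needs columns id, chrom, pos")
  if (nrow(variants) != ncol(dosage))
    stop("variants rows must match dosage columns")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (!identical(as.character(variants$id), colnames(dosage)))
    stop("variant ids must match dosage column names in order")
  if (anyNA(dosage)) stop("dosage contains missing values after load")
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  if (any(variants$pos <= 0) || any(variants$pos != round(variants$pos)))
    stop("variant positions must be positive integers")
  variants$chrom <- as.character(variants$chrom)
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' Expression matrix container
#'
#' Sample-by-gene continuous expression on a normalized log-like scale,
#' paired with gene coordinates (1-based, inclusive).
#'
#' @param values numeric matrix, samples in rows, genes in columns; rownames
#'   are sample identifiers, colnames gene identifiers.
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`, one
#'   row per column of `values`.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `genes`.
#' @export
expression_matrix <- function(values, genes) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(rownames(values))) stop("values must have sample rownames")
  if (is.null(colnames(values))) colnames(values) <- genes$id
  if (!all(c("id", "chrom", "start", "end") %in% names(genes)))
    stop("genes needs columns id, chrom, start, end")
  if (nrow(genes) != ncol(values)) stop("genes rows must match value columns")
  if (anyDuplicated(genes$id)) stop("gene ids must be unique")
  if (!identical(as.character(genes$id), colnames(values)))
    stop("gene ids must match value column names in order")
  if (anyNA(values)) stop("expression contains missing values")
  ok <- is.na(genes$start) | is.na(genes$end) | genes$start <= genes$end
  if (!all(ok)) stop("gene start must be <= end")
  genes$chrom <- as.character(genes$chrom)
  structure(list(values = values, genes = genes),
            class = "expression_matrix")
}

#' Covariate set container
#'
#' Per-sample adjustment variables (technical covariates, expression
#' principal components). The column space must be full rank after adding an
#' intercept; this is checked at model-fit time so offending columns can be
#' named.
#'
#' @param covariates numeric matrix (samples x covariates) with sample
#'   rownames and covariate colnames; a data.frame is accepted.
#' @return An object of class `covariate_set` wrapping the matrix.
#' @export
covariate_set <- function(covariates) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (ncol(covariates) > 0L && is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  if (is.null(rownames(covariates))) stop("covariates must have sample rownames")
  if (anyNA(covariates)) stop("covariates contain missing values")
  structure(list(covariates = covariates), class = "covariate_set")
}

#' Combine covariate sets column-wise
#'
#' @param ... `covariate_set` objects (or matrices) over identical samples.
#' @return A single `covariate_set`.
#' @export
cbind_covariates <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  mats <- lapply(parts, function(p) if (inherits(p, "covariate_set")) p$covariates else as.matrix(p))
  mats <- Filter(function(m) ncol(m) > 0L, mats)
  if (length(mats) == 0L) stop("no covariates supplied")
  rn <- rownames(mats[[1]])
  for (m in mats) .check_aligned(rn, rownames(m), "covariates")
  covariate_set(do.call(cbind, mats))
}

# internal: covariate_set | matrix | NULL -> plain matrix (possibly 0-col)
.cov_matrix <- function(covariates, samples) {
  if (is.null(covariates))
    return(matrix(0, nrow = length(samples), ncol = 0,
                  dimnames = list(samples, NULL)))
  m <- if (inherits(covariates, "covariate_set")) covariates$covariates
       else as.matrix(covariates)
  .check_aligned(samples, rownames(m), "covariates")
  m
}

.check_aligned <- function(ref, other, what) {
  if (!identical(as.character(ref), as.character(other)))
    stop("sample order of ", what, " does not match; align samples first")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  invisible(x)
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("covariate_set:", nrow(x$covariates), "samples x",
      ncol(x$covariates), "covariates (",
      paste(utils::head(colnames(x$covariates), 8), collapse = ", "),
      if (ncol(x$covariates) > 8) ", ..." else "", ")\n", sep = "")
  invisible(x)
}
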