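# Plain-text readers and writers for the pipeline's standard inputs:
# expression TSV (rows = genes), dosage TSV (rows = variants), BED-like
# gene annotation, variant annotation, truth records, and results tables.

#' Write / read an expression TSV
#'
#' Rows are genes, columns samples, first column `gene_id` — the layout
#' produced by most expression pipelines.
#'
#' @param expression an [expression_matrix()].
#' @param file path.
#' @param annotation for the reader: a gene annotation data.frame (`id`,
#'   `chrom`, `start`, `end`), e.g. from [read_gene_annotation_tsv()].
#' @return the reader returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(expression, file) {
  df <- data.frame(gene_id = colnames(expression$values),
                   t(expression$values), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file, annotation) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(vals) <- df$gene_id
  if (anyNA(vals)) stop("missing expression values are not supported")
  ann <- annotation[match(colnames(vals), annotation$id), ]
  expression_matrix(vals, ann)
}

#' Write / read a dosage TSV
#'
#' Rows are variants, columns samples, first column `variant_id`. Missing
#' dosages are mean-imputed at load, with a message reporting how many.
#'
#' @param genotypes a [genotype_matrix()].
#' @param file path.
#' @param annotation for the reader: a variant annotation data.frame
#'   (`id`, `chrom`, `pos`, ...).
#' @return the reader returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(genotypes, file) {
  df <- data.frame(variant_id = colnames(genotypes$dosage),
                   t(genotypes$dosage), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(file, annotation) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  dose <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(dose) <- df$variant_id
  dose <- .impute_dosage(dose)
  ann <- annotation[match(colnames(dose), annotation$id), ]
  genotype_matrix(dose, ann)
}

.impute_dosage <- function(dose) {
  n_missing <- sum(is.na(dose))
  if (n_missing > 0) {
    message("mean-imputing ", n_missing, " missing dosage value(s)")
    for (j in which(colSums(is.na(dose)) > 0)) {
      m <- mean(dose[, j], na.rm = TRUE)
      dose[is.na(dose[, j]), j] <- m
    }
  }
  dose
}

#' Read dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate
#' alleles from `GT`. Requires the vcfR package.
#'
#' @param file VCF path (plain or gzipped).
#' @return a [genotype_matrix()] (samples x variants).
#' @export
read_dosage_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF needs the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    dm <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dm <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dose <- t(dm)
  colnames(dose) <- ids
  dose <- .impute_dosage(dose)
  ann <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(dose, ann)
}

#' Write / read gene and variant annotation TSVs
#'
#' Gene annotation is BED-like (`id`, `chrom`, `start`, `end`, 1-based
#' inclusive); variant annotation is (`id`, `chrom`, `pos`, `ref`, `alt`).
#'
#' @param genes,variants annotation data.frames.
#' @param file path.
#' @export
write_gene_annotation_tsv <- function(genes, file) {
  write.table(genes[, c("id", "chrom", "start", "end")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_gene_annotation_tsv <- function(file) {
  read.delim(file, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

#' @rdname write_gene_annotation_tsv
#' @export
write_variant_annotation_tsv <- function(variants, file) {
  cols <- intersect(c("id", "chrom", "pos", "ref", "alt", "maf"),
                    names(variants))
  write.table(variants[, cols], file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_variant_annotation_tsv <- function(file) {
  read.delim(file, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

#' Write / read a simulation truth record
#'
#' Flat `key=value` text; the true edge list is serialized as
#' comma-separated `a-b` pairs. Intended for test harnesses.
#'
#' @param truth the `truth` element of [simulate_trio_expression()].
#' @param file path.
#' @export
write_truth_record <- function(truth, file) {
  lines <- c(paste0("variant=", truth$variant),
             paste0("cis_gene=", truth$cis_gene),
             paste0("trans_gene=", truth$trans_gene),
             paste0("a=", truth$a), paste0("b=", truth$b),
             paste0("d=", truth$d),
             paste0("label=", truth$label),
             paste0("edges=", paste(paste0(truth$edges$a, "-", truth$edges$b),
                                    collapse = ",")))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(file) {
  lines <- readLines(file)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
  for (f in c("a", "b", "d")) out[[f]] <- as.numeric(out[[f]])
  if (nzchar(out$edges)) {
    pr <- strsplit(strsplit(out$edges, ",")[[1]], "-", fixed = TRUE)
    out$edges <- data.frame(a = vapply(pr, `[[`, "", 1),
                            b = vapply(pr, `[[`, "", 2),
                            stringsAsFactors = FALSE)
  } else {
    out$edges <- data.frame(a = character(0), b = character(0))
  }
  out
}

#' Write an eQTL record table
#'
#' @param records an `eqtl_records` data.frame.
#' @param file path.
#' @param header optional character vector echoed as `#` comment lines.
#' @export
write_eqtl_tsv <- function(records, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
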