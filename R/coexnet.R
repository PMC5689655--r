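# --- Meinshausen-Buhlmann neighborhood selection -------------------------
#
# Each gene is regressed on all others with an L1 penalty; the support of
# the solution is the gene's candidate neighborhood, and per-lambda graphs
# are formed by OR/AND symmetrization. The per-node lasso is solved by
# coordinate descent with warm starts along the lambda path (glmnet); with
# two genes the single-predictor solution is the closed-form soft threshold
# (support nonzero iff |r| > lambda) and is computed directly.

# column standardization with 1/n variance, matching the lasso objective
# (1/2n)||y - Xb||^2 + lambda ||b||_1 so lambda_max = max |x'y| / n.
.standardize_n <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sds <- sqrt(colMeans(Xc^2))
  if (any(sds == 0))
    stop("constant gene column: ", colnames(X)[which(sds == 0)[1]])
  sweep(Xc, 2, sds, "/")
}

# per-node supports and per-lambda symmetrized edge sets for one data matrix
.mb_fit <- function(X, lambda, rule) {
  n <- nrow(X)
  p <- ncol(X)
  ids <- colnames(X)
  Xs <- .standardize_n(X)
  nl <- length(lambda)
  supports <- lapply(seq_len(nl), function(l) vector("list", p))
  for (j in seq_len(p)) {
    y <- Xs[, j]
    Xj <- Xs[, -j, drop = FALSE]
    if (ncol(Xj) == 1L) {
      r <- sum(Xj[, 1] * y) / n
      for (l in seq_len(nl)) # strict inequality: zero on the KKT boundary
        supports[[l]][[j]] <- if (abs(r) > lambda[l] * (1 + 1e-10))
          colnames(Xj) else character(0)
    } else {
      fit <- glmnet::glmnet(Xj, y, family = "gaussian", lambda = lambda,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-8)
      B <- as.matrix(fit$beta)
      li <- pmin(seq_len(nl), ncol(B)) # guard against early path exit
      for (l in seq_len(nl))
        supports[[l]][[j]] <- rownames(B)[B[, li[l]] != 0]
    }
    for (l in seq_len(nl)) names(supports[[l]])[j] <- ids[j]
  }
  edges <- lapply(supports, symmetrize, rule = rule)
  list(supports = supports, edges = edges)
}

#' Symmetrize per-node neighborhood supports into an undirected edge set
#'
#' Under the `OR` rule (the default, matching the documented behavior of
#' the reference neighborhood-selection implementation) an edge (i, j) is
#' present when either node's regression selected the other; under `AND`
#' both must agree.
#'
#' @param supports named list: for each node, the character vector of
#'   selected neighbor ids.
#' @param rule `"OR"` or `"AND"`.
#' @return data.frame with columns `a`, `b` (node ids, a before b in node
#'   order) and `selected_by` (`"a"`, `"b"`, or `"both"`).
#' @export
symmetrize <- function(supports, rule = c("OR", "AND")) {
  rule <- match.arg(rule)
  ids <- names(supports)
  p <- length(ids)
  M <- matrix(FALSE, p, p, dimnames = list(ids, ids))
  for (j in seq_len(p)) {
    sel <- intersect(supports[[j]], ids)
    M[j, sel] <- TRUE
  }
  keep <- if (rule == "OR") M | t(M) else M & t(M)
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(a = character(0), b = character(0),
                      selected_by = character(0), stringsAsFactors = FALSE))
  by_a <- M[idx]                       # row selected col
  by_b <- t(M)[idx]                    # col selected row
  data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
             selected_by = ifelse(by_a & by_b, "both",
                                  ifelse(by_a, "a", "b")),
             stringsAsFactors = FALSE)
}

#' Neighborhood-selection regularization path
#'
#' Runs Meinshausen-Buhlmann neighborhood selection over a log-spaced
#' lambda grid from `lambda_max` (the smallest penalty at which every
#' neighborhood is empty, `max |cor|` over gene pairs after
#' standardization) down to `lambda_max * lambda_min_ratio`.
#'
#' @param expression an [expression_matrix()] or plain samples x genes
#'   matrix (at least 2 genes, 10 samples); columns are standardized
#'   internally.
#' @param n_lambda number of grid points (default 10).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`
#'   (default 0.1). These defaults mirror the documented defaults of the
#'   reference implementation.
#' @param rule symmetrization rule, see [symmetrize()].
#' @return An object of class `regularization_path`: `lambda` (descending),
#'   `edges` (per-lambda edge data.frames), `supports`, `sparsity`
#'   (fraction of possible pairs present), plus the data needed for
#'   stability selection.
#' @export
neighborhood_selection_path <- function(expression, n_lambda = 10,
                                        lambda_min_ratio = 0.1,
                                        rule = c("OR", "AND")) {
  rule <- match.arg(rule)
  X <- if (inherits(expression, "expression_matrix")) expression$values
       else as.matrix(expression)
  if (ncol(X) < 2) stop("need at least 2 genes")
  if (nrow(X) < 10) stop("need at least 10 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  Xs <- .standardize_n(X)
  S <- crossprod(Xs) / nrow(X)
  diag(S) <- 0
  lambda_max <- max(abs(S))
  if (lambda_max == 0) lambda_max <- 1e-3
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = n_lambda))
  fit <- .mb_fit(X, lambda, rule)
  n_pairs <- choose(ncol(X), 2)
  structure(list(lambda = lambda,
                 edges = fit$edges,
                 supports = fit$supports,
                 sparsity = vapply(fit$edges, nrow, 1L) / n_pairs,
                 genes = colnames(X), X = X, n = nrow(X), rule = rule),
            class = "regularization_path")
}

#' @export
print.regularization_path <- function(x, ...) {
  cat("regularization_path:", length(x$lambda), "lambdas over",
      length(x$genes), "genes;",
      "edge counts:", paste(vapply(x$edges, nrow, 1L), collapse = " "), "\n")
  invisible(x)
}

#' Select a graph along the path by stability (StARS)
#'
#' Re-estimates the neighborhood-selection path on random subsamples (size
#' `floor(10 * sqrt(n))`, capped at `n - 1`, unless `subsample_ratio` is
#' given), measures per-edge instability `2 * xi * (1 - xi)` averaged over
#' all gene pairs (`xi` = edge selection frequency across subsamples), and
#' picks the densest lambda whose total instability is at or below
#' `instability_threshold`; if none qualifies the sparsest lambda is used
#' with a warning. A `lambda_index` override pins the selection for exact
#' experiment reproduction.
#'
#' @param path a [neighborhood_selection_path()] result.
#' @param method only `"stars"` is implemented.
#' @param subsample_ratio optional fraction of samples per subsample;
#'   default `NULL` uses the `10 * sqrt(n)` rule.
#' @param n_subsamples number of subsamples (default 20).
#' @param instability_threshold StARS beta (default 0.1).
#' @param seed RNG seed; selection is deterministic given the seed.
#' @param lambda_index fixed-lambda override (1 = sparsest).
#' @return An object of class `coexpression_graph`: `nodes`, `edges`
#'   (a/b/selected_by/lambda), selected `lambda`, `lambda_index`, and the
#'   per-lambda `instability` profile.
#' @export
select_graph <- function(path, method = "stars", subsample_ratio = NULL,
                         n_subsamples = 20, instability_threshold = 0.1,
                         seed = 1L, lambda_index = NULL) {
  stopifnot(inherits(path, "regularization_path"))
  method <- match.arg(method)
  nl <- length(path$lambda)
  instability <- rep(NA_real_, nl)
  if (is.null(lambda_index)) {
    if (nl == 1L) {
      lambda_index <- 1L
    } else {
      n <- path$n
      b <- if (!is.null(subsample_ratio)) floor(subsample_ratio * n)
           else min(floor(10 * sqrt(n)), n - 1)
      if (b >= n || b < 10) {
        warning("too few samples for stability subsampling; ",
                "falling back to a fixed mid-path lambda")
        lambda_index <- ceiling(nl / 2)
      } else {
        set.seed(seed)
        p <- length(path$genes)
        counts <- array(0, dim = c(p, p, nl))
        for (s in seq_len(n_subsamples)) {
          idx <- sample.int(n, b)
          sub <- .mb_fit(path$X[idx, , drop = FALSE], path$lambda, path$rule)
          for (l in seq_len(nl)) {
            e <- sub$edges[[l]]
            if (nrow(e)) {
              ai <- match(e$a, path$genes); bi <- match(e$b, path$genes)
              counts[cbind(ai, bi, l)] <- counts[cbind(ai, bi, l)] + 1
            }
          }
        }
        n_pairs <- choose(p, 2)
        for (l in seq_len(nl)) {
          xi <- counts[, , l][upper.tri(counts[, , l])] / n_subsamples
          instability[l] <- sum(2 * xi * (1 - xi)) / n_pairs
        }
        ok <- which(instability <= instability_threshold)
        lambda_index <- if (length(ok)) max(ok) else {
          warning("no lambda met the instability threshold; using sparsest")
          1L
        }
      }
    }
  }
  edges <- path$edges[[lambda_index]]
  edges$lambda <- if (nrow(edges)) path$lambda[lambda_index] else numeric(0)
  structure(list(nodes = path$genes, edges = edges,
                 lambda = path$lambda[lambda_index],
                 lambda_index = lambda_index,
                 instability = instability, rule = path$rule, seed = seed),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat("coexpression_graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges at lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Adjacency query
#'
#' @param graph a [select_graph()] result.
#' @param gene gene id (must be a node of the graph).
#' @return character vector of neighboring gene ids (empty for isolated
#'   nodes).
#' @export
neighbors <- function(graph, gene) {
  stopifnot(inherits(graph, "coexpression_graph"))
  if (!gene %in% graph$nodes) stop("unknown gene id: ", gene)
  e <- graph$edges
  sort(unique(c(e$b[e$a == gene], e$a[e$b == gene])))
}

#' Write / read a co-expression graph as a TSV edge list
#'
#' The edge list carries the selected lambda and per-edge provenance
#' (which node's regression selected it); the node list is stored in a
#' commented header line so isolated nodes survive the round trip.
#'
#' @param graph a `coexpression_graph`.
#' @param file path to write to / read from.
#' @return `read_graph_tsv` returns a `coexpression_graph`.
#' @export
write_graph_tsv <- function(graph, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes=", paste(graph$nodes, collapse = ",")), con)
  writeLines(paste0("# lambda=", format(graph$lambda, digits = 17)), con)
  write.table(graph$edges[, c("a", "b", "selected_by", "lambda")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(file) {
  hdr <- readLines(file, n = 2)
  nodes <- strsplit(sub("^# nodes=", "", hdr[1]), ",")[[1]]
  lambda <- as.numeric(sub("^# lambda=", "", hdr[2]))
  edges <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = c(a = "character", b = "character"))
  structure(list(nodes = nodes, edges = edges, lambda = lambda,
                 lambda_index = NA_integer_, instability = NULL,
                 rule = NA_character_, seed = NA_integer_),
            class = "coexpression_graph")
}

#' Export a graph as GraphML (requires igraph)
#'
#' @param graph a `coexpression_graph`.
#' @param file output path.
#' @export
write_graphml <- function(graph, file) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the igraph package")
  g <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
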