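## Delimited-matrix input and JSON/TSV/SIF output.

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a numeric samples x features matrix from delimited text
#'
#' CSV or TSV (inferred from the extension, overridable), optional header
#' row of feature names.  Non-numeric, missing, or non-finite cells are
#' rejected with a located error.  A response can be split off by column
#' name or read from a separate single-column file, yielding a
#' [regression_data].
#'
#' @param path file path.
#' @param response optional column name to use as the response.
#' @param response_file optional path to a single-column response file.
#' @param sep field separator override.
#' @param header logical; first row holds column names.
#' @return numeric matrix, or a [regression_data] when a response is given.
#' @export
read_matrix <- function(path, response = NULL, response_file = NULL,
                        sep = NULL, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = .infer_sep(path, sep), header = header,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  x <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) x <- matrix(x, 1L)
  dimnames(x) <- list(NULL, names(df))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or missing value at row ", bad[1L, 1L], ", column ",
         colnames(x)[bad[1L, 2L]] %||% bad[1L, 2L], " of ", path)
  colnames(x) <- names(df)
  if (!is.null(response_file)) {
    yv <- read_matrix(response_file, sep = sep, header = header)
    if (ncol(yv) != 1L) stop("response file must have a single column")
    return(regression_data(x, drop(yv)))
  }
  if (!is.null(response)) {
    if (!response %in% colnames(x))
      stop("response column '", response, "' not found")
    j <- match(response, colnames(x))
    return(regression_data(x[, -j, drop = FALSE], x[, j]))
  }
  x
}

#' Write a fitted model to JSON
#'
#' Serializes an `l0fit` as a JSON object: `theta` as a name -> value map
#' over the support, plus `lambda`, `p`, `n_iter`, `converged`,
#' `objective`, and the package version.
#'
#' @param fit an `l0fit`.
#' @param path output file path.
#' @param seed optional seed to embed for provenance.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "l0fit"))
  sup <- fit$theta[fit$support]
  obj <- list(theta = as.list(sup),
              support = fit$support,
              lambda = fit$lambda, p = fit$p,
              n_iter = fit$n_iter, converged = fit$converged,
              objective = fit$objective,
              package_version = as.character(packageVersion("l0em")))
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a network to edge-list, SIF, and degree-table files
#'
#' `edges.tsv` (nodeA, nodeB, score), `graph.sif` (Cytoscape simple
#' interaction format; interaction type `pd` for positive-dependency
#' graphs, `assoc` otherwise), `degrees.tsv`, and optionally
#' `graph.graphml` (requires the igraph package).
#'
#' @param graph an `l0graph`.
#' @param outdir output directory (created if missing).
#' @param formats subset of `c("tsv", "sif", "graphml")`.
#' @return character vector of written paths, invisibly.
#' @export
write_graph_files <- function(graph, outdir,
                              formats = c("tsv", "sif")) {
  stopifnot(inherits(graph, "l0graph"))
  formats <- match.arg(formats, c("tsv", "sif", "graphml"),
                       several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- length(graph$node_names)
  up <- which(upper.tri(graph$adjacency) & graph$adjacency != 0,
              arr.ind = TRUE)
  edges <- data.frame(nodeA = graph$node_names[up[, 1L]],
                      nodeB = graph$node_names[up[, 2L]],
                      score = graph$score[up])
  itype <- if (graph$positive_only) "pd" else "assoc"
  written <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(outdir, "edges.tsv")
    write.table(edges, p, sep = "\t", quote = FALSE, row.names = FALSE)
    deg <- data.frame(node = graph$node_names,
                      degree = colSums(graph$adjacency))
    pd <- file.path(outdir, "degrees.tsv")
    write.table(deg, pd, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p, pd)
  }
  if ("sif" %in% formats) {
    p <- file.path(outdir, "graph.sif")
    lines <- if (nrow(edges) > 0)
      paste(edges$nodeA, itype, edges$nodeB)
    else character(0)
    # isolated nodes still appear as single-column SIF rows
    isolated <- graph$node_names[colSums(graph$adjacency) == 0]
    writeLines(c(lines, isolated), p)
    written <- c(written, p)
  }
  if ("graphml" %in% formats) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("graphml export requires the igraph package")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = graph$node_names)
    p <- file.path(outdir, "graph.graphml")
    igraph::write_graph(g, p, format = "graphml")
    written <- c(written, p)
  }
  invisible(written)
}

#' Write an experiment to a replicate table and JSON summary
#'
#' @param experiment an `l0experiment` from [run_experiment()].
#' @param outdir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_experiment_files <- function(experiment, outdir) {
  stopifnot(inherits(experiment, "l0experiment"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pt <- file.path(outdir, "replicates.tsv")
  write.table(experiment$replicates, pt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ps <- file.path(outdir, "summary.json")
  sc <- experiment$scenario
  jsonlite::write_json(
    list(scenario = list(n = sc$n, m = sc$m, r = sc$r, sigma = sc$sigma,
                         theta_true = sc$theta_true),
         seed = experiment$seed,
         summary = experiment$summary),
    ps, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pt, ps))
}

#' Write a cross-validation result to JSON
#'
#' @param cv an `l0cv` from [cross_validate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv <- function(cv, path) {
  stopifnot(inherits(cv, "l0cv"))
  jsonlite::write_json(
    list(lambda = cv$lambda, mse_mean = cv$mse_mean, mse_sd = cv$mse_sd,
         k_mean = cv$k_mean, k_sd = cv$k_sd,
         lambda_mse = cv$lambda_mse, lambda_ss = cv$lambda_ss,
         lambda_opt = cv$lambda_opt, k = cv$k, seed = cv$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
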