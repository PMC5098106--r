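## Neighborhood-selection Gaussian graphical model: each variable is
## regressed on all others with the L0 solver at a fixed (information
## criterion) penalty; nonzero coefficients become edges.  With m variables
## only m regressions are needed -- no cross-validation -- which is what
## makes L0 network construction fast.

#' L0 neighborhood regression of one variable on the rest
#'
#' Minimizes `||x_j - X_{-j} theta||^2 + lambda ||theta||_0` (the solver's
#' 1/2-scaled objective at penalty `lambda`); the nonzero coefficients mark
#' the estimated partial-association neighborhood of variable `j`.
#'
#' @param x samples x variables numeric matrix.
#' @param j target column index.
#' @param lambda fixed penalty; defaults to the `criterion` value.
#' @param criterion `"bic"` (lambda = log n) or `"aic"` (lambda = 2), used
#'   when `lambda` is NULL.
#' @param positive_only constrain coefficients to be nonnegative (clamped
#'   each EM step), modeling positive dependency only.
#' @param solver solve route, see [lpem_fit()].
#' @param ... further solver settings.
#' @return named coefficient vector over the other m - 1 variables.  A
#'   constant target column yields an all-zero vector with a warning.
#' @examples
#' nd <- gen_band_network(100, m = 10, band = 1, seed = 1)
#' fit_neighborhood(nd$x, 5, criterion = "aic")
#' @export
fit_neighborhood <- function(x, j, lambda = NULL,
                             criterion = c("bic", "aic"),
                             positive_only = FALSE, solver = "auto", ...) {
  x <- as.matrix(x)
  m <- ncol(x)
  stopifnot(m >= 2L, j >= 1L, j <= m)
  criterion <- match.arg(criterion)
  lambda <- lambda %||% info_criterion_lambda(criterion, n = nrow(x), m = m)
  if (sd(x[, j]) == 0) {
    warning("target column ", j, " is constant; empty neighborhood")
    out <- numeric(m - 1L)
    names(out) <- colnames(x)[-j] %||% paste0("V", seq_len(m))[-j]
    return(out)
  }
  fit <- .em_fit(x[, -j, drop = FALSE], x[, j], lambda, mode = solver,
                 positive_only = positive_only, ...)
  fit$theta
}

#' Build a coexpression/association network by L0 neighborhood selection
#'
#' Runs [fit_neighborhood()] for every variable and assembles the directed
#' coefficients into an undirected graph: under the default OR rule, an
#' edge i--j is present when either regression selects the other variable
#' (AND requires both).  Pairs are scored by the symmetrized absolute
#' coefficient magnitude `max(|W[j,i]|, |W[i,j]|)` for ROC ranking.
#'
#' @inheritParams fit_neighborhood
#' @param symmetrization `"or"` (default) or `"and"`.
#' @return an object of class `l0graph`: list with `weights` (m x m, row j
#'   holding the regression coefficients of variable j on the others, zero
#'   diagonal), `adjacency` (symmetric binary), `score` (symmetric
#'   nonnegative), `node_names`, `symmetrization`, `lambda`, `criterion`.
#' @examples
#' nd <- gen_band_network(100, m = 15, band = 1, seed = 1)
#' g <- build_network(nd$x, criterion = "aic")
#' sum(g$adjacency) / 2
#' @export
build_network <- function(x, criterion = c("bic", "aic"), lambda = NULL,
                          positive_only = FALSE,
                          symmetrization = c("or", "and"),
                          solver = "auto", ...) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  stopifnot(m >= 2L)
  criterion <- if (is.null(lambda)) match.arg(criterion) else NULL
  symmetrization <- match.arg(symmetrization)
  lambda <- lambda %||% info_criterion_lambda(criterion, n = n, m = m)
  nms <- colnames(x) %||% paste0("V", seq_len(m))
  colnames(x) <- nms

  # all inner products come from one Gram matrix; each regression solves on
  # the submatrix with row/column j removed
  gram <- crossprod(x)
  W <- matrix(0, m, m, dimnames = list(nms, nms))
  for (j in seq_len(m)) {
    if (sd(x[, j]) == 0) {
      warning("column ", j, " is constant; empty neighborhood")
      next
    }
    fit <- .em_fit(x[, -j, drop = FALSE], x[, j], lambda, mode = solver,
                   positive_only = positive_only,
                   gram = gram[-j, -j, drop = FALSE],
                   xty = gram[-j, j], ...)
    W[j, -j] <- fit$theta
  }

  nz <- W != 0
  adjacency <- if (symmetrization == "or") (nz | t(nz)) else (nz & t(nz))
  adjacency <- matrix(as.integer(adjacency), m, m,
                      dimnames = dimnames(W))
  score <- pmax(abs(W), t(abs(W)))
  diag(score) <- 0
  structure(list(weights = W, adjacency = adjacency, score = score,
                 node_names = nms, symmetrization = symmetrization,
                 lambda = lambda, criterion = criterion,
                 positive_only = positive_only),
            class = "l0graph")
}

#' @export
print.l0graph <- function(x, ...) {
  cat(sprintf(
    "l0graph: %d nodes, %d edges (%s rule, lambda = %.4g%s%s)\n",
    length(x$node_names), sum(x$adjacency) / 2L, toupper(x$symmetrization),
    x$lambda,
    if (!is.null(x$criterion)) paste0(", ", toupper(x$criterion)) else "",
    if (x$positive_only) ", positive-only" else ""))
  invisible(x)
}

# Tied-rank (Mann-Whitney) AUC: equals the trapezoidal area under the ROC
# curve when tied scores are grouped on one segment.
.rank_auc <- function(score, label) {
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Edge-recovery metrics against a known network structure
#'
#' Scores an estimated graph against the true adjacency over all unordered
#' pairs: AUC from ranking pairs by `score` (tied-rank/trapezoidal; all
#' exact-zero pairs tie at 0), edge false-discovery rate (false selected
#' edges / selected edges) and false-negative rate (missed true edges /
#' true edges), both in percent.
#'
#' @param graph an `l0graph` from [build_network()].
#' @param truth binary symmetric m x m adjacency with zero diagonal.
#' @return list of class `structure_metrics`: `auc`, `fdr` (%), `fnr` (%),
#'   `n_selected`, `n_true`, and `fdr_defined` (FALSE when no edge was
#'   selected, in which case `fdr` is reported as 0).  `auc` is NA with a
#'   warning when `truth` has no edges.
#' @examples
#' nd <- gen_band_network(200, m = 20, band = 1, seed = 1)
#' g <- build_network(nd$x, criterion = "aic")
#' structure_metrics(g, nd$adjacency)
#' @export
structure_metrics <- function(graph, truth) {
  stopifnot(inherits(graph, "l0graph"))
  truth <- as.matrix(truth)
  m <- length(graph$node_names)
  if (!all(dim(truth) == m)) stop("truth has wrong dimensions")
  if (any(truth != t(truth)) || any(diag(truth) != 0))
    stop("truth must be symmetric with zero diagonal")
  up <- upper.tri(truth)
  lab <- as.integer(truth[up] != 0)
  sel <- graph$adjacency[up] != 0
  n_true <- sum(lab)
  auc <- .rank_auc(graph$score[up], lab)
  if (n_true == 0L) warning("truth has no edges; AUC undefined")
  tp <- sum(sel & lab == 1L)
  fp <- sum(sel & lab == 0L)
  fn <- sum(!sel & lab == 1L)
  fdr_defined <- sum(sel) > 0L
  structure(list(auc = auc,
                 fdr = if (fdr_defined) 100 * fp / sum(sel) else 0,
                 fnr = if (n_true > 0L) 100 * fn / n_true else NA_real_,
                 n_selected = sum(sel), n_true = n_true,
                 fdr_defined = fdr_defined),
            class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | FDR %.2f%%%s | FNR %.2f%% | %d selected / %d true\n",
              x$auc, x$fdr, if (x$fdr_defined) "" else " (no selections)",
              x$fnr, x$n_selected, x$n_true))
  invisible(x)
}

#' Replicate a band-network structure-recovery experiment
#'
#' Generates fresh [gen_band_network()] data per replicate, builds the
#' network at the given criterion, and aggregates [structure_metrics()].
#'
#' @inheritParams gen_band_network
#' @inheritParams build_network
#' @param n_replicates number of replicates.
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @param ... passed to [build_network()].
#' @return list with `replicates` (one row per replicate: auc, fdr, fnr,
#'   n_selected) and `summary` (means and SDs).
#' @examples
#' r <- run_network_experiment(band = 1, n = 100, m = 20,
#'                             criterion = "aic", n_replicates = 2, seed = 1)
#' r$summary$auc_mean
#' @export
run_network_experiment <- function(band, n, m = 100L,
                                   criterion = c("bic", "aic"),
                                   n_replicates = 20L, seed = NULL, ...) {
  criterion <- match.arg(criterion)
  seeds <- child_seeds(seed, n_replicates)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    nd <- gen_band_network(n, m = m, band = band, seed = seeds[i])
    g <- build_network(nd$x, criterion = criterion, ...)
    sm <- structure_metrics(g, nd$adjacency)
    rows[[i]] <- data.frame(rep = i, seed = seeds[i], auc = sm$auc,
                            fdr = sm$fdr, fnr = sm$fnr,
                            n_selected = sm$n_selected)
  }
  reps <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)
  list(replicates = reps,
       summary = list(auc_mean = mean(reps$auc), auc_sd = sd0(reps$auc),
                      fdr_mean = mean(reps$fdr), fdr_sd = sd0(reps$fdr),
                      fnr_mean = mean(reps$fnr), fnr_sd = sd0(reps$fnr),
                      n_replicates = n_replicates),
       band = band, n = n, m = m, criterion = criterion)
}
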