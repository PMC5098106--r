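## Selection of the penalty weight lambda: log-spaced grids anchored at the
## null-model threshold, k-fold cross-validation on test MSE, stability
## selection on support-size consistency, the combined max rule, and fixed
## information-criterion values.

#' Log-spaced lambda grid anchored at the null-model threshold
#'
#' The upper endpoint is `lambda_max = max_j (x_j' y)^2 / (4 x_j' x_j)`:
#' above it the L0 EM iteration admits no nontrivial fixed point for any
#' single feature, so the fitted support is empty.  Values are equally
#' log-spaced from `lam_min` up to `lambda_max` and returned in descending
#' order.
#'
#' @inheritParams l0em_fit
#' @param n_points number of grid values (default 100).
#' @param lam_min lower endpoint (default 1e-4).
#' @return descending numeric vector of length `n_points` with attribute
#'   `lambda_max`; both endpoints appear exactly.
#' @examples
#' lambda_grid(matrix(c(1, 0), 2, 1), c(2, 0), n_points = 3, lam_min = 1e-4)
#' @export
lambda_grid <- function(x, y = NULL, n_points = 100L, lam_min = 1e-4) {
  d <- as_xy(x, y)
  stopifnot(n_points >= 1L, lam_min > 0)
  css <- colSums(d$x^2)
  if (all(css == 0)) stop("all columns of x are zero")
  ok <- css > 0
  lam_max <- max(drop(crossprod(d$x[, ok, drop = FALSE], d$y))^2 /
                   (4 * css[ok]))
  if (lam_max <= lam_min)
    stop("lambda_max (", signif(lam_max, 4), ") <= lam_min (", lam_min, ")")
  v <- exp(seq(log(lam_min), log(lam_max), length.out = n_points))
  v[1L] <- lam_min
  v[n_points] <- lam_max
  structure(rev(v), lambda_max = lam_max)
}

#' Fixed information-criterion values for the L0 penalty weight
#'
#' With an L0 penalty the classical model-selection criteria correspond to
#' fixed penalty weights: AIC gives `lambda = 2`, BIC `log n`, RIC
#' `2 log m` (natural logarithms).  No cross-validation is needed.
#'
#' @param criterion one of `"aic"`, `"bic"`, `"ric"` (case-insensitive).
#' @param n sample count (used by BIC).
#' @param m feature count (used by RIC).
#' @return scalar lambda.
#' @examples
#' info_criterion_lambda("bic", n = 100)  # log(100)
#' @export
info_criterion_lambda <- function(criterion, n = NULL, m = NULL) {
  criterion <- match.arg(tolower(criterion), c("aic", "bic", "ric"))
  switch(criterion,
         aic = 2,
         bic = {
           stopifnot(!is.null(n), n >= 2)
           log(n)
         },
         ric = {
           stopifnot(!is.null(m), m >= 1)
           2 * log(m)
         })
}

#' Stability-selection lambda from cross-validated support sizes
#'
#' Picks the smallest lambda at which every fold selects the same number of
#' nonzero coefficients (SD of support sizes across folds equal to zero).
#' If no grid value attains SD = 0, falls back to the lambda minimizing the
#' SD, breaking ties toward the larger (sparser) lambda.
#'
#' @param k_counts folds x lambda integer matrix of support sizes.
#' @param lambda penalty grid matching the columns of `k_counts`.
#' @return the selected lambda (scalar).
#' @examples
#' counts <- rbind(c(4, 3, 3), c(5, 3, 3), c(3, 3, 3))
#' stability_select(counts, lambda = c(1.0, 0.5, 0.1))  # 0.5
#' @export
stability_select <- function(k_counts, lambda) {
  k_counts <- as.matrix(k_counts)
  if (ncol(k_counts) != length(lambda))
    stop("ncol(k_counts) must equal length(lambda)")
  sds <- apply(k_counts, 2L, function(v) if (length(v) < 2L) 0 else sd(v))
  stable <- sds == 0
  if (any(stable)) return(min(lambda[stable]))
  cand <- lambda[sds == min(sds)]
  max(cand)
}

#' k-fold cross-validation with test-MSE and stability selection
#'
#' For each lambda on the grid and each of `k` seeded folds, fits the EM
#' solver on the training part (cold-started from the ridge solution at
#' that lambda) and records the held-out MSE and the fitted support size.
#' Three selections are reported: `lambda_mse` minimizing the mean test MSE,
#' `lambda_ss` from [stability_select()], and the combined rule
#' `lambda_opt = max(lambda_mse, lambda_ss)`, which empirically gives the
#' most reliable support recovery.
#'
#' @inheritParams l0em_fit
#' @param lambda optional descending penalty grid; defaults to
#'   [lambda_grid()] on the full data.
#' @param k number of folds (default 5).
#' @param n_points,lam_min grid parameters when `lambda` is NULL.
#' @param seed integer seed for the fold partition (uniform random, no
#'   stratification); NULL uses the current RNG stream.
#' @param p penalty exponent (0 = L0).
#' @param solver `"auto"`, `"primal"`, or `"dual"` solve route.
#' @param ... further solver settings passed on (`tol`, `max_iter`,
#'   `zero_eps`, `positive_only`).
#' @return an object of class `l0cv`: list with the grid (`lambda`), per-fold
#'   matrices `mse` and `k_counts` (folds x lambda), per-lambda summaries
#'   `mse_mean`, `mse_sd`, `k_mean`, `k_sd`, the selections `lambda_mse`,
#'   `lambda_ss`, `lambda_opt`, and the `fold` assignment.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 10), 100, 10)
#' y <- drop(x %*% c(2, -3, 0, 0, 4, rep(0, 5))) + rnorm(100)
#' cv <- cross_validate(x, y, k = 5, n_points = 25, seed = 42)
#' cv$lambda_opt
#' @export
cross_validate <- function(x, y = NULL, lambda = NULL, k = 5L,
                           n_points = 100L, lam_min = 1e-4, seed = NULL,
                           p = 0, solver = "auto", ...) {
  d <- as_xy(x, y)
  n <- nrow(d$x); m <- ncol(d$x)
  stopifnot(k >= 2L, n >= k)
  if (is.null(lambda))
    lambda <- lambda_grid(d$x, d$y, n_points = n_points, lam_min = lam_min)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  nl <- length(lambda)
  if (nl == 0L) stop("empty lambda grid")

  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  if (min(tabulate(fold, k)) < 2L) stop("a fold has fewer than 2 samples")

  mse_mat <- matrix(NA_real_, k, nl)
  k_mat <- matrix(NA_integer_, k, nl)
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- d$x[tr, , drop = FALSE]; ytr <- d$y[tr]
    xte <- d$x[!tr, , drop = FALSE]; yte <- d$y[!tr]
    gram <- if (m <= 2000L) crossprod(xtr)
    xty <- drop(crossprod(xtr, ytr))
    xxt <- if (m > nrow(xtr)) tcrossprod(xtr)
    for (l in seq_len(nl)) {
      fit <- .em_fit(xtr, ytr, lambda[l], p = p, mode = solver,
                     gram = gram, xty = xty, xxt = xxt, ...)
      mse_mat[f, l] <- mean((yte - drop(xte %*% fit$theta))^2)
      k_mat[f, l] <- length(fit$support)
    }
  }

  mse_mean <- colMeans(mse_mat)
  lambda_mse <- lambda[which.min(mse_mean)]  # ties resolve to larger lambda
  lambda_ss <- stability_select(k_mat, lambda)
  structure(list(lambda = lambda,
                 mse = mse_mat, k_counts = k_mat,
                 mse_mean = mse_mean,
                 mse_sd = apply(mse_mat, 2L, sd),
                 k_mean = colMeans(k_mat),
                 k_sd = apply(k_mat, 2L, sd),
                 lambda_mse = lambda_mse,
                 lambda_ss = lambda_ss,
                 lambda_opt = max(lambda_mse, lambda_ss),
                 fold = fold, k = k, p = p, seed = seed),
            class = "l0cv")
}

#' @export
print.l0cv <- function(x, ...) {
  cat(sprintf("l0cv: %d-fold CV over %d lambda values in [%.3g, %.3g]\n",
              x$k, length(x$lambda), min(x$lambda), max(x$lambda)))
  cat(sprintf("  lambda_mse = %.4g (mean test MSE %.4f)\n",
              x$lambda_mse, min(x$mse_mean)))
  cat(sprintf("  lambda_ss  = %.4g\n  lambda_opt = %.4g\n",
              x$lambda_ss, x$lambda_opt))
  invisible(x)
}

#' Regularization path over a lambda grid
#'
#' Fits the solver at every grid value, by default cold-starting each fit
#' from the ridge solution at its own lambda.  Warm starts are available as
#' an opt-in mode: the previous solution is carried down the grid, but
#' because exact zeros are absorbing in the EM, zeroed coordinates are
#' re-inflated from the ridge solution at the current lambda so they can
#' re-enter as the penalty relaxes.
#'
#' @inheritParams cross_validate
#' @param warm_start logical; see Details above.
#' @param zero_eps hard-zero threshold, also the re-inflation magnitude
#'   under warm starts.
#' @return an object of class `l0path`: list with `lambda` (descending),
#'   `coefficients` (m x n_lambda matrix), `support_size`, `objective`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 40, 5)
#' y <- drop(x %*% c(2, -3, 0, 0, 4)) + rnorm(40)
#' path <- fit_path(x, y, n_points = 10)
#' path$support_size
#' @export
fit_path <- function(x, y = NULL, lambda = NULL, n_points = 100L,
                     lam_min = 1e-4, p = 0, solver = "auto",
                     warm_start = FALSE, zero_eps = 1e-6, ...) {
  d <- as_xy(x, y)
  n <- nrow(d$x); m <- ncol(d$x)
  if (is.null(lambda))
    lambda <- lambda_grid(d$x, d$y, n_points = n_points, lam_min = lam_min)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  nl <- length(lambda)
  gram <- if (m <= 2000L) crossprod(d$x)
  xty <- drop(crossprod(d$x, d$y))
  xxt <- if (m > n) tcrossprod(d$x)
  co <- matrix(0, m, nl, dimnames = list(colnames(d$x), signif(lambda, 4)))
  obj <- numeric(nl)
  prev <- NULL
  for (l in seq_len(nl)) {
    init <- if (warm_start && !is.null(prev)) {
      ridge <- .ridge_solve(d$x, d$y, max(lambda[l], 1e-8), gram = gram,
                            xty = xty, xxt = xxt)
      ifelse(prev != 0, prev, ridge)
    } else "ridge"
    fit <- .em_fit(d$x, d$y, lambda[l], p = p, mode = solver, init = init,
                   zero_eps = zero_eps, gram = gram, xty = xty, xxt = xxt,
                   ...)
    co[, l] <- fit$theta
    obj[l] <- fit$objective
    prev <- fit$theta
  }
  structure(list(lambda = lambda, coefficients = co,
                 support_size = unname(colSums(co != 0)), objective = obj,
                 p = p),
            class = "l0path")
}

#' @export
print.l0path <- function(x, ...) {
  cat(sprintf("l0path: %d lambda values, support sizes %d..%d\n",
              length(x$lambda), min(x$support_size), max(x$support_size)))
  invisible(x)
}
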