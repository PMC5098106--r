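## Core EM fixed-point solvers for Lp-penalized least squares.
##
## The L0-penalized objective is
##   E(theta) = 1/2 ||y - X theta||^2 + lambda/2 * ||theta||_0 .
## Writing the penalty as lambda/2 * sum_j theta_j^2 / eta_j^2 with the
## auxiliary vector eta and alternating
##   M-step: theta <- (D X'X + lambda I)^-1 D X' y,   D = diag(eta^2)
##   E-step: eta <- theta
## gives a fixed-point iteration whose limits are stationary points of E.
## The dual identity  (D X'X + lambda I_m)^-1 D X' = D X' (X D X' + lambda I_n)^-1
## turns the m x m solve into an n x n solve for wide (n << m) problems.
## For general p in [0,2] the weight matrix is D = diag(|eta|^(2-p)); p = 1
## reproduces lasso stationary points (penalty lambda*||theta||_1) and p = 2
## is plain ridge.

.mode_code <- function(mode) {
  switch(match.arg(mode, c("auto", "primal", "dual")),
         auto = 0L, primal = 1L, dual = 2L)
}

.check_settings <- function(lambda, p, tol, max_iter, zero_eps) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            is.numeric(p), length(p) == 1L, p >= 0, p <= 2,
            tol > 0, max_iter >= 1L, zero_eps >= 0)
}

# Ridge solve (1/2||y - X theta||^2 + lambda/2 ||theta||^2), through the
# n x n dual system when m > n.  gram/xty/xxt are optional precomputed
# crossprod(x), crossprod(x, y), tcrossprod(x).
.ridge_solve <- function(x, y, lambda, gram = NULL, xty = NULL, xxt = NULL) {
  n <- nrow(x); m <- ncol(x)
  if (m <= n) {
    g <- gram %||% crossprod(x)
    z <- xty %||% drop(crossprod(x, y))
    diag(g) <- diag(g) + lambda
    drop(solve(g, z))
  } else {
    k <- xxt %||% tcrossprod(x)
    diag(k) <- diag(k) + lambda
    drop(crossprod(x, solve(k, y)))
  }
}

#' Ridge-regression initializer
#'
#' Minimizes 1/2||y - X theta||^2 + (lambda/2)||theta||^2, switching to the
#' equivalent n x n dual system when m > n.  Used as the default nonzero
#' starting point for the EM solvers (the all-zero vector is a trivial fixed
#' point of the iteration and must be avoided).
#'
#' @param x design matrix (or a [regression_data] object).
#' @param y response vector (ignored when `x` is a `regression_data`).
#' @param lambda ridge penalty, must be > 0.
#' @return numeric coefficient vector of length `ncol(x)`.
#' @examples
#' ridge_init(diag(5), rep(1, 5), lambda = 1)  # all 0.5
#' @export
ridge_init <- function(x, y = NULL, lambda) {
  d <- as_xy(x, y)
  stopifnot(lambda > 0)
  theta <- .ridge_solve(d$x, d$y, lambda)
  names(theta) <- colnames(d$x)
  theta
}

# Shared driver behind l0em_fit / dl0em_fit / lpem_fit and the selection /
# network code (which passes cached Gram pieces).
.em_fit <- function(x, y, lambda, p = 0, mode = "auto", tol = 1e-8,
                    max_iter = 500L, zero_eps = 1e-6, init = "ridge",
                    positive_only = FALSE, gram = NULL, xty = NULL,
                    xxt = NULL) {
  .check_settings(lambda, p, tol, max_iter, zero_eps)
  n <- nrow(x); m <- ncol(x)
  user_init <- is.numeric(init)
  if (user_init) {
    theta0 <- as.numeric(init)
    if (length(theta0) != m) stop("init vector must have length ncol(x)")
    if (all(theta0 == 0))
      stop("trivial fixed point: all-zero initialization")
  } else {
    if (!identical(init, "ridge")) stop("init must be \"ridge\" or a vector")
    if (lambda > 0) {
      theta0 <- .ridge_solve(x, y, lambda, gram = gram, xty = xty, xxt = xxt)
    } else {
      # unpenalized start: small ridge keeps the init well-defined for m > n
      theta0 <- .ridge_solve(x, y, max(1e-8, lambda), gram = gram, xty = xty,
                             xxt = xxt)
    }
  }
  g <- if (is.null(gram)) matrix(0, 0, 0) else gram
  z <- if (is.null(xty)) numeric(0) else xty
  res <- .em_engine_cpp(x, y, lambda, p, tol, as.integer(max_iter), zero_eps,
                        theta0, positive_only, .mode_code(mode), g, z)
  theta <- drop(res$theta)
  names(theta) <- colnames(x)
  structure(list(theta = theta,
                 support = unname(which(theta != 0)),
                 lambda = lambda, p = p,
                 n_iter = res$n_iter,
                 converged = res$converged,
                 objective = .pen_objective(x, y, theta, lambda, p),
                 positive_only = positive_only,
                 mode = mode),
            class = "l0fit")
}

#' L0-penalized regression by primal EM fixed-point iteration
#'
#' Approximately minimizes `1/2 ||y - X theta||^2 + lambda/2 ||theta||_0`
#' by iterating a reweighted m x m ridge solve restricted to the active
#' support; coefficients falling below `zero_eps` in absolute value are set
#' to exact zero and never re-enter.  Initialization defaults to the ridge
#' solution at the same `lambda` (an all-zero start is a trivial fixed
#' point and is rejected).
#'
#' @param x design matrix (or a [regression_data]); assumed already on a
#'   common scale (see `standardize`).
#' @param y response vector.
#' @param lambda nonnegative penalty; common fixed choices are
#'   [info_criterion_lambda()] values (AIC 2, BIC log n, RIC 2 log m).
#' @param tol convergence tolerance on the max-abs coefficient change.
#' @param max_iter iteration cap; convergence typically needs far fewer
#'   (under one hundred) iterations.
#' @param zero_eps hard-zero threshold.
#' @param init `"ridge"` or a user numeric start vector.
#' @param positive_only clamp negative coefficients to zero after every
#'   M-step (positive-dependency constraint used in network mode).
#' @param center center columns of x and y before fitting (model has no
#'   intercept by default).
#' @param standardize scale columns of x to unit SD before fitting;
#'   coefficients are reported on the original scale.
#' @return an object of class `l0fit`: list with `theta` (named, length m),
#'   `support` (indices of nonzeros), `lambda`, `p`, `n_iter`, `converged`,
#'   and `objective` (the penalized objective at `theta`).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 60, 5)
#' y <- drop(x %*% c(2, -3, 0, 0, 4)) + rnorm(60)
#' fit <- l0em_fit(x, y, lambda = log(60))
#' fit$support   # 1 2 5
#' @seealso [dl0em_fit()] for the dual (n x n) form, [lpem_fit()] for
#'   general p.
#' @export
l0em_fit <- function(x, y = NULL, lambda, tol = 1e-8, max_iter = 500L,
                     zero_eps = 1e-6, init = "ridge", positive_only = FALSE,
                     center = FALSE, standardize = FALSE) {
  d <- as_xy(x, y)
  pre <- .preprocess(d$x, d$y, center, standardize)
  fit <- .em_fit(pre$x, pre$y, lambda, p = 0, mode = "primal", tol = tol,
                 max_iter = max_iter, zero_eps = zero_eps, init = init,
                 positive_only = positive_only)
  .postprocess(fit, pre)
}

#' L0-penalized regression by dual EM fixed-point iteration (n << m)
#'
#' Same contract and results as [l0em_fit()], but every M-step solves the
#' n x n dual system `theta = D X'(X D X' + lambda I_n)^-1 y`, which is much
#' cheaper when the active support is larger than the sample count.  The two
#' routes are algebraically identical and agree to solver tolerance.
#'
#' @inheritParams l0em_fit
#' @return an `l0fit` object; see [l0em_fit()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(10 * 200), 10, 200)
#' y <- drop(x[, 1:2] %*% c(3, -4))
#' dl0em_fit(x, y, lambda = log(10))$support
#' @export
dl0em_fit <- function(x, y = NULL, lambda, tol = 1e-8, max_iter = 500L,
                      zero_eps = 1e-6, init = "ridge", positive_only = FALSE,
                      center = FALSE, standardize = FALSE) {
  d <- as_xy(x, y)
  pre <- .preprocess(d$x, d$y, center, standardize)
  fit <- .em_fit(pre$x, pre$y, lambda, p = 0, mode = "dual", tol = tol,
                 max_iter = max_iter, zero_eps = zero_eps, init = init,
                 positive_only = positive_only)
  .postprocess(fit, pre)
}

#' Lp-penalized regression, p in \[0, 2\], by reweighted EM iteration
#'
#' Generalizes the L0 solver with weight matrix `D = diag(|eta|^(2-p))`.
#' `p = 0` is identical to [l0em_fit()]; `p = 2` gives `D = I`, so the first
#' iteration returns the ridge solution, which is a fixed point; `p = 1`
#' converges to lasso stationary points for the penalty
#' `lambda * ||theta||_1` (note the factor: the quadratic surrogate
#' `(lambda/2) theta^2/|eta|` has gradient `lambda*sign(theta)` at
#' `eta = theta`).
#'
#' @inheritParams l0em_fit
#' @param p penalty exponent in \[0, 2\].
#' @param mode `"auto"` (default), `"primal"`, or `"dual"` solve route.
#' @return an `l0fit` object; `objective` is
#'   `1/2 ||y - X theta||^2 + (lambda/2) sum |theta_j|^p` (with `0^0 = 0`).
#' @examples
#' x <- diag(4); y <- c(3, 2, 0.2, 1)
#' lpem_fit(x, y, lambda = 1, p = 2)$theta  # ridge: y / 2
#' @export
lpem_fit <- function(x, y = NULL, lambda, p = 0, mode = "auto", tol = 1e-8,
                     max_iter = 500L, zero_eps = 1e-6, init = "ridge",
                     positive_only = FALSE, center = FALSE,
                     standardize = FALSE) {
  d <- as_xy(x, y)
  pre <- .preprocess(d$x, d$y, center, standardize)
  fit <- .em_fit(pre$x, pre$y, lambda, p = p, mode = mode, tol = tol,
                 max_iter = max_iter, zero_eps = zero_eps, init = init,
                 positive_only = positive_only)
  .postprocess(fit, pre)
}

.preprocess <- function(x, y, center, standardize) {
  centers <- NULL; scales <- NULL; ybar <- 0
  if (center) {
    centers <- colMeans(x)
    x <- sweep(x, 2L, centers)
    ybar <- mean(y)
    y <- y - ybar
  }
  if (standardize) {
    scales <- apply(x, 2L, stats::sd)
    if (any(scales == 0)) stop("cannot standardize a constant column")
    x <- sweep(x, 2L, scales, "/")
  }
  list(x = x, y = y, centers = centers, scales = scales, ybar = ybar)
}

.postprocess <- function(fit, pre) {
  if (!is.null(pre$scales)) {
    fit$theta <- fit$theta / pre$scales
    fit$support <- unname(which(fit$theta != 0))
  }
  if (!is.null(pre$centers))
    fit$intercept <- pre$ybar - sum(pre$centers * fit$theta)
  fit
}

# Penalized objective; |0|^0 taken as 0 so p = 0 counts the support.
.pen_objective <- function(x, y, theta, lambda, p = 0) {
  rss <- sum((y - drop(x %*% theta))^2)
  nz <- theta[theta != 0]
  pen <- if (p == 0) length(nz) else sum(abs(nz)^p)
  0.5 * rss + 0.5 * lambda * pen
}

#' L0-penalized objective value
#'
#' `1/2 ||y - X theta||^2 + (lambda/2) * #\{j : theta_j != 0\}`.
#'
#' @inheritParams l0em_fit
#' @param theta coefficient vector of length `ncol(x)`.
#' @return scalar objective value (>= 0).
#' @examples
#' l0_objective(diag(3), rep(1, 3), c(0, 0, 0), lambda = 2)  # 1.5
#' @export
l0_objective <- function(x, y = NULL, theta, lambda) {
  d <- as_xy(x, y)
  if (length(theta) != ncol(d$x)) stop("theta has wrong length")
  .pen_objective(d$x, d$y, theta, lambda, p = 0)
}

#' Contraction diagnostic for the EM fixed-point map
#'
#' Evaluates the sufficient-condition bound for local contraction of the
#' iteration at `theta`:
#' `gamma = 2 lambda ||(D X'X + lambda I)^-2||_inf * ||D X' y||_inf` with
#' `D = diag(theta^2)`.  The iteration map has infinity-norm derivative
#' bounded by `gamma`, so `gamma < 1` guarantees convergence to a unique
#' nearby fixed point.  Purely diagnostic: the solvers run regardless.
#'
#' @inheritParams l0_objective
#' @return list with `gamma_bound` and logical `satisfied`
#'   (`gamma_bound < 1`).
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' check_contraction(x, rnorm(8), rep(0, 5), lambda = 1)$satisfied  # TRUE
#' @export
check_contraction <- function(x, y = NULL, theta, lambda) {
  d <- as_xy(x, y)
  m <- ncol(d$x)
  if (length(theta) != m) stop("theta has wrong length")
  D <- theta^2
  A <- D * crossprod(d$x)           # D X'X (row scaling)
  diag(A) <- diag(A) + lambda
  Ainv <- solve(A)
  norm_inf <- norm(Ainv %*% Ainv, type = "I")
  b <- max(abs(D * drop(crossprod(d$x, d$y))))
  gamma <- 2 * lambda * norm_inf * b
  list(gamma_bound = gamma, satisfied = gamma < 1)
}

#' Hard-threshold small coefficients to exact zero
#'
#' @param theta coefficient vector.
#' @param zero_eps threshold; entries with `|theta_j| < zero_eps` become 0.
#' @return thresholded vector.
#' @examples
#' prune(c(1e-9, 0.5, -1e-7), 1e-6)
#' @export
prune <- function(theta, zero_eps) {
  stopifnot(zero_eps >= 0)
  theta[abs(theta) < zero_eps] <- 0
  theta
}

#' @export
print.l0fit <- function(x, ...) {
  cat(sprintf(
    "l0fit (p = %g, lambda = %.4g): %d nonzero of %d coefficients\n",
    x$p, x$lambda, length(x$support), length(x$theta)))
  cat(sprintf("  objective %.4f | %d iterations | %sconverged\n",
              x$objective, x$n_iter, if (x$converged) "" else "NOT "))
  if (length(x$support) > 0 && length(x$support) <= 20) {
    cat("  support:\n")
    print(x$theta[x$support])
  }
  invisible(x)
}

#' Extract coefficients from an l0fit
#' @param object an `l0fit`.
#' @param ... unused.
#' @return named numeric vector of all m coefficients.
#' @export
coef.l0fit <- function(object, ...) object$theta
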