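## Seeded generators for the synthetic study designs: AR(1)-correlated
## Gaussian feature matrices, sparse linear responses, and banded-precision
## network data.  All generators are pure functions of their parameters and
## seed; the caller's RNG state is untouched when a seed is supplied.

#' Describe a sparse-regression simulation scenario
#'
#' Defaults encode the reference design: n = 100 samples, AR(1)-correlated
#' standard-normal features with correlation `r`, true model
#' `y = 2 x1 - 3 x2 + 4 x5 + eps`, `eps ~ N(0, 1)`.
#'
#' @param n sample count.
#' @param m feature count (>= 5 for the default coefficients).
#' @param r AR(1) correlation between features, `Sigma_ij = r^|i-j|`,
#'   `0 <= r < 1`.
#' @param theta_true true coefficient vector (default 2, -3, 4 at
#'   positions 1, 2, 5, zero elsewhere).
#' @param sigma noise SD (> 0).
#' @param seed integer seed, or NULL.
#' @return list of class `sim_scenario`.
#' @examples
#' sim_scenario(n = 100, m = 50, r = 0.3, seed = 1)
#' @export
sim_scenario <- function(n = 100L, m = 50L, r = 0, theta_true = NULL,
                         sigma = 1, seed = NULL) {
  stopifnot(n >= 2L, m >= 1L, r >= 0, r < 1, sigma > 0)
  if (is.null(theta_true)) {
    if (m < 5L) stop("default theta_true needs m >= 5")
    theta_true <- numeric(m)
    theta_true[c(1L, 2L, 5L)] <- c(2, -3, 4)
  }
  if (length(theta_true) != m) stop("theta_true must have length m")
  structure(list(n = as.integer(n), m = as.integer(m), r = r,
                 theta_true = theta_true, sigma = sigma, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: n = %d, m = %d, r = %g, sigma = %g, %d nonzero\n",
              x$n, x$m, x$r, x$sigma, sum(x$theta_true != 0)))
  invisible(x)
}

# Upper Cholesky factor of the AR(1) Toeplitz correlation matrix r^|i-j|.
.ar1_chol <- function(m, r) {
  stopifnot(r >= 0, r < 1)
  chol(toeplitz(r^(0:(m - 1L))))
}

#' Generate an AR(1)-correlated Gaussian design matrix
#'
#' Draws n i.i.d. rows from `N(0, Sigma)` with `Sigma_ij = r^|i-j|`, by
#' multiplying a standard-normal matrix with the Cholesky factor of the
#' explicit Toeplitz Sigma (positive definiteness is thereby verified).
#'
#' @param n sample count, or a [sim_scenario] (then `m`, `r`, `seed` are
#'   taken from it).
#' @param m feature count.
#' @param r AR(1) correlation, `0 <= r < 1`.
#' @param seed integer seed or NULL.
#' @param chol_sigma optional precomputed `.ar1_chol(m, r)` factor, for
#'   reuse across replicates.
#' @return n x m numeric matrix.
#' @examples
#' x <- gen_ar1_design(200, 10, r = 0.6, seed = 1)
#' cor(x[, 1], x[, 2])  # about 0.6
#' @export
gen_ar1_design <- function(n, m = NULL, r = 0, seed = NULL,
                           chol_sigma = NULL) {
  if (inherits(n, "sim_scenario")) {
    sc <- n; n <- sc$n; m <- sc$m; r <- sc$r; seed <- seed %||% sc$seed
  }
  stopifnot(n >= 1L, m >= 1L, r >= 0, r < 1)
  z <- with_seed(seed, matrix(rnorm(n * m), n, m))
  if (r == 0) return(z)
  R <- chol_sigma %||% .ar1_chol(m, r)
  z %*% R
}

#' Generate a sparse linear response
#'
#' `y = X theta_true + eps`, `eps` i.i.d. `N(0, sigma^2)`.
#'
#' @param x design matrix.
#' @param theta_true coefficient vector of length `ncol(x)`.
#' @param sigma noise SD (>= 0; 0 gives the noiseless response).
#' @param seed integer seed or NULL.
#' @return numeric response vector of length `nrow(x)`.
#' @examples
#' x <- gen_ar1_design(50, 5, seed = 1)
#' y <- gen_response(x, c(2, -3, 0, 0, 4), sigma = 1, seed = 2)
#' @export
gen_response <- function(x, theta_true, sigma = 1, seed = NULL) {
  stopifnot(length(theta_true) == ncol(x), sigma >= 0)
  mu <- drop(x %*% theta_true)
  if (sigma == 0) return(mu)
  mu + with_seed(seed, sigma * rnorm(nrow(x)))
}

#' Generate banded-precision Gaussian network data with known structure
#'
#' Two designs for benchmarking graphical-structure recovery:
#' \describe{
#'   \item{band 1}{covariance `Sigma_ij = 0.6^|i-j|`; the precision matrix
#'     of an AR(1) process is tridiagonal, so the true graph links
#'     `|i-j| = 1` (m-1 edges).}
#'   \item{band 2}{precision matrix `Omega = I + 0.25 at lag 1 + 0.4 at
#'     lag 2` (positive off-diagonals; the banded Toeplitz matrix with
#'     negative entries of these magnitudes is not positive definite, and
#'     edge-recovery scoring is sign-free); true graph links
#'     `|i-j| in {1, 2}` (2m-3 edges).  `X ~ N(0, Omega^-1)`.}
#' }
#' Positive definiteness is asserted via Cholesky; a failure is an error,
#' never silently repaired.
#'
#' @param n sample count.
#' @param m variable count (default 100).
#' @param band 1 or 2.
#' @param seed integer seed or NULL.
#' @return list of class `network_data`: `x` (n x m matrix), `adjacency`
#'   (true binary m x m adjacency, zero diagonal), `band`.
#' @examples
#' nd <- gen_band_network(50, m = 20, band = 1, seed = 1)
#' sum(nd$adjacency) / 2  # 19 edges
#' @export
gen_band_network <- function(n, m = 100L, band = 1L, seed = NULL) {
  stopifnot(n >= 2L, m >= 3L, band %in% c(1L, 2L))
  if (band == 1L) {
    R <- .ar1_chol(m, 0.6)
    truth_lag <- 1L
  } else {
    omega <- diag(m)
    idx <- seq_len(m - 1L)
    omega[cbind(idx, idx + 1L)] <- omega[cbind(idx + 1L, idx)] <- 0.25
    idx2 <- seq_len(m - 2L)
    omega[cbind(idx2, idx2 + 2L)] <- omega[cbind(idx2 + 2L, idx2)] <- 0.4
    ch <- tryCatch(chol(omega),
                   error = function(e) stop("precision matrix is not ",
                                            "positive definite: ",
                                            conditionMessage(e)))
    sigma <- chol2inv(ch)
    R <- chol(sigma)
    truth_lag <- 2L
  }
  z <- with_seed(seed, matrix(rnorm(n * m), n, m))
  x <- z %*% R
  colnames(x) <- paste0("V", seq_len(m))
  adj <- matrix(0L, m, m, dimnames = list(colnames(x), colnames(x)))
  for (lag in seq_len(truth_lag)) {
    i <- seq_len(m - lag)
    adj[cbind(i, i + lag)] <- adj[cbind(i + lag, i)] <- 1L
  }
  structure(list(x = x, adjacency = adj, band = as.integer(band)),
            class = "network_data")
}

#' @export
print.network_data <- function(x, ...) {
  cat(sprintf("network_data: band %d, %d samples x %d variables, %d edges\n",
              x$band, nrow(x$x), ncol(x$x), sum(x$adjacency) / 2L))
  invisible(x)
}
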