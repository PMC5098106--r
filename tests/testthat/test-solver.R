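# Core EM solver: ridge initialization, fixed points, primal-dual
# equivalence, support behavior, the Lp generalization, and diagnostics.

test_that("ridge_init solves the penalized normal equations", {
  expect_equal(unname(ridge_init(diag(5), rep(1, 5), lambda = 1)),
               rep(0.5, 5))
  set.seed(4)
  x <- matrix(rnorm(30), 6, 5)
  expect_equal(unname(ridge_init(x, rep(0, 6), lambda = 0.7)), rep(0, 5))
  # primal (m x m) and dual (n x n) forms are the same estimator
  set.seed(5)
  xw <- matrix(rnorm(10 * 20), 10, 20)
  yw <- rnorm(10)
  g <- crossprod(xw)
  primal <- solve(g + diag(0.3, 20), drop(crossprod(xw, yw)))
  expect_equal(unname(ridge_init(xw, yw, lambda = 0.3)), primal,
               tolerance = 1e-10)
})

test_that("orthonormal designs follow the fixed-point closed form", {
  # per-coordinate map theta <- theta^2 z / (theta^2 + lambda): a nonzero
  # limit exists iff z^2 >= 4 lambda and equals the larger quadratic root
  z <- c(3, 2.1, 0.1, 0.05, 1.5, -2.8)
  lambda <- 1
  fit <- l0em_fit(diag(6), z, lambda = lambda)
  expected <- orthonormal_fixed_point(z, lambda)
  expect_equal(unname(fit$theta), expected, tolerance = 1e-6)
  expect_equal(fit$support, which(z^2 >= 4 * lambda))
  # strong signals are left nearly unbiased (oracle property): root -> z
  z2 <- c(6, -5, 0.2, 0.1, 7)
  fit2 <- l0em_fit(diag(5), z2, lambda = lambda)
  expect_equal(unname(fit2$theta[c(1, 2, 5)]), z2[c(1, 2, 5)],
               tolerance = 0.05)
  # same closed form on a non-trivial orthonormal design
  set.seed(11)
  Q <- orthonormal_design(40, 6)
  y <- drop(Q %*% z) + 0         # exact marginals z
  fit3 <- l0em_fit(Q, y, lambda = lambda)
  expect_equal(unname(fit3$theta), expected, tolerance = 1e-6)
})

test_that("zero response yields the empty model", {
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  fit <- l0em_fit(x, rep(0, 8), lambda = 1)
  expect_equal(length(fit$support), 0L)
  expect_true(fit$converged)
  expect_equal(fit$objective, 0)
})

test_that("all-zero user initialization is rejected as a trivial fixed point", {
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  expect_error(l0em_fit(x, rnorm(8), lambda = 1, init = rep(0, 5)),
               "trivial fixed point")
})

test_that("primal and dual solvers agree across shapes and seeds", {
  worst <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- sample(10:50, 1)
    m <- sample(5:200, 1)
    x <- matrix(rnorm(n * m), n, m)
    k_true <- min(3, m)
    theta <- numeric(m); theta[seq_len(k_true)] <- c(3, -2, 4)[seq_len(k_true)]
    y <- drop(x %*% theta) + 0.5 * rnorm(n)
    lam <- exp(runif(1, log(0.05), log(5)))
    a <- l0em_fit(x, y, lambda = lam)
    b <- dl0em_fit(x, y, lambda = lam)
    worst <- max(worst, max(abs(a$theta - b$theta)))
  }
  expect_lt(worst, 1e-8)
})

test_that("converged fits satisfy the fixed-point equation", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(rnorm(30 * 8), 30, 8)
    theta_true <- c(2, -3, 0, 0, 4, 0, 0, 0)
    y <- drop(x %*% theta_true) + 0.5 * rnorm(30)
    fit <- l0em_fit(x, y, lambda = log(30))
    expect_true(fit$converged)
    D <- fit$theta^2
    A <- D * crossprod(x)
    diag(A) <- diag(A) + fit$lambda
    g <- drop(solve(A, D * crossprod(x, y)))
    expect_lt(max(abs(fit$theta - g)), 10 * 1e-8)
  }
})

test_that("the EM solution matches the exhaustive best-subset oracle", {
  hits <- 0
  n_cases <- 40
  for (s in seq_len(n_cases)) {
    set.seed(200 + s)
    m <- 8; n <- 30
    x <- matrix(rnorm(n * m), n, m)
    theta_true <- numeric(m); theta_true[c(1, 2, 5)] <- c(2, -3, 4)
    y <- drop(x %*% theta_true) + 0.5 * rnorm(n)
    lam <- log(n)
    fit <- l0em_fit(x, y, lambda = lam)
    oracle <- brute_force_best_subset(x, y, lam)
    # the EM objective can never beat the exhaustive global minimum, and
    # its fixed point carries a small stationarity excess over the
    # least-squares refit (x_j' r = lambda / theta_j on the support, not 0)
    expect_gte(fit$objective, oracle$objective - 1e-8)
    expect_lt(fit$objective, oracle$objective * 1.05)
    if (setequal(fit$support, oracle$support)) hits <- hits + 1
  }
  # the selected support agrees with the oracle in at least 90% of
  # well-separated instances
  expect_gte(hits, 0.9 * n_cases)
})

test_that("support recovery on wide problems with strong signals", {
  # n << m regime; at n = 30, m = 200 the dual solver recovers the three
  # spikes from a cold ridge start in most seeded instances
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(30 * 200), 30, 200)
    theta_true <- numeric(200); theta_true[c(1, 2, 5)] <- c(2, -3, 4)
    y <- drop(x %*% theta_true) + 0.3 * rnorm(30)
    fit <- dl0em_fit(x, y, lambda = log(30))
    if (setequal(fit$support, c(1, 2, 5))) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("the support only shrinks across iterations", {
  set.seed(31)
  x <- matrix(rnorm(50 * 12), 50, 12)
  y <- drop(x %*% c(2, -3, rep(0, 9), 4)) + rnorm(50)
  prev <- NULL
  for (iters in c(1, 2, 3, 5, 10, 25, 100)) {
    fit <- l0em_fit(x, y, lambda = 2, max_iter = iters)
    sup <- fit$support
    if (!is.null(prev)) expect_true(all(sup %in% prev))
    prev <- sup
  }
})

test_that("above the null-model threshold the fitted support is empty", {
  for (s in 1:5) {
    set.seed(300 + s)
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- drop(x %*% c(1, -1, 0, 0, 0, 2)) + rnorm(40)
    lam_max <- max(drop(crossprod(x, y))^2 / (4 * colSums(x^2)))
    fit <- l0em_fit(x, y, lambda = lam_max * 1.01)
    expect_equal(length(fit$support), 0L)
  }
})

test_that("lpem_fit generalizes: p = 2 is ridge, p = 0 is the L0 solver", {
  set.seed(9)
  x <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  r2 <- lpem_fit(x, y, lambda = 0.8, p = 2)
  closed <- drop(solve(crossprod(x) + diag(0.8, 5), crossprod(x, y)))
  expect_equal(unname(r2$theta), closed, tolerance = 1e-12)
  expect_equal(r2$n_iter, 1L)
  l0a <- lpem_fit(x, y, lambda = 0.8, p = 0, mode = "primal")
  l0b <- l0em_fit(x, y, lambda = 0.8)
  expect_identical(l0a$theta, l0b$theta)
})

test_that("p = 1 fixed points are lasso solutions at penalty lambda", {
  set.seed(42)
  n <- 50; m <- 10
  x <- matrix(rnorm(n * m), n, m)
  y <- drop(x %*% c(2, -3, 0, 0, 4, rep(0, 5))) + rnorm(n)
  lam <- 5
  fit <- lpem_fit(x, y, lambda = lam, p = 1, tol = 1e-12, max_iter = 5000)
  oracle <- cd_lasso(x, y, lam)
  expect_equal(unname(fit$theta), oracle, tolerance = 1e-4)
  obj <- function(th) 0.5 * sum((y - drop(x %*% th))^2) + lam * sum(abs(th))
  expect_equal(obj(fit$theta), obj(oracle), tolerance = 1e-6)
})

test_that("positive_only clamps the fit to nonnegative coefficients", {
  set.seed(3)
  x <- matrix(rnorm(200), 40, 5)
  y <- drop(x %*% c(2, -3, 0, 0, 4)) + 0.3 * rnorm(40)
  fit <- l0em_fit(x, y, lambda = 1, positive_only = TRUE)
  expect_true(all(fit$theta >= 0))
  expect_true(all(c(1, 5) %in% fit$support))
  expect_false(2 %in% fit$support)
})

test_that("objective and prune follow their definitions", {
  set.seed(6)
  x <- matrix(rnorm(30), 6, 5)
  y <- rnorm(6)
  expect_equal(l0_objective(x, y, rep(0, 5), lambda = 3), 0.5 * sum(y^2))
  # exact interpolation with k nonzeros costs lambda * k / 2
  x5 <- diag(5); th <- c(1, 2, 0, 0, 3)
  expect_equal(l0_objective(x5, th, th, lambda = 4), 4 * 3 / 2)
  expect_equal(prune(c(1e-9, 0.5, -1e-7), 1e-6), c(0, 0.5, 0))
  expect_equal(prune(c(1e-9, 0.5), 0), c(1e-9, 0.5))
  expect_equal(prune(c(5, -2), Inf), c(0, 0))
})

test_that("contraction diagnostic behaves at its limits and predicts decay", {
  set.seed(8)
  x <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  d0 <- check_contraction(x, y, rep(0, 5), lambda = 1)
  expect_equal(d0$gamma_bound, 0)
  expect_true(d0$satisfied)
  th <- rnorm(5)
  big <- check_contraction(x, y, th, lambda = 1e8)
  expect_true(big$satisfied)   # (lambda I)^-2 scaling kills the bound
  # when satisfied at the solution, iterate gaps shrink monotonically
  fit <- l0em_fit(x, y, lambda = 2)
  diag_fit <- check_contraction(x, y, fit$theta, lambda = 2)
  if (diag_fit$satisfied) {
    gaps <- numeric(0)
    prev <- ridge_init(x, y, lambda = 2)
    for (i in 1:8) {
      cur <- l0em_fit(x, y, lambda = 2, max_iter = i)$theta
      gaps <- c(gaps, max(abs(cur - prev)))
      prev <- cur
    }
    late <- gaps[gaps > 0]
    expect_true(all(diff(late) <= 1e-12))
  }
})

test_that("identical inputs and settings give bit-identical results", {
  set.seed(12)
  x <- matrix(rnorm(50 * 30), 50, 30)
  y <- rnorm(50)
  f1 <- l0em_fit(x, y, lambda = 1.3)
  f2 <- l0em_fit(x, y, lambda = 1.3)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$n_iter, f2$n_iter)
})

test_that("malformed inputs are rejected up front", {
  expect_error(regression_data(matrix(c(1, NA, 3, 4), 2, 2), c(1, 2)),
               "non-finite")
  expect_error(regression_data(matrix(1:4, 2, 2), c(1, 2, 3)), "length")
  expect_error(l0em_fit(diag(3), rep(1, 3), lambda = -1))
  expect_error(lpem_fit(diag(3), rep(1, 3), lambda = 1, p = 2.5))
})

test_that("centering and standardization report on the original scale", {
  set.seed(21)
  x <- sweep(matrix(rnorm(300), 60, 5), 2, c(5, -2, 0, 1, 3), "+")
  x <- sweep(x, 2, c(1, 4, 2, 0.5, 1), "*")
  y <- 7 + drop(x %*% c(2, -3, 0, 0, 4)) + 0.2 * rnorm(60)
  fit <- l0em_fit(x, y, lambda = log(60), center = TRUE,
                  standardize = TRUE)
  expect_equal(fit$support, c(1L, 2L, 5L))
  expect_equal(unname(fit$theta[c(1, 2, 5)]), c(2, -3, 4), tolerance = 0.1)
  expect_equal(fit$intercept, 7, tolerance = 0.5)
})
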