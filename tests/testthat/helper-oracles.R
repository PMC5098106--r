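# Independent oracles used across the suite.  These deliberately avoid the
# package's own solver path.

# Exhaustive best-subset minimum of 1/2||y - X theta||^2 + lambda/2 * |S|
# over all 2^m supports, least-squares refit per support.
brute_force_best_subset <- function(x, y, lambda) {
  m <- ncol(x)
  best <- list(objective = 0.5 * sum(y^2), support = integer(0),
               theta = numeric(m))
  for (code in seq_len(2^m - 1L)) {
    s <- which(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0)
    xs <- x[, s, drop = FALSE]
    th <- qr.coef(qr(xs), y)
    rss <- sum((y - drop(xs %*% th))^2)
    obj <- 0.5 * rss + 0.5 * lambda * length(s)
    if (obj < best$objective) {
      theta <- numeric(m); theta[s] <- th
      best <- list(objective = obj, support = s, theta = theta)
    }
  }
  best
}

# Cyclic coordinate descent for 1/2||y - X theta||^2 + lambda * ||theta||_1
# (note: penalty weight lambda, not lambda/2).
cd_lasso <- function(x, y, lambda, tol = 1e-10, max_iter = 5000L) {
  m <- ncol(x)
  theta <- numeric(m)
  r <- y
  css <- colSums(x^2)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(m)) {
      old <- theta[j]
      rho <- sum(x[, j] * r) + css[j] * old
      new <- sign(rho) * max(abs(rho) - lambda, 0) / css[j]
      if (new != old) {
        r <- r - x[, j] * (new - old)
        delta <- max(delta, abs(new - old))
      }
      theta[j] <- new
    }
    if (delta < tol) break
  }
  theta
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(equal).
pairwise_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# n x m matrix with exactly orthonormal columns (m <= n).
orthonormal_design <- function(n, m) {
  qr.Q(qr(matrix(rnorm(n * m), n, m)))[, seq_len(m), drop = FALSE]
}

# Exact fixed-point prediction for an orthonormal design: a coordinate with
# marginal z_j survives iff z_j^2 >= 4 lambda (and the ridge start lies
# above the repelling smaller root), converging to the larger root of
# theta^2 - z theta + lambda = 0.
orthonormal_fixed_point <- function(z, lambda) {
  disc <- z^2 - 4 * lambda
  ifelse(disc >= 0, (z + sign(z) * sqrt(pmax(disc, 0))) / 2, 0)
}
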