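## Evaluation quantities for replicated simulation experiments: test /
## in-sample MSE, coefficient bias, selected-feature counts, exact-support
## recovery, and the replicate driver aggregating them.

#' Mean squared error
#' @param y_true,y_pred numeric vectors of equal length.
#' @return `mean((y_true - y_pred)^2)`.
#' @examples
#' mse(1:3, c(2, 3, 4))  # 1
#' @export
mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean((y_true - y_pred)^2)
}

#' Coefficient-estimation bias
#'
#' Norm of `theta_hat - theta_true` over all m coordinates: Euclidean by
#' default (the convention under which the reference designs give biases
#' around 0.14-0.2 at r = 0), or the L1 sum of absolute deviations.
#'
#' @param theta_hat,theta_true numeric vectors of equal length.
#' @param type `"euclidean"` (default) or `"l1"`.
#' @return scalar bias.
#' @examples
#' bias_norm(c(2.1, -3, 4), c(2, -3, 4))  # 0.1
#' @export
bias_norm <- function(theta_hat, theta_true,
                      type = c("euclidean", "l1")) {
  stopifnot(length(theta_hat) == length(theta_true))
  d <- theta_hat - theta_true
  switch(match.arg(type), euclidean = sqrt(sum(d^2)), l1 = sum(abs(d)))
}

#' Exact-support recovery indicator
#' @param support,true_support integer index sets.
#' @return TRUE iff the two sets are identical.
#' @examples
#' true_model_indicator(c(1, 2, 5), c(5, 2, 1))  # TRUE
#' @export
true_model_indicator <- function(support, true_support) {
  setequal(as.integer(support), as.integer(true_support))
}

#' Replicated sparse-regression experiment
#'
#' For each replicate, draws a fresh design and response from the scenario,
#' selects lambda by each requested rule, refits on the full data, and
#' records the support size, MSE, coefficient bias, and exact-support
#' recovery.  CV-based rules (`"cv_mse"`, `"cv_opt"`) share one
#' cross-validation per replicate and report the held-out mean test MSE at
#' the selected lambda; information-criterion rules (`"aic"`, `"bic"`,
#' `"ric"`) and fixed numeric lambdas fit once and report the in-sample MSE
#' of that fit (the two MSE kinds are labeled in the output).
#'
#' @param scenario a [sim_scenario].
#' @param selection character vector of rules among `"cv_mse"`, `"cv_opt"`,
#'   `"aic"`, `"bic"`, `"ric"`, and/or numeric lambdas (as names see
#'   Details); numeric entries are treated as fixed lambdas.
#' @param n_replicates number of replicates.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param k CV folds.
#' @param n_points,lam_min lambda-grid parameters for CV rules.
#' @param solver solve route passed to the fitter.
#' @param bias_type passed to [bias_norm()].
#' @param ... further solver settings.
#' @return object of class `l0experiment`: list with `replicates` (long
#'   data.frame: rep, selection, lambda, n_selected, mse, mse_type, bias,
#'   true_model) and `summary` (data.frame, one row per selection rule:
#'   means and SDs plus `true_model_count`).
#' @examples
#' sc <- sim_scenario(n = 60, m = 10, r = 0, seed = 1)
#' ex <- run_experiment(sc, selection = "bic", n_replicates = 3, seed = 1)
#' ex$summary
#' @export
run_experiment <- function(scenario, selection = "cv_opt",
                           n_replicates = 100L, seed = NULL, k = 5L,
                           n_points = 100L, lam_min = 1e-4,
                           solver = "auto", bias_type = "euclidean", ...) {
  stopifnot(inherits(scenario, "sim_scenario"), n_replicates >= 1L)
  if (is.numeric(selection)) selection <- as.character(selection)
  fixed <- suppressWarnings(as.numeric(selection))
  known <- c("cv_mse", "cv_opt", "aic", "bic", "ric")
  bad <- is.na(fixed) & !selection %in% known
  if (any(bad)) stop("unknown selection rule: ", selection[bad][1L])
  need_cv <- any(selection %in% c("cv_mse", "cv_opt"))

  n <- scenario$n; m <- scenario$m
  chol_sigma <- if (scenario$r > 0) .ar1_chol(m, scenario$r)
  true_support <- which(scenario$theta_true != 0)
  seeds <- child_seeds(seed %||% scenario$seed, 3L * n_replicates)
  seeds <- matrix(seeds, nrow = 3L)   # design / noise / folds per replicate

  rows <- vector("list", n_replicates * length(selection))
  ri <- 0L
  for (i in seq_len(n_replicates)) {
    x <- gen_ar1_design(n, m, scenario$r, seed = seeds[1L, i],
                        chol_sigma = chol_sigma)
    y <- gen_response(x, scenario$theta_true, scenario$sigma,
                      seed = seeds[2L, i])
    cv <- if (need_cv)
      cross_validate(x, y, k = k, n_points = n_points, lam_min = lam_min,
                     seed = seeds[3L, i], solver = solver, ...)
    for (s in selection) {
      lam <- switch(s,
                    cv_mse = cv$lambda_mse,
                    cv_opt = cv$lambda_opt,
                    aic = , bic = , ric = info_criterion_lambda(s, n, m),
                    as.numeric(s))
      fit <- .em_fit(x, y, lam, mode = solver, ...)
      this_mse <- if (s %in% c("cv_mse", "cv_opt"))
        cv$mse_mean[match(lam, cv$lambda)]
      else mean((y - drop(x %*% fit$theta))^2)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = i, selection = s, lambda = lam,
        n_selected = length(fit$support),
        mse = this_mse,
        mse_type = if (s %in% c("cv_mse", "cv_opt")) "cv_test"
                   else "in_sample",
        bias = bias_norm(fit$theta, scenario$theta_true, type = bias_type),
        true_model = true_model_indicator(fit$support, true_support))
    }
  }
  reps <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)
  agg <- lapply(split(reps, reps$selection), function(d) {
    data.frame(selection = d$selection[1L],
               n_selected_mean = mean(d$n_selected),
               n_selected_sd = sd0(d$n_selected),
               mse_mean = mean(d$mse), mse_sd = sd0(d$mse),
               mse_type = d$mse_type[1L],
               bias_mean = mean(d$bias), bias_sd = sd0(d$bias),
               true_model_count = sum(d$true_model),
               n_replicates = nrow(d))
  })
  summary <- do.call(rbind, agg[unique(reps$selection)])
  rownames(summary) <- NULL
  structure(list(replicates = reps, summary = summary, scenario = scenario,
                 seed = seed %||% scenario$seed),
            class = "l0experiment")
}

#' @export
print.l0experiment <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("l0experiment: n = %d, m = %d, r = %g, %d replicates\n",
              sc$n, sc$m, sc$r, x$summary$n_replicates[1L]))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf(
      "  %-7s #SF %.2f (+-%.2f) | %s MSE %.3f (+-%.3f) | bias %.3f (+-%.3f) | true model %d/%d\n",
      s$selection[i], s$n_selected_mean[i], s$n_selected_sd[i],
      s$mse_type[i], s$mse_mean[i], s$mse_sd[i],
      s$bias_mean[i], s$bias_sd[i],
      s$true_model_count[i], s$n_replicates[i]))
  invisible(x)
}
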