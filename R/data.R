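#' Bundle a design matrix and response for penalized regression
#'
#' Light container for the linear model y = X theta + eps.  Validates
#' dimensions and finiteness once so downstream solvers can assume clean
#' input.
#'
#' @param x numeric matrix, n samples by m features.
#' @param y numeric response vector of length n.
#' @param feature_names optional character vector of m column labels;
#'   defaults to existing column names or V1..Vm.
#' @return an object of class `regression_data`: a list with elements `x`,
#'   `y`, `feature_names`.
#' @examples
#' d <- regression_data(matrix(rnorm(20), 5, 4), rnorm(5))
#' d$feature_names
#' @export
regression_data <- function(x, y, feature_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (ncol(x) < 1L) stop("need at least 1 feature")
  if (length(y) != nrow(x))
    stop("length(y) [", length(y), "] != nrow(x) [", nrow(x), "]")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value in x at row ", bad[1L], ", column ", bad[2L])
  }
  if (!all(is.finite(y)))
    stop("non-finite value in y at position ", which(!is.finite(y))[1L])
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("V", seq_len(ncol(x)))
  if (length(feature_names) != ncol(x))
    stop("feature_names must have one entry per column of x")
  colnames(x) <- feature_names
  structure(list(x = x, y = y, feature_names = feature_names),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat("regression_data: ", nrow(x$x), " samples x ", ncol(x$x),
      " features\n", sep = "")
  invisible(x)
}

# Accept either a regression_data object or (x, y) and return the pair.
as_xy <- function(x, y = NULL) {
  if (inherits(x, "regression_data")) return(list(x = x$x, y = x$y))
  d <- regression_data(x, y)
  list(x = d$x, y = d$y)
}
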