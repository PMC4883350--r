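## Base kernels, correlation-derived feature weights, and the weighted
## composite kernel Kc(x, y) = sum_p c_p K_p(x_p, y_p).
##
## The radial basis kernel is the Gaussian exp(-gamma ||x - y||^2) with
## gamma = 1 / (2 sigma^2); per-feature base kernels are the direct
## restriction of each family to one coordinate.

KERNEL_FAMILIES <- c("linear", "quadratic", "poly3", "rbf")

#' Specify a kernel
#'
#' @param family one of `"linear"`, `"quadratic"`, `"poly3"`, `"rbf"`.
#' @param weighted logical; use the correlation-weighted composite kernel
#'   instead of the prime (unweighted) kernel.
#' @param gamma radial-basis width parameter, `gamma = 1 / (2 sigma^2)`;
#'   ignored by the other families.
#' @param sigma optional alias: when given, `gamma` is derived from it.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "quadratic", "poly3", "rbf"),
                        weighted = FALSE, gamma = 0.5, sigma = NULL) {
  family <- match.arg(family)
  if (!is.null(sigma)) {
    stopifnot(sigma > 0)
    gamma <- 1 / (2 * sigma^2)
  }
  if (family == "rbf" && gamma <= 0) stop("gamma must be positive")
  structure(list(family = family, weighted = isTRUE(weighted),
                 gamma = gamma),
            class = "kernel_spec")
}

#' Evaluate a prime (unweighted) base kernel
#'
#' Linear `x . y`; quadratic `(x . y + 1)^2`; third-order polynomial
#' `(x . y + 1)^3`; radial basis `exp(-gamma ||x - y||^2)`.
#'
#' @param x,y numeric vectors of equal length.
#' @param spec a [kernel_spec()].
#' @return Scalar kernel value.
#' @export
#' @examples
#' base_kernel(c(1, 2), c(3, 4), kernel_spec("linear"))    # 11
#' base_kernel(c(1, 2), c(3, 4), kernel_spec("quadratic")) # 144
base_kernel <- function(x, y, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y)) stop("dimension mismatch")
  switch(spec$family,
         linear = sum(x * y),
         quadratic = (sum(x * y) + 1)^2,
         poly3 = (sum(x * y) + 1)^3,
         rbf = exp(-spec$gamma * sum((x - y)^2)))
}

#' Correlation-derived feature weights
#'
#' The importance of a feature is the magnitude of the Pearson correlation
#' between its column and the class labels: weights are
#' `c_p = |r_p| / sum_q |r_q|`, nonnegative and summing to 1, so strongly
#' class-associated features dominate the composite kernel.  A constant
#' feature gets `r_p = 0`; if every correlation vanishes the weights fall
#' back to uniform with a warning.
#'
#' @param ds a `ddd_dataset` with at least 2 rows per class.
#' @return Numeric weight vector aligned with the feature columns.
#' @export
correlation_weights <- function(ds) {
  stopifnot(inherits(ds, "ddd_dataset"))
  if (sum(ds$y == 0) < 2 || sum(ds$y == 1) < 2) {
    stop("need at least 2 rows per class")
  }
  r <- suppressWarnings(
    apply(ds$X, 2, function(col) stats::cor(col, ds$y)))
  r[!is.finite(r)] <- 0
  a <- abs(r)
  if (sum(a) < .Machine$double.eps) {
    warning("all feature-label correlations vanish; using uniform weights")
    a <- rep(1, ncol(ds$X))
  }
  w <- a / sum(a)
  names(w) <- colnames(ds$X)
  w
}

per_feature_kernel <- function(op, family, gamma) {
  # op = outer product x_p * y_p, od2 = squared difference (x_p - y_p)^2
  switch(family,
         linear = op,
         quadratic = (op + 1)^2,
         poly3 = (op + 1)^3,
         stop("per-feature rbf needs squared differences"))
}

#' Evaluate the weighted composite kernel
#'
#' `Kc(x, y) = sum_p c_p K_p(x_p, y_p)` with per-feature base kernels:
#' linear `x_p y_p`, quadratic `(x_p y_p + 1)^2`, poly3 `(x_p y_p + 1)^3`,
#' rbf `exp(-gamma (x_p - y_p)^2)`.  With nonnegative weights this is a
#' conic combination of valid kernels, hence itself a valid (positive
#' semidefinite) kernel.
#'
#' @param x,y numeric vectors of equal length.
#' @param w weight vector (`c_p >= 0`, summing to 1) of the same length.
#' @param spec a [kernel_spec()].
#' @return Scalar kernel value.
#' @export
weighted_kernel <- function(x, y, w, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y) || length(w) != length(x)) {
    stop("dimension mismatch")
  }
  if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1")
  }
  kp <- switch(spec$family,
               linear = x * y,
               quadratic = (x * y + 1)^2,
               poly3 = (x * y + 1)^3,
               rbf = exp(-spec$gamma * (x - y)^2))
  sum(w * kp)
}

#' Kernel (Gram) matrix
#'
#' `G[i, j] = K(x_i, y_j)` for all row pairs, vectorized per family.  With
#' `Y = X` the result is symmetric and, for valid weights, positive
#' semidefinite up to numerical tolerance.
#'
#' @param X numeric matrix (n x p) of rows to compare.
#' @param spec a [kernel_spec()].
#' @param w weight vector for the composite kernel; required when
#'   `spec$weighted`, ignored otherwise.
#' @param Y optional second matrix (m x p); defaults to `X`.
#' @return `n x m` kernel matrix.
#' @export
gram_matrix <- function(X, spec, w = NULL, Y = NULL) {
  stopifnot(inherits(spec, "kernel_spec"), is.matrix(X))
  Y <- Y %||% X
  stopifnot(ncol(X) == ncol(Y))
  if (spec$weighted) {
    if (is.null(w)) stop("weighted kernel requires a weight vector")
    stopifnot(length(w) == ncol(X))
    if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-9) {
      stop("weights must be nonnegative and sum to 1")
    }
    G <- matrix(0, nrow(X), nrow(Y))
    for (p in seq_len(ncol(X))) {
      if (w[p] == 0) next
      if (spec$family == "rbf") {
        d2 <- outer(X[, p], Y[, p], "-")^2
        G <- G + w[p] * exp(-spec$gamma * d2)
      } else {
        op <- outer(X[, p], Y[, p])
        G <- G + w[p] * per_feature_kernel(op, spec$family, spec$gamma)
      }
    }
    return(G)
  }
  D <- if (nrow(Y) == nrow(X) && identical(Y, X)) {
    tcrossprod(X)  # exactly symmetric
  } else {
    X %*% t(Y)
  }
  switch(spec$family,
         linear = D,
         quadratic = (D + 1)^2,
         poly3 = (D + 1)^3,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * D
           d2[d2 < 0] <- 0
           exp(-spec$gamma * d2)
         })
}
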