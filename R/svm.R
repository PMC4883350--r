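## Dual SVM solved by sequential minimal optimization (SMO) over a
## precomputed Gram matrix.  The composite kernels are custom, so the
## solver works purely from kernel values; it maximizes
##   D(alpha) = sum_i alpha_i - 1/2 sum_ij alpha_i alpha_j b_i b_j G_ij
## subject to alpha_i in [0, C] and sum_i alpha_i b_i = 0, selecting the
## maximal violating pair at each step (KKT-gap working-set selection).

#' Solve the dual SVM problem
#'
#' @param gram symmetric positive semidefinite kernel matrix (n x n).
#' @param labels class labels `b_i` in {-1, +1}, both classes present.
#' @param C box constraint (`alpha_i <= C`); `Inf` gives the hard-margin
#'   problem.
#' @param tol convergence tolerance on the maximal KKT violation.
#' @param max_iter cap on pairwise updates; the solver stops at the cap
#'   (the residual gap is reported in the result) and errors only if the
#'   remaining violation exceeds 0.01.
#' @return List with `alpha`, `bias`, `objective` (dual objective at the
#'   solution), `iterations`, and `kkt_gap`.  The bias is the average of
#'   `b_s - sum_i alpha_i b_i G_is` over margin vectors
#'   (`0 < alpha_s < C`).
#' @export
solve_dual <- function(gram, labels, C = 1, tol = 1e-6,
                       max_iter = NULL) {
  stopifnot(is.matrix(gram), nrow(gram) == ncol(gram))
  n <- nrow(gram)
  y <- as.numeric(labels)
  stopifnot(length(y) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present")
  max_iter <- max_iter %||% max(20000L, 100L * n)
  alpha <- numeric(n)
  f <- numeric(n)  # f_i = sum_j alpha_j y_j G_ij
  eps_a <- 1e-12
  dg <- diag(gram)
  it <- 0L
  repeat {
    s <- y - f
    up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
    lo <- (y > 0 & alpha > eps_a) | (y < 0 & alpha < C - eps_a)
    if (!any(up) || !any(lo)) {
      gap <- 0
      break
    }
    iu <- which(up)[which.max(s[up])]
    gap <- s[iu] - min(s[lo])
    if (gap < tol) {
      # confirm convergence on exactly recomputed values before stopping
      f <- drop(gram %*% (alpha * y))
      s <- y - f
      iu <- which(up)[which.max(s[up])]
      gap <- s[iu] - min(s[lo])
      if (gap < tol) break
    }
    if (it >= max_iter) {
      # ill-conditioned duals (huge polynomial kernel values) close the
      # last decades of the KKT gap extremely slowly; a small residual
      # gap is harmless for classification, but a large one means the
      # solution is unusable
      if (gap > 0.01) {
        stop(sprintf(paste0("SMO did not converge in %d updates ",
                            "(KKT gap %.3e, n = %d, C = %g)"),
                     it, gap, n, C))
      }
      break
    }
    # second-order working-set selection: i is the worst violator from
    # above; j maximizes the guaranteed objective gain b^2 / a among
    # violating partners (much faster than first-order selection when
    # the kernel scale makes the dual ill-conditioned)
    i <- iu
    cand <- which(lo & s < s[i])
    a2 <- pmax(dg[i] + dg[cand] - 2 * gram[i, cand], 1e-12)
    b2 <- s[i] - s[cand]
    j <- cand[which.max(b2^2 / a2)]
    Ei <- f[i] - y[i]
    Ej <- f[j] - y[j]
    eta <- max(dg[i] + dg[j] - 2 * gram[i, j], 1e-12)
    aj_new <- alpha[j] + y[j] * (Ei - Ej) / eta
    if (y[i] != y[j]) {
      L <- max(0, alpha[j] - alpha[i])
      H <- min(C, C + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - C)
      H <- min(C, alpha[i] + alpha[j])
    }
    aj_new <- min(H, max(L, aj_new))
    ai_new <- alpha[i] + y[i] * y[j] * (alpha[j] - aj_new)
    f <- f + (ai_new - alpha[i]) * y[i] * gram[, i] +
      (aj_new - alpha[j]) * y[j] * gram[, j]
    alpha[i] <- ai_new
    alpha[j] <- aj_new
    it <- it + 1L
    if (it %% 500L == 0L) {
      # refresh the cache: incremental updates accumulate rounding drift
      f <- drop(gram %*% (alpha * y))
    }
  }
  f <- drop(gram %*% (alpha * y))
  margin <- alpha > 1e-8 & alpha < C - 1e-8
  bias <- if (any(margin)) {
    mean((y - f)[margin])
  } else {
    s <- y - f
    up <- (y > 0 & alpha < C - eps_a) | (y < 0 & alpha > eps_a)
    lo <- (y > 0 & alpha > eps_a) | (y < 0 & alpha < C - eps_a)
    (max(s[up]) + min(s[lo])) / 2
  }
  av <- alpha * y
  objective <- sum(alpha) - 0.5 * drop(crossprod(av, gram %*% av))
  list(alpha = alpha, bias = bias, objective = objective,
       iterations = it, kkt_gap = gap)
}

#' KKT residuals of a dual solution
#'
#' Diagnostics used in property tests: the equality-constraint residual
#' `|sum_i alpha_i b_i|`, the worst stationarity violation on margin
#' vectors `max |b_s f(x_s) - 1|`, and the worst complementarity-style
#' violations at the box bounds.
#'
#' @param gram,labels,C as in [solve_dual()].
#' @param alpha,bias a dual solution.
#' @return Named numeric vector of residuals.
#' @export
kkt_residuals <- function(gram, labels, alpha, bias, C = 1) {
  y <- as.numeric(labels)
  fx <- drop(gram %*% (alpha * y)) + bias
  m <- y * fx
  margin <- alpha > 1e-8 & alpha < C - 1e-8
  c(equality = abs(sum(alpha * y)),
    stationarity = if (any(margin)) max(abs(m[margin] - 1)) else 0,
    lower = max(0, max(c(1 - m[alpha <= 1e-8], -Inf))),
    upper = if (is.finite(C)) {
      max(0, max(c(m[alpha >= C - 1e-8] - 1, -Inf)))
    } else 0)
}

#' Train a kernel SVM classifier
#'
#' Fits standardization statistics and (for weighted kernels) the
#' correlation feature weights on the training rows only, builds the Gram
#' matrix, solves the dual, and retains the support vectors
#' (`alpha > 1e-8`).
#'
#' @param ds a `ddd_dataset` of training rows (unstandardized).
#' @param spec a [kernel_spec()].
#' @param C box constraint (default 1; `Inf` for hard margin).
#' @return An object of class `ddd_model` storing standardized support
#'   vectors, their `alpha` and labels, the bias, the kernel spec, the
#'   weight vector (absent for prime kernels), the standardization
#'   statistics, and `C`.
#' @export
svm_train <- function(ds, spec, C = 1) {
  stopifnot(inherits(ds, "ddd_dataset"), inherits(spec, "kernel_spec"))
  st <- fit_standardization(ds)
  Z <- apply_standardization(ds$X, st)
  zds <- new_dataset(Z, ds$y, ds$groups, st)
  w <- if (spec$weighted) correlation_weights(zds) else NULL
  G <- gram_matrix(Z, spec, w = w)
  y <- 2 * ds$y - 1
  sol <- solve_dual(G, y, C = C)
  sv <- sol$alpha > 1e-8
  structure(list(sv = Z[sv, , drop = FALSE],
                 alpha = sol$alpha[sv], labels = y[sv],
                 bias = sol$bias, spec = spec, weights = w,
                 stats = st, C = C, objective = sol$objective,
                 iterations = sol$iterations),
            class = "ddd_model")
}

#' @export
print.ddd_model <- function(x, ...) {
  cat(sprintf("<ddd_model> %s%s kernel, %d support vectors, C = %g\n",
              if (x$spec$weighted) "weighted " else "", x$spec$family,
              nrow(x$sv), x$C))
  invisible(x)
}

#' Predict classes with a trained model
#'
#' Decision value `f(x) = sum_i alpha_i b_i K(x_i, x) + bias`; class 1
#' (drunk) when `f(x) > 0`, class 0 (normal) otherwise -- ties deliberately
#' resolve to normal, the conservative choice for an alerting system.
#'
#' @param model a `ddd_model`.
#' @param X numeric matrix (or single vector) of raw feature rows in
#'   canonical order; the model's standardization is applied internally.
#' @return `data.frame` with columns `decision` and `class`.
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "ddd_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Z <- apply_standardization(X, model$stats)
  K <- gram_matrix(model$sv, model$spec, w = model$weights, Y = Z)
  f <- drop(crossprod(K, model$alpha * model$labels)) + model$bias
  data.frame(decision = f, class = as.integer(f > 0))
}

#' Serialize / restore a trained model as JSON
#'
#' @param model a `ddd_model`.
#' @param path file path.
#' @param provenance optional named list merged into the file (e.g. seed,
#'   config hash).
#' @return `path` invisibly / the restored `ddd_model`.
#' @export
write_model <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "ddd_model"))
  obj <- list(support_vectors = unname(apply(model$sv, 1, as.numeric,
                                             simplify = FALSE)),
              feature_names = colnames(model$sv),
              alpha = model$alpha, labels = model$labels,
              bias = model$bias,
              kernel = list(family = model$spec$family,
                            weighted = model$spec$weighted,
                            gamma = model$spec$gamma),
              weights = model$weights,
              standardization = list(mean = model$stats$mean,
                                     sd = model$stats$sd,
                                     constant = model$stats$constant),
              C = if (is.finite(model$C)) model$C else "Inf",
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- obj$support_vectors
  if (is.list(sv)) {
    sv <- do.call(rbind, lapply(sv, as.numeric))
  } else {
    sv <- as.matrix(sv)
  }
  colnames(sv) <- obj$feature_names
  spec <- kernel_spec(obj$kernel$family, weighted = obj$kernel$weighted,
                      gamma = obj$kernel$gamma)
  st <- list(mean = stats::setNames(obj$standardization$mean,
                                    obj$feature_names),
             sd = stats::setNames(obj$standardization$sd,
                                  obj$feature_names),
             constant = obj$standardization$constant)
  w <- if (is.null(obj$weights)) NULL else {
    stats::setNames(as.numeric(obj$weights), obj$feature_names)
  }
  structure(list(sv = sv, alpha = as.numeric(obj$alpha),
                 labels = as.numeric(obj$labels), bias = obj$bias,
                 spec = spec, weights = w, stats = st,
                 C = if (identical(obj$C, "Inf")) Inf else obj$C),
            class = "ddd_model")
}
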