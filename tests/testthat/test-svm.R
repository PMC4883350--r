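# brute-force QP reference for the dual on tiny instances; expects a
# strictly positive-definite Gram (fixtures add a small ridge)
ipop_objective <- function(G, y, C) {
  Q <- (y %o% y) * G
  sol <- kernlab::ipop(c = matrix(-1, length(y), 1), H = Q,
                       A = matrix(y, 1), b = 0,
                       l = matrix(0, length(y), 1),
                       u = matrix(C, length(y), 1), r = 0,
                       sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(sol)
  sum(alpha) - 0.5 * drop(crossprod(alpha, Q %*% alpha))
}

ridge_gram <- function(G) G + diag(1e-4 * mean(diag(G)), nrow(G))

test_that("the two-point hard-margin problem is solved analytically", {
  G <- matrix(c(1, -1, -1, 1), 2)
  s <- solve_dual(G, c(-1, 1), C = Inf)
  expect_equal(s$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(s$bias, 0, tolerance = 1e-8)
  expect_equal(s$objective, 0.5, tolerance = 1e-8)
  expect_error(solve_dual(G, c(1, 1), C = 1), "both classes")
})

test_that("dual solutions match a quadratic-programming reference on toys", {
  set.seed(31)
  fams <- c("linear", "quadratic", "poly3", "rbf")
  for (trial in 1:8) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    spec <- kernel_spec(fams[1 + trial %% 4])
    G <- ridge_gram(gram_matrix(X, spec))
    for (C in c(1, 10)) {
      sol <- solve_dual(G, y, C = C, max_iter = 2e5)
      ref <- ipop_objective(G, y, C)
      expect_lt(abs(sol$objective - ref), 1e-4)
      res <- kkt_residuals(G, y, sol$alpha, sol$bias, C = C)
      expect_lt(max(res), 1e-5)
    }
  }
})

test_that("duplicating training points leaves the decision unchanged", {
  set.seed(5)
  X <- rbind(matrix(rnorm(8, -2), 4, 2), matrix(rnorm(8, 2), 4, 2))
  y <- rep(c(-1, 1), each = 4)
  spec <- kernel_spec("linear")
  G <- gram_matrix(X, spec)
  s1 <- solve_dual(G, y, C = Inf)
  Xd <- rbind(X, X)
  yd <- c(y, y)
  s2 <- solve_dual(gram_matrix(Xd, spec), yd, C = Inf)
  probe <- matrix(rnorm(40), 20, 2)
  f1 <- drop(crossprod(gram_matrix(X, spec, Y = probe),
                       s1$alpha * y)) + s1$bias
  f2 <- drop(crossprod(gram_matrix(Xd, spec, Y = probe),
                       s2$alpha * yd)) + s2$bias
  expect_equal(sign(f1), sign(f2))
  expect_equal(f1, f2, tolerance = 1e-4)
})

test_that("training separates a wide-margin toy set perfectly", {
  ds <- separable_dataset(n_per_class = 20)
  for (weighted in c(FALSE, TRUE)) {
    model <- svm_train(ds, kernel_spec("linear", weighted = weighted),
                       C = 1)
    pred <- svm_predict(model, ds$X)
    expect_equal(pred$class, ds$y)
    if (weighted) {
      expect_length(model$weights, 10)
    } else {
      expect_null(model$weights)
    }
  }
  # support vectors sit on the margin: |f| = 1 within solver tolerance
  model <- svm_train(ds, kernel_spec("linear"), C = Inf)
  margin <- model$alpha > 1e-6
  f_sv <- svm_predict(model,
                      sweep(sweep(model$sv, 2, model$stats$sd, "*"),
                            2, model$stats$mean, "+"))$decision
  expect_lt(max(abs(abs(f_sv[margin]) - 1)), 1e-4)
})

test_that("prediction applies stored standardization and breaks ties to normal", {
  ds <- separable_dataset(n_per_class = 15)
  model <- svm_train(ds, kernel_spec("rbf"), C = 1)
  scaled <- ds
  scaled$X <- ds$X * 1000
  model_s <- svm_train(scaled, kernel_spec("rbf"), C = 1)
  expect_equal(svm_predict(model, ds$X)$class,
               svm_predict(model_s, scaled$X)$class)

  fake <- model
  fake$bias <- 0
  fake$alpha <- numeric(0)
  fake$sv <- model$sv[0, , drop = FALSE]
  fake$labels <- numeric(0)
  tie <- svm_predict(fake, ds$X[1:3, ])
  expect_equal(tie$decision, rep(0, 3))
  expect_equal(tie$class, rep(0L, 3))  # f = 0 goes to class 0
})

test_that("models serialize to JSON and restore identically", {
  ds <- separable_dataset(n_per_class = 10)
  model <- svm_train(ds, kernel_spec("poly3", weighted = TRUE), C = 1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model(model, path, provenance = list(seed = 1))
  back <- read_model(path)
  expect_equal(back$alpha, model$alpha)
  expect_equal(back$bias, model$bias)
  expect_equal(unname(back$sv), unname(model$sv))
  expect_equal(back$spec$family, "poly3")
  expect_true(back$spec$weighted)
  expect_equal(svm_predict(back, ds$X)$decision,
               svm_predict(model, ds$X)$decision, tolerance = 1e-12)

  # identical training inputs give identical model files
  path2 <- tempfile(fileext = ".json")
  on.exit(unlink(path2), add = TRUE)
  write_model(svm_train(ds, kernel_spec("poly3", weighted = TRUE), C = 1),
              path2, provenance = list(seed = 1))
  expect_identical(readLines(path), readLines(path2))
})

test_that("weights and standardization come from training rows only", {
  ds <- separable_dataset(n_per_class = 20)
  tr_idx <- c(1:15, 21:35)
  tr <- ecgddd:::new_dataset(ds$X[tr_idx, ], ds$y[tr_idx],
                             ds$groups[tr_idx])
  model <- svm_train(tr, kernel_spec("linear", weighted = TRUE), C = 1)
  st <- fit_standardization(tr)
  expect_equal(model$stats$mean, st$mean)
  z <- standardize_dataset(tr, st)
  expect_equal(model$weights, correlation_weights(z))
})
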