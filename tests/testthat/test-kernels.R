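test_that("base kernels evaluate their closed forms", {
  x <- c(1, 2)
  y <- c(3, 4)
  expect_equal(base_kernel(x, y, kernel_spec("linear")), 11)
  expect_equal(base_kernel(x, y, kernel_spec("quadratic")), 144)
  expect_equal(base_kernel(x, y, kernel_spec("poly3")), 1728)
  expect_equal(base_kernel(x, x, kernel_spec("rbf")), 1)
  expect_equal(base_kernel(x, y, kernel_spec("rbf", gamma = 0.5)),
               exp(-0.5 * 8))
  # sigma alias: gamma = 1 / (2 sigma^2)
  expect_equal(kernel_spec("rbf", sigma = 2)$gamma, 1 / 8)
  expect_error(base_kernel(x, c(1, 2, 3), kernel_spec("linear")),
               "dimension")
})

test_that("correlation weights rank features by |r| and sum to one", {
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(as.numeric(y), matrix(5, n, 3))
  colnames(X) <- paste0("f", 1:4)
  ds <- ecgddd:::new_dataset(X, y, as.character(1:n))
  w <- correlation_weights(ds)
  expect_equal(unname(w), c(1, 0, 0, 0))

  # 4-row toy against the Pearson formula computed by hand
  Xt <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 2, 1))
  yt <- c(0L, 0L, 1L, 1L)
  dst <- ecgddd:::new_dataset(Xt, yt, as.character(1:4))
  pearson <- function(v, u) {
    num <- sum((v - mean(v)) * (u - mean(u)))
    num / sqrt(sum((v - mean(v))^2) * sum((u - mean(u))^2))
  }
  r <- c(pearson(Xt[, 1], yt), pearson(Xt[, 2], yt))
  expect_equal(unname(correlation_weights(dst)),
               abs(r) / sum(abs(r)))
  expect_equal(sum(correlation_weights(dst)), 1)

  allconst <- ecgddd:::new_dataset(matrix(3, 10, 4), rep(c(0L, 1L), 5),
                                   as.character(1:10))
  expect_warning(wu <- correlation_weights(allconst), "uniform")
  expect_equal(unname(wu), rep(0.25, 4))
})

test_that("the weighted composite kernel is the weighted per-feature sum", {
  expect_equal(weighted_kernel(c(1, 2), c(3, 4), c(0.7, 0.3),
                               kernel_spec("linear", weighted = TRUE)),
               0.7 * 3 + 0.3 * 8)
  # uniform weights and linear family recover the prime kernel / P
  p <- 10
  x <- rnorm(p)
  y <- rnorm(p)
  expect_equal(weighted_kernel(x, y, rep(1 / p, p),
                               kernel_spec("linear", weighted = TRUE)),
               sum(x * y) / p)
  # rbf at zero distance sums the weights
  w <- runif(p)
  w <- w / sum(w)
  expect_equal(weighted_kernel(x, x, w,
                               kernel_spec("rbf", weighted = TRUE)), 1)
  expect_error(weighted_kernel(x, y, rep(1, p), kernel_spec("linear")),
               "sum to 1")
})

test_that("Gram matrices are symmetric, consistent, and PSD", {
  set.seed(7)
  X <- matrix(rnorm(20 * 10), 20, 10)
  w <- runif(10)
  w <- w / sum(w)
  for (fam in c("linear", "quadratic", "poly3", "rbf")) {
    for (weighted in c(FALSE, TRUE)) {
      spec <- kernel_spec(fam, weighted = weighted)
      G <- gram_matrix(X, spec, w = if (weighted) w)
      expect_identical(G, t(G))
      # agrees with the scalar kernel entrywise
      ref <- if (weighted) {
        weighted_kernel(X[2, ], X[5, ], w, spec)
      } else {
        base_kernel(X[2, ], X[5, ], spec)
      }
      expect_equal(G[2, 5], ref, tolerance = 1e-12)
      ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * sum(diag(G)))
    }
  }
  expect_equal(dim(gram_matrix(X[1, , drop = FALSE],
                               kernel_spec("linear"))), c(1L, 1L))
  # rectangular cross-kernel blocks
  K <- gram_matrix(X[1:4, ], kernel_spec("rbf"), Y = X[5:10, ])
  expect_equal(dim(K), c(4L, 6L))
})

test_that("random weighted Gram matrices stay PSD", {
  set.seed(99)
  fams <- c("linear", "quadratic", "poly3", "rbf")
  for (i in 1:50) {
    X <- matrix(rnorm(15 * 10, sd = runif(1, 0.5, 2)), 15, 10)
    w <- runif(10)
    w <- w / sum(w)
    spec <- kernel_spec(sample(fams, 1), weighted = TRUE)
    G <- gram_matrix(X, spec, w = w)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(G)))
  }
})
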