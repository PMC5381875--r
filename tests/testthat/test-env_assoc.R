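test_that("diversity regression recovers perfect and published fits", {
  alpha <- data.frame(sample = paste0("s", 1:5), shannon = c(1, 2, 3, 4, 5))
  env <- data.frame(sample = paste0("s", 1:5), pH = c(4, 5, 6, 7, 8))
  fit <- diversity_env_regression(alpha, env)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)

  # published per-sample Shannon vs pH across the seven soils
  rich <- study_fixture("richness")
  soil <- study_fixture("env")
  fit2 <- diversity_env_regression(rich, soil)
  expect_equal(fit2$r_squared, 0.9198536, tolerance = 1e-6)
  expect_gt(fit2$slope, 0)
  expect_lt(fit2$p_value, 0.01)
  expect_equal(fit2$n, 7)
})

test_that("degenerate regression inputs are refused", {
  alpha <- data.frame(sample = c("a", "b", "c"), shannon = 1:3)
  env_const <- data.frame(sample = c("a", "b", "c"), pH = c(5, 5, 5))
  expect_error(diversity_env_regression(alpha, env_const), "constant predictor")
  env_two <- data.frame(sample = c("a", "b"), pH = c(5, 6))
  expect_error(diversity_env_regression(alpha, env_two), "3 common samples")
})

test_that("abundant-genus selection applies >= at the threshold", {
  rel <- rbind(kept = c(1.0, 0.2), dropped = c(0.99, 0.5), big = c(30, 40))
  colnames(rel) <- c("s1", "s2")
  out <- select_abundant_genera(rel, 1)
  expect_setequal(rownames(out), c("kept", "big"))
  expect_identical(nrow(select_abundant_genera(rel, 0)), 3L)
})

test_that("RDA recovers exact fits and orthogonal nulls", {
  set.seed(2)
  x <- rnorm(10)
  Y <- matrix(2 * x + 3, ncol = 1, dimnames = list(paste0("s", 1:10), "g1"))
  fit <- rda_fit(Y, matrix(x, dimnames = list(paste0("s", 1:10), "pH")), n_perm = 0)
  expect_equal(unname(fit$percent_of_total[1]), 100, tolerance = 1e-9)
  expect_equal(unname(fit$pseudo_canonical_correlation[1]), 1, tolerance = 1e-9)

  # constraint orthogonal to Y (after centering): no canonical variance
  y <- c(1, -1, 1, -1, 1, -1)
  xo <- c(1, 1, -1, -1, 1, -1) * 0 + c(1, 2, 3, 4, 5, 6)
  xo <- xo - mean(xo)
  y2 <- y - mean(y)
  xo <- xo - sum(xo * y2) / sum(y2^2) * y2   # orthogonalize against y
  fit2 <- rda_fit(matrix(y, ncol = 1), matrix(xo, ncol = 1), n_perm = 0)
  expect_lt(sum(fit2$eigenvalues), 1e-20)
})

test_that("RDA with space-spanning constraints equals PCA of Y", {
  set.seed(8)
  n <- 7
  Y <- matrix(rnorm(n * 10), n, 10, dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
  X <- matrix(rnorm(n * (n - 1)), n, n - 1,
              dimnames = list(paste0("s", 1:n), paste0("x", 1:(n - 1))))
  fit <- rda_fit(Y, X, n_perm = 0)
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  expect_equal(unname(fit$eigenvalues), unname(pc$sdev[1:length(fit$eigenvalues)]^2),
               tolerance = 1e-8)
  expect_equal(sum(fit$eigenvalues), fit$total_variance, tolerance = 1e-8)
})

test_that("RDA canonical variance is bounded by total variance", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    Y <- matrix(rnorm(n * 8), n, 8)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    fit <- rda_fit(Y, X, n_perm = 0)
    expect_lte(sum(fit$eigenvalues), fit$total_variance + 1e-10)
    expect_true(all(fit$pseudo_canonical_correlation <= 1 + 1e-10))
  }
})

test_that("RDA agrees with an independent constrained-ordination implementation", {
  skip_if_not_installed("vegan")
  set.seed(4)
  n <- 8
  Y <- matrix(rpois(n * 12, 20), n, 12,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:12)))
  X <- data.frame(pH = rnorm(n), NO3 = rnorm(n))
  fit <- rda_fit(Y, X, n_perm = 0)
  ref <- vegan::rda(Y ~ pH + NO3, data = X)
  expect_equal(unname(fit$eigenvalues),
               unname(ref$CCA$eig[seq_along(fit$eigenvalues)]), tolerance = 1e-8)
  expect_equal(fit$total_variance, unname(ref$tot.chi), tolerance = 1e-8)
})

test_that("RDA is invariant to consistent sample reordering", {
  set.seed(19)
  n <- 9
  Y <- matrix(rnorm(n * 6), n, 6)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  fit1 <- rda_fit(Y, X, n_perm = 0)
  perm <- sample(n)
  fit2 <- rda_fit(Y[perm, ], X[perm, ], n_perm = 0)
  expect_equal(fit1$eigenvalues, fit2$eigenvalues, tolerance = 1e-10)
  expect_equal(fit1$percent_of_total, fit2$percent_of_total, tolerance = 1e-10)
})

test_that("collinear constraints are reported by name", {
  set.seed(23)
  n <- 8
  Y <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  X <- cbind(X, c = X[, "a"] * 2)
  expect_error(rda_fit(Y, X, n_perm = 0), "collinear")
})

test_that("permutation P is roughly uniform for an unrelated constraint", {
  set.seed(31)
  pvals <- replicate(200, {
    Y <- matrix(rnorm(7 * 4), 7, 4)
    X <- matrix(rnorm(7), 7, 1, dimnames = list(NULL, "noise"))
    rda_fit(Y, X, n_perm = 59, seed = sample.int(1e6, 1))$term_effects$p_value
  })
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})
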