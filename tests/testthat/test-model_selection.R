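test_that("lambda grid spans [min_ratio*lmax, lmax] on a log scale", {
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.8; S[1, 3] <- S[3, 1] <- 0.3
  g <- lambda_grid(S, n_lambda = 10, min_ratio = 0.01)
  expect_equal(g$lambda_max, 0.8)
  expect_equal(max(g$values), 0.8)
  expect_equal(min(g$values), 0.008)
  expect_true(all(diff(g$values) < 0))
  expect_equal(length(g$values), 10)
  # log-spacing: ratios between consecutive values are constant
  expect_equal(diff(log(g$values)), rep(diff(log(g$values))[1], 9))

  g2 <- lambda_grid(S, n_lambda = 2, min_ratio = 0.01)
  expect_equal(g2$values, c(0.8, 0.008))
  expect_error(lambda_grid(diag(4)), "degenerate")
})

test_that("criterion arithmetic matches the closed form", {
  # identity Omega and S, lambda 0: ll = (10/2)(0 - 3) = -15, k = 0
  expect_equal(criterion_score(diag(3), diag(3), 10, 0, "BIC"), 30)
  expect_equal(criterion_score(diag(3), diag(3), 10, 0, "AIC"), 30)
  # EBIC with gamma = 0 equals BIC on an edge-bearing model
  Om <- matrix(c(1.2, 0.3, 0, 0.3, 1.1, 0, 0, 0, 0.9), 3, 3)
  S <- random_spd(3, seed = 51)
  expect_equal(criterion_score(Om, S, 20, 0.1, "EBIC", ebic_gamma = 0),
               criterion_score(Om, S, 20, 0.1, "BIC"))
  expect_error(criterion_score(diag(3), diag(3), 1, 0), "at least 2")
})

test_that("criterion matches an independent symbolic evaluation", {
  Om <- matrix(c(2.0, -0.5, 0,
                 -0.5, 1.5, 0.3,
                 0, 0.3, 1.0), 3, 3, byrow = TRUE)
  S <- matrix(c(1.0, 0.2, 0.1,
                0.2, 1.0, -0.3,
                0.1, -0.3, 1.0), 3, 3, byrow = TRUE)
  n <- 25; lam <- 0.15
  # oracle path: determinant() and explicit elementwise sums
  ld <- as.numeric(determinant(Om, logarithm = TRUE)$modulus)
  tr <- sum(diag(S %*% Om))
  pen_l1 <- lam * (2 * (0.5 + 0.3))
  ll <- (n / 2) * (ld - tr - pen_l1)
  k <- 2
  expect_equal(criterion_score(Om, S, n, lam, "BIC"), -2 * ll + k * log(n))
  expect_equal(criterion_score(Om, S, n, lam, "AIC"), -2 * ll + 2 * k)
  expect_equal(criterion_score(Om, S, n, lam, "EBIC", 0.5),
               -2 * ll + k * log(n) + 2 * k * log(3))
  # non-PD input is flagged, not silently scored
  expect_true(is.na(criterion_score(matrix(c(1, 2, 2, 1), 2), diag(2), 10, 0)))
})

test_that("one-standard-error rule picks the sparsest model within one SE", {
  lambdas <- c(0.5, 0.3, 0.2, 0.1)
  means <- c(10.5, 10.4, 10.0, 11.0)
  ses <- c(0.2, 0.2, 0.6, 0.2)
  expect_equal(choose_lambda(lambdas, means, ses, one_se = TRUE), 0.5)
  expect_equal(choose_lambda(lambdas, means, ses, one_se = FALSE), 0.2)
  # NA criteria are excluded
  means2 <- c(NA, 10.4, 10.0, 11.0)
  expect_equal(choose_lambda(lambdas, means2, ses, one_se = FALSE), 0.2)
  expect_error(choose_lambda(0.1, NA, 0.1), "no usable")
})

test_that("cross-validated selection is reproducible and well-formed", {
  sim <- simulate_truth(p = 20, density = 0.15, seed = 61)
  D <- sample_expression(sim$Sigma_true, 80, seed = 62)
  pr <- prior_network(sim$prior_W)
  S <- crossprod(standardize_expression(D)) / 79
  grid <- lambda_grid(S, n_lambda = 6, min_ratio = 0.1)
  t1 <- cv_select_lambda(D, pr, grid, K = 4, seed = 7)
  t2 <- cv_select_lambda(D, pr, grid, K = 4, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "chosen_lambda"), attr(t2, "chosen_lambda"))
  expect_true(attr(t1, "chosen_lambda") %in% grid$values)
  # edge count non-increasing in lambda
  expect_true(all(diff(t1$k) >= 0))
  # a one-lambda grid returns that lambda
  t3 <- cv_select_lambda(D, pr, 0.4, K = 4, seed = 7)
  expect_equal(attr(t3, "chosen_lambda"), 0.4)
  expect_error(cv_select_lambda(D, pr, grid, K = 200), "exceed")
})

test_that("whole-data criterion mode uses the same formula as CV", {
  sim <- simulate_truth(p = 15, density = 0.2, seed = 63)
  D <- sample_expression(sim$Sigma_true, 90, seed = 64)
  pr <- prior_network(matrix(0, 15, 15))
  Dstd <- standardize_expression(D)
  S <- crossprod(Dstd) / 89
  lambdas <- c(0.5, 0.3)
  tab <- ic_select_lambda(D, pr, lambdas)
  # reconstruct each value through the exported criterion operation
  for (j in seq_along(lambdas)) {
    fit <- fit_ahglasso(D, pr, lambdas[j], tol = 1e-4, max_iter = 100)
    expect_equal(tab$mean[j],
                 criterion_score(fit$precision, S, nrow(D), 0, "BIC"),
                 tolerance = 1e-6)
  }
  expect_equal(attr(tab, "K"), 1)
})

test_that("stronger complexity penalties select sparser models", {
  sim <- simulate_truth(p = 60, density = 0.06, seed = 65)
  D <- sample_expression(sim$Sigma_true, 150, seed = 66)
  pr <- prior_network(matrix(0, 60, 60))
  S <- crossprod(standardize_expression(D)) / 149
  grid <- lambda_grid(S, n_lambda = 10, min_ratio = 0.05)
  lam_for <- function(crit) {
    tune <- cv_select_lambda(D, pr, grid, K = 5, criterion = crit, seed = 67)
    attr(tune, "chosen_lambda")
  }
  # AIC's 2k < BIC's k log n < EBIC's k log n + 4*gamma*k log p
  expect_lte(lam_for("AIC"), lam_for("BIC"))
  expect_lte(lam_for("BIC"), lam_for("EBIC"))
  expect_lt(lam_for("AIC"), lam_for("EBIC"))
})
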