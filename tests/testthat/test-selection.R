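test_that("screening keeps high-correlation nodes and forced keeps", {
  r <- c(1, 0.5, 0.2, -0.4)
  expect_equal(screen_candidates(r, 1, 0.3), c(2L, 4L))
  expect_equal(screen_candidates(r, 1, 0), 2:4)
  expect_equal(screen_candidates(r, 1, 1, forced_keep = 3L), 3L)
  # the node itself is never a candidate, even if forced
  expect_false(1L %in% screen_candidates(r, 1, 0, forced_keep = 1L))
  expect_error(screen_candidates(c(0.5, 1.7), 1, 0.1), "\\[-1, 1\\]")
})

test_that("neighborhood at lambda_max is empty without prior help", {
  D <- mvn_from_precision(chain_precision(), 400, seed = 21)
  Dstd <- standardize_expression(D)
  S <- crossprod(Dstd) / (nrow(D) - 1)
  lmax <- max(abs(S[upper.tri(S)]))
  fit <- neighborhood_lasso(Dstd, 1, lmax)
  expect_length(fit$support, 0)
})

test_that("a prior weight of 1 removes the penalty entirely", {
  D <- mvn_from_precision(chain_precision(), 300, seed = 22)
  Dstd <- standardize_expression(D)
  # node 1 vs node 3: conditionally independent, but unpenalized OLS keeps
  # the covariate with probability one
  fit <- neighborhood_lasso(Dstd, 1, lam = 0.9, prior_neighbors = 3L,
                            prior_weights = 1)
  expect_true(3L %in% fit$support)
})

test_that("chain data recovers the conditional-independence pattern", {
  Omega <- chain_precision()
  D <- mvn_from_precision(Omega, 5000, seed = 23)
  Dstd <- standardize_expression(D)
  # oracle: sample partial correlations from the inverted sample correlation
  S <- crossprod(Dstd) / (nrow(D) - 1)
  P <- -stats::cov2cor(solve(S))
  expect_gt(abs(P[1, 2]), 0.15)
  expect_gt(abs(P[2, 3]), 0.15)
  expect_lt(abs(P[1, 3]), 0.05)
  fit2 <- neighborhood_lasso(Dstd, 2, lam = 0.05)
  expect_setequal(fit2$support, c(1L, 3L))
  fit1 <- neighborhood_lasso(Dstd, 1, lam = 0.05)
  expect_equal(fit1$support, 2L)
})

test_that("with a zero prior the fit equals plain Lasso (oracle: glmnet)", {
  set.seed(24)
  sim <- simulate_truth(p = 30, density = 0.1, seed = 9)
  D <- sample_expression(sim$Sigma_true, 150, seed = 10)
  Dstd <- standardize_expression(D)
  n <- nrow(Dstd)
  for (node in c(1, 7, 20)) {
    lam <- 0.25
    fit <- neighborhood_lasso(Dstd, node, lam, screen = FALSE)
    g <- glmnet::glmnet(Dstd[, -node], Dstd[, node], alpha = 1,
                        lambda = lam, standardize = FALSE, intercept = FALSE,
                        thresh = 1e-8)
    sup_g <- setdiff(seq_len(30), node)[as.vector(g$beta) != 0]
    expect_setequal(fit$support, sup_g)
  }
})

test_that("screening at the penalty level does not change the support", {
  set.seed(25)
  sim <- simulate_truth(p = 20, density = 0.15, seed = 12)
  D <- sample_expression(sim$Sigma_true, 120, seed = 13)
  Dstd <- standardize_expression(D)
  for (node in 1:10) {
    lam <- 0.3
    screened <- neighborhood_lasso(Dstd, node, lam, screen = TRUE)
    full <- neighborhood_lasso(Dstd, node, lam, screen = FALSE)
    expect_setequal(screened$support, full$support)
  }
})

test_that("screened candidate sets are nested along the lambda path", {
  set.seed(26)
  sim <- simulate_truth(p = 25, density = 0.12, seed = 14)
  D <- sample_expression(sim$Sigma_true, 100, seed = 15)
  Dstd <- standardize_expression(D)
  S <- crossprod(Dstd) / 99
  lambdas <- lambda_grid(S, n_lambda = 8, min_ratio = 0.1)$values
  r <- as.vector(crossprod(Dstd, Dstd[, 1])) / 99
  cands <- lapply(lambdas, function(l) screen_candidates(r, 1, l))
  for (j in 2:length(lambdas)) {
    expect_true(all(cands[[j - 1]] %in% cands[[j]]))
  }
  # skeleton edge counts are non-increasing in lambda
  pr0 <- prior_network(matrix(0, 25, 25))
  sk <- ahglasso:::.skeletons_path(Dstd, pr0, lambdas)
  counts <- vapply(sk, function(A) sum(A[upper.tri(A)]), numeric(1))
  expect_true(all(diff(rev(counts)) <= 0))
})

test_that("skeleton assembly follows the OR and AND rules", {
  fits <- list(list(node = 1, support = 2L), list(node = 2, support = integer(0)),
               list(node = 3, support = integer(0)))
  A_or <- build_skeleton(fits, 3, "OR")
  expect_equal(A_or[1, 2], 1L)
  expect_equal(A_or, t(A_or))
  A_and <- build_skeleton(fits, 3, "AND")
  expect_true(all(A_and == 0))
  empty <- list(list(node = 1, support = integer(0)),
                list(node = 2, support = integer(0)))
  expect_true(all(build_skeleton(empty, 2) == 0))
  expect_error(build_skeleton(fits[1:2], 3), "one neighborhood fit per node")
})
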