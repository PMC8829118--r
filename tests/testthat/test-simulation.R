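test_that("scale-free generator hits the target density", {
  A <- simulate_scale_free(1000, 0.02, seed = 71)
  target <- 1000 * 999 / 2 * 0.02
  expect_lt(abs(sum(A[upper.tri(A)]) - target) / target, 0.25)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))

  A5 <- simulate_scale_free(500, 0.02, seed = 72)
  # m = 5 edges per incoming node: close to m(p - m)
  expect_lt(abs(sum(A5[upper.tri(A5)]) - 5 * 495) / (5 * 495), 0.25)
  expect_identical(simulate_scale_free(500, 0.02, seed = 72), A5)
  expect_error(simulate_scale_free(200, 0.001, seed = 73), "density too low")
})

test_that("scale-free degree distribution is right-skewed", {
  for (s in 74:76) {
    A <- simulate_scale_free(500, 0.02, seed = s)
    deg <- rowSums(A)
    expect_gt(max(deg), 4 * median(deg))
  }
})

test_that("precision construction draws magnitudes in [vmin, vmax]", {
  A <- simulate_scale_free(50, 0.1, seed = 77)
  Om <- build_precision(A, seed = 78)
  vals <- abs(Om[upper.tri(Om) & A == 1])
  expect_true(all(vals >= 0.2 & vals <= 1))
  expect_equal(diag(Om), rep(1, 50))
  expect_true(all(Om[A == 0 & upper.tri(A)] == 0))
  expect_identical(build_precision(A, seed = 78), Om)

  empty <- build_precision(matrix(0L, 5, 5), seed = 79)
  expect_equal(empty, diag(5))
  expect_error(build_precision(A, vmin = 0.5, vmax = 0.2, seed = 1), "vmin")
})

test_that("positive-definite shift follows the eigenvalue formula", {
  M <- diag(c(-0.3, 1))
  out <- ensure_positive_definite(M)
  expect_equal(min(eigen(out)$values), 0.1)
  expect_equal(ensure_positive_definite(diag(2)), 2.1 * diag(2))
  for (s in 80:83) {
    A <- simulate_scale_free(60, 0.1, seed = s)
    Om <- ensure_positive_definite(build_precision(A, seed = s + 10))
    expect_gte(min(eigen(Om, symmetric = TRUE)$values), 0.1 - 1e-10)
    Sig <- chol2inv(chol(Om))
    expect_lt(max(abs(Om %*% Sig - diag(60))), 1e-8)
  }
  expect_error(ensure_positive_definite(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("perturbation respects the 0.2 reset rule and sparsity bound", {
  for (s in 84:86) {
    A <- simulate_scale_free(80, 0.08, seed = s)
    Om <- build_precision(A, seed = s + 20)
    n_before <- sum(Om[upper.tri(Om)] != 0)
    P <- perturb_precision(Om, seed = s + 40)
    expect_equal(P, t(P))
    expect_equal(diag(P), diag(Om))
    nz <- P[upper.tri(P)]
    nz <- nz[nz != 0]
    # every altered entry below 0.2 in magnitude was reset to zero
    expect_true(all(abs(nz) >= 0.2))
    n_after <- sum(P[upper.tri(P)] != 0)
    expect_lte(n_after, 2 * n_before)
  }
})

test_that("edge mutation preserves the edge count exactly", {
  A <- simulate_scale_free(60, 0.1, seed = 87)
  Om <- build_precision(A, seed = 88)
  up <- upper.tri(Om)
  n0 <- sum(Om[up] != 0)
  expect_identical(mutate_edges(Om, 0, seed = 89), Om)
  for (pct in c(0.2, 0.5, 1)) {
    M <- mutate_edges(Om, pct, seed = 90)
    expect_equal(sum(M[up] != 0), n0)
  }
  M1 <- mutate_edges(Om, 1, seed = 91)
  expect_equal(sum(M1[up] != 0 & Om[up] != 0), 0)
  # new magnitudes live in [0.2, 1]
  new <- abs(M1[up][M1[up] != 0])
  expect_true(all(new >= 0.2 & new <= 1))
})

test_that("overlap is intersection over target edges", {
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(overlap_pct(A, A), 100)
  B <- matrix(0L, 4, 4); B[1, 3] <- B[3, 1] <- B[2, 4] <- B[4, 2] <- 1L
  expect_equal(overlap_pct(A, B), 0)
  C <- matrix(0L, 4, 4); C[1, 2] <- C[2, 1] <- 1L
  expect_equal(overlap_pct(C, A), 50)
  expect_error(overlap_pct(A, matrix(0L, 4, 4)), "no edges")
})

test_that("subset priors are true-edge subsamples", {
  A <- simulate_scale_free(60, 0.1, seed = 92)
  expect_equal(subset_prior(A, 1, seed = 93), A, ignore_attr = TRUE)
  half <- subset_prior(A, 0.5, seed = 94)
  expect_equal(sum(half[upper.tri(half)]),
               round(0.5 * sum(A[upper.tri(A)])))
  expect_true(all(half[A == 0] == 0))
})

test_that("prior weights are absolute partial correlations", {
  expect_true(all(prior_weights(diag(3)) == 0))
  W <- prior_weights(matrix(c(2, -1, -1, 2), 2))
  expect_equal(W[1, 2], 0.5)
  A <- simulate_scale_free(40, 0.1, seed = 95)
  Wp <- prior_weights(build_precision(A, seed = 96))
  expect_true(all(Wp >= 0 & Wp <= 1))
  expect_true(all(diag(Wp) == 0))
})

test_that("expression sampling matches the target covariance at large n", {
  Om <- chain_precision()
  Sigma <- solve(Om)
  X <- sample_expression(Sigma, 50000, seed = 97)
  expect_identical(sample_expression(Sigma, 50000, seed = 97), X)
  S_hat <- crossprod(scale(X, scale = FALSE)) / (nrow(X) - 1)
  rel <- norm(S_hat - Sigma, "F") / norm(Sigma, "F")
  expect_lt(rel, 0.05)
  expect_true(all(abs(colMeans(X)) < 3 * sqrt(diag(Sigma)) / sqrt(50000) * 3))
  expect_error(sample_expression(matrix(c(1, 2, 2, 1), 2), 10, 1),
               "positive definite")
})

test_that("the full simulation pipeline is seed-deterministic", {
  s1 <- simulate_truth(p = 40, density = 0.08, overlap = 70, seed = 98)
  s2 <- simulate_truth(p = 40, density = 0.08, overlap = 70, seed = 98)
  expect_identical(s1$Omega_true, s2$Omega_true)
  expect_identical(s1$prior_W, s2$prior_W)
  expect_identical(s1$adjacency_true, s2$adjacency_true)
  # realized overlap is the mutation target up to rounding
  expect_equal(s1$overlap_pct, 70, tolerance = 2)
  # truth adjacency equals the nonzero pattern of the precision
  off <- upper.tri(s1$Omega_true)
  expect_equal((s1$Omega_true[off] != 0) * 1L, s1$adjacency_true[off])
  # Sigma is the inverse of Omega
  expect_lt(max(abs(s1$Omega_true %*% s1$Sigma_true - diag(40))), 1e-8)
})

test_that("non-scale-free topologies are generated at matched density", {
  for (ty in c("random", "hub", "cluster")) {
    A <- simulate_scale_free(200, 0.04, seed = 99, type = ty)
    expect_equal(A, t(A))
    dens <- sum(A[upper.tri(A)]) / (200 * 199 / 2)
    expect_lt(abs(dens - 0.04) / 0.04, 0.5)
  }
})
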