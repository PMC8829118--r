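# Shared fixture builders; everything is generated in code under fixed seeds.

# A small positive-definite "chain" precision matrix: 1-2 and 2-3 connected,
# 1-3 conditionally independent.
chain_precision <- function() {
  matrix(c(1.0, 0.4, 0.0,
           0.4, 1.5, 0.5,
           0.0, 0.5, 1.0), 3, 3, byrow = TRUE)
}

# Draw n samples from N(0, solve(Omega)) deterministically.
mvn_from_precision <- function(Omega, n, seed) {
  Sigma <- chol2inv(chol(Omega))
  Sigma <- (Sigma + t(Sigma)) / 2
  sample_expression(Sigma, n, seed)
}

# Random sparse symmetric skeleton on p nodes with each edge present with
# probability prob.
random_skeleton <- function(p, prob, seed) {
  set.seed(seed)
  A <- matrix(0L, p, p)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, prob)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0L
  A
}

# Well-conditioned random covariance for small p.
random_spd <- function(p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(5 * p * p), 5 * p, p)
  S <- crossprod(X) / (5 * p)
  (S + t(S)) / 2
}

# Brute-force constrained Gaussian MLE via BFGS over the free entries
# (diagonal + skeleton edges), with analytic gradient 2*(Omega^-1 - S) off
# the diagonal and (Omega^-1 - S) on it. Independent of the package's
# cyclic-regression solver.
bruteforce_cmle <- function(S, A) {
  p <- nrow(S)
  up <- which(upper.tri(A) & A == 1)
  n_off <- length(up)
  build <- function(theta) {
    Om <- matrix(0, p, p)
    diag(Om) <- theta[seq_len(p)]
    if (n_off) {
      Om[up] <- theta[p + seq_len(n_off)]
      Om <- Om + t(Om) - diag(diag(Om))
    }
    Om
  }
  obj <- function(theta) {
    Om <- build(theta)
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(S * Om))
  }
  grad <- function(theta) {
    Om <- build(theta)
    G <- -(chol2inv(chol(Om)) - S)
    c(diag(G), if (n_off) 2 * G[up] else NULL)
  }
  theta0 <- c(1 / diag(S), rep(0, n_off))
  fit <- optim(theta0, obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  build(fit$par)
}
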