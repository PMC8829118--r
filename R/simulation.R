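# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps every generator function independently
# reproducible without clobbering the session RNG.
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a stream offset
#'
#' One master seed drives every stage of a pipeline through a fixed counter
#' scheme, so any single replicate or stage can be re-run in isolation. All
#' arithmetic stays below 2^53, so the modulus is exact in double precision
#' and the result fits a 32-bit integer.
#'
#' @param master Master integer seed.
#' @param offset Integer stream offset (stage/replicate counter).
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer(((master %% 94906249) * 22695477 + offset) %% 2147483647)
}

#' Simulate a sparse network adjacency
#'
#' Generates the ground-truth graph for the simulation study. The default
#' \code{"scale_free"} mode uses Barabasi-Albert preferential attachment with
#' \code{m = round(density * (p - 1) / 2)} edges per incoming node, which
#' targets the requested edge density; \code{"random"} is Erdos-Renyi,
#' \code{"hub"} a union of star subgraphs, and \code{"cluster"} a block
#' (stochastic-block-like) construction, all at matched density.
#'
#' @param p Number of nodes (at least 10).
#' @param density Target edge density in (0, 1); biological PPI networks sit
#'   around 0.02-0.04.
#' @param seed Integer seed.
#' @param type Graph topology (see above).
#' @return Symmetric binary p x p adjacency matrix with zero diagonal.
#' @export
simulate_scale_free <- function(p, density, seed,
                                type = c("scale_free", "random", "hub",
                                         "cluster")) {
  type <- match.arg(type)
  stopifnot(p >= 10, density > 0, density < 1)
  n_target <- round(density * p * (p - 1) / 2)
  g <- .with_seed(seed, switch(type,
    scale_free = {
      m <- round(density * (p - 1) / 2)
      if (m < 1) stop("density too low for p: edges-per-node rounds to 0")
      igraph::sample_pa(p, m = m, directed = FALSE)
    },
    random = igraph::sample_gnm(p, n_target),
    hub = {
      n_hubs <- max(2L, round(p / 50))
      sizes <- diff(round(seq(0, p, length.out = n_hubs + 1)))
      base <- igraph::disjoint_union(lapply(sizes, igraph::make_star,
                                            mode = "undirected"))
      extra <- n_target - igraph::ecount(base)
      if (extra > 0) {
        avail <- which(igraph::as_adjacency_matrix(base, sparse = FALSE) == 0,
                       arr.ind = TRUE)
        avail <- avail[avail[, 1] < avail[, 2], , drop = FALSE]
        pick <- avail[sample.int(nrow(avail), min(extra, nrow(avail))), ,
                      drop = FALSE]
        base <- igraph::add_edges(base, t(pick))
      }
      base
    },
    cluster = {
      n_blocks <- max(2L, round(p / 100))
      sizes <- diff(round(seq(0, p, length.out = n_blocks + 1)))
      within <- min(1, n_target / sum(sizes * (sizes - 1) / 2))
      pm <- matrix(within * 0.05, n_blocks, n_blocks)
      diag(pm) <- within
      igraph::sample_sbm(p, pref.matrix = pm, block.sizes = sizes)
    }))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- pmin(A, 1L)
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

#' Assign edge magnitudes to build a precision matrix
#'
#' Each edge of the adjacency receives a magnitude drawn uniformly from
#' \code{[vmin, vmax]} (symmetric placement); the diagonal is 1. The result
#' is the pre-shift precision matrix; apply
#' [ensure_positive_definite()] before inverting.
#'
#' @param adjacency Symmetric binary adjacency matrix.
#' @param vmin,vmax Magnitude range, default 0.2 to 1.
#' @param seed Integer seed.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
build_precision <- function(adjacency, vmin = 0.2, vmax = 1.0, seed) {
  if (vmin <= 0 || vmin >= vmax) stop("need 0 < vmin < vmax")
  A <- as.matrix(adjacency)
  p <- nrow(A)
  Omega <- matrix(0, p, p)
  up <- which(upper.tri(A) & A != 0)
  if (length(up)) {
    vals <- .with_seed(seed, stats::runif(length(up), vmin, vmax))
    Omega[up] <- vals
    Omega <- Omega + t(Omega)
  }
  diag(Omega) <- 1
  Omega
}

#' Shift a precision matrix to be positive definite
#'
#' Returns \eqn{\Omega + (|\lambda_1| + 0.1) I}, where \eqn{\lambda_1} is the
#' smallest eigenvalue of the input. The shift is applied unconditionally, so
#' the output's smallest eigenvalue is always at least 0.1.
#'
#' @param Omega Symmetric matrix.
#' @return Positive-definite matrix with the same off-diagonal entries.
#' @export
ensure_positive_definite <- function(Omega) {
  Omega <- as.matrix(Omega)
  if (!isSymmetric(unname(Omega), tol = 1e-10)) stop("Omega must be symmetric")
  l1 <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  Omega + diag(abs(l1) + 0.1, nrow(Omega))
}

#' Randomly perturb a precision matrix
#'
#' Emulates dynamic rewiring of a biological network: symmetric
#' Uniform(-0.5, 0.5) noise is added to every existing off-diagonal entry and
#' to an equal-count random sample of zero positions; any altered entry whose
#' absolute value falls below 0.2 is reset to 0. Strong connections are
#' therefore likely to survive while weak ones can vanish, and sparsity stays
#' at a similar level. The diagonal is untouched.
#'
#' @param Omega Pre-shift precision matrix (unit diagonal).
#' @param seed Integer seed.
#' @return Perturbed symmetric matrix.
#' @export
perturb_precision <- function(Omega, seed) {
  Omega <- as.matrix(Omega)
  p <- nrow(Omega)
  up <- upper.tri(Omega)
  nz <- which(up & Omega != 0)
  z <- which(up & Omega == 0)
  .with_seed(seed, {
    z_pick <- z[sample.int(length(z), min(length(nz), length(z)))]
    idx <- c(nz, z_pick)
    Omega[idx] <- Omega[idx] + stats::runif(length(idx), -0.5, 0.5)
    Omega[idx][abs(Omega[idx]) < 0.2] <- 0
  })
  Omega[lower.tri(Omega)] <- t(Omega)[lower.tri(Omega)]
  Omega
}

#' Rewire a fixed fraction of edges
#'
#' Removes \code{round(mutation_pct * |E|)} randomly chosen edges and creates
#' the same number of new edges at random zero positions with magnitudes
#' drawn uniformly from \code{[0.2, 1]}. The edge count is preserved exactly;
#' the prior-vs-target overlap becomes approximately
#' \code{100 * (1 - mutation_pct)} percent.
#'
#' @param Omega Pre-shift precision matrix.
#' @param mutation_pct Fraction of edges to rewire, in \code{[0, 1]}.
#' @param seed Integer seed.
#' @return Mutated symmetric matrix with identical edge count.
#' @export
mutate_edges <- function(Omega, mutation_pct, seed) {
  stopifnot(mutation_pct >= 0, mutation_pct <= 1)
  Omega <- as.matrix(Omega)
  up <- upper.tri(Omega)
  nz <- which(up & Omega != 0)
  z <- which(up & Omega == 0)
  n_mut <- round(mutation_pct * length(nz))
  if (n_mut > length(z)) stop("not enough zero positions to rewire into")
  if (n_mut > 0) {
    .with_seed(seed, {
      drop_idx <- nz[sample.int(length(nz), n_mut)]
      add_idx <- z[sample.int(length(z), n_mut)]
      Omega[drop_idx] <- 0
      Omega[add_idx] <- stats::runif(n_mut, 0.2, 1)
    })
  }
  Omega[lower.tri(Omega)] <- t(Omega)[lower.tri(Omega)]
  Omega
}

#' Prior/target edge-set overlap
#'
#' The overlap \eqn{\rho} is the percentage of target-network edges that are
#' also present in the prior network, computed over the strict upper triangle
#' of the binarized matrices.
#'
#' @param adj_prior,adj_true Symmetric binary (or binarizable) matrices of
#'   the same shape.
#' @return Scalar percentage in \code{[0, 100]}.
#' @export
overlap_pct <- function(adj_prior, adj_true) {
  A <- as.matrix(adj_prior) != 0
  B <- as.matrix(adj_true) != 0
  if (!identical(dim(A), dim(B))) stop("shape mismatch")
  up <- upper.tri(A)
  n_true <- sum(B[up])
  if (n_true == 0) stop("target network has no edges")
  100 * sum(A[up] & B[up]) / n_true
}

#' Subset prior: retain a fraction of the true edges
#'
#' Models partially-known (incomplete but clean) prior information: the prior
#' keeps \code{round(subset_pct * |E_true|)} uniformly sampled true edges and
#' contains no false edges.
#'
#' @param adj_true Symmetric binary adjacency of the target network.
#' @param subset_pct Fraction of true edges retained, in (0, 1].
#' @param seed Integer seed.
#' @return Binary adjacency, always a subgraph of \code{adj_true}.
#' @export
subset_prior <- function(adj_true, subset_pct, seed) {
  stopifnot(subset_pct > 0, subset_pct <= 1)
  A <- as.matrix(adj_true)
  out <- matrix(0L, nrow(A), ncol(A))
  nz <- which(upper.tri(A) & A != 0)
  n_keep <- round(subset_pct * length(nz))
  keep <- .with_seed(seed, nz[sample.int(length(nz), n_keep)])
  out[keep] <- 1L
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Prior edge weights from a precision matrix
#'
#' The absolute partial correlation derived from the prior network's
#' precision matrix serves as the prior edge weight (direction is discarded,
#' as STRING-style association scores are undirected). Applied to the
#' pre-shift precision (unit diagonal) this yields weights equal to the edge
#' magnitudes, spanning \code{[0.2, 1]} like filtered STRING scores.
#'
#' @param Omega_prior Precision matrix with positive diagonal.
#' @return Symmetric weight matrix in \code{[0, 1]} with zero diagonal.
#' @export
prior_weights <- function(Omega_prior) {
  W <- abs(partial_correlations(Omega_prior))
  W <- pmin(W, 1)
  diag(W) <- 0
  W
}

#' Draw multivariate-normal expression data
#'
#' Samples n i.i.d. rows from \eqn{N(0, \Sigma_{true})} via the Cholesky
#' factor.
#'
#' @param Sigma_true Positive-definite covariance matrix.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return n x p numeric matrix; column names are taken from
#'   \code{Sigma_true} if present.
#' @export
sample_expression <- function(Sigma_true, n, seed) {
  Sigma_true <- as.matrix(Sigma_true)
  R <- tryCatch(chol(Sigma_true),
                error = function(e) stop("covariance is not positive definite"))
  p <- ncol(Sigma_true)
  Z <- .with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  X <- Z %*% R
  colnames(X) <- colnames(Sigma_true)
  X
}

#' Simulate a complete ground-truth instance
#'
#' Runs the full simulation pipeline: scale-free (or other topology) prior
#' network, edge magnitudes in \code{[0.2, 1]}, prior weights as absolute
#' partial correlations, optional random perturbation, controlled rewiring to
#' reach a target prior/target overlap, the positive-definite shift, and the
#' implied covariance. All stage seeds are derived from \code{seed}.
#'
#' @param p,density,type Passed to [simulate_scale_free()].
#' @param overlap Target overlap percentage in (0, 100]; reached by rewiring
#'   a \code{1 - overlap/100} fraction of edges. \code{NULL} skips rewiring.
#' @param perturb If \code{TRUE}, additionally apply [perturb_precision()]
#'   (overlap then becomes approximate).
#' @param subset_pct If non-\code{NULL}, instead build the prior as a random
#'   subset of the true network retaining this fraction of edges.
#' @param seed Master seed for the instance.
#' @return Object of class \code{sim_truth}: \code{adjacency_true},
#'   \code{Omega_true}, \code{Sigma_true}, \code{prior_W},
#'   \code{adjacency_prior}, realized \code{overlap_pct}, and \code{params}.
#' @export
simulate_truth <- function(p, density, overlap = NULL, perturb = FALSE,
                           subset_pct = NULL, type = "scale_free", seed = 1) {
  adj_prior <- simulate_scale_free(p, density, derive_seed(seed, 1), type)
  Omega0 <- build_precision(adj_prior, seed = derive_seed(seed, 2))
  Om <- Omega0
  if (perturb) Om <- perturb_precision(Om, derive_seed(seed, 3))
  if (!is.null(overlap)) {
    Om <- mutate_edges(Om, 1 - overlap / 100, derive_seed(seed, 4))
  }
  adj_true <- (Om != 0) * 1L
  diag(adj_true) <- 0L
  if (!is.null(subset_pct)) {
    adj_sub <- subset_prior(adj_true, subset_pct, derive_seed(seed, 5))
    # weights for the retained true edges come from the true magnitudes
    Omega_sub <- Om * adj_sub
    diag(Omega_sub) <- 1
    W <- prior_weights(Omega_sub)
    adj_prior <- adj_sub
  } else {
    W <- prior_weights(Omega0)
  }
  Omega_true <- ensure_positive_definite(Om)
  Sigma_true <- chol2inv(chol(Omega_true))
  Sigma_true <- (Sigma_true + t(Sigma_true)) / 2
  structure(list(adjacency_true = adj_true, Omega_true = Omega_true,
                 Sigma_true = Sigma_true, prior_W = W,
                 adjacency_prior = adj_prior,
                 overlap_pct = overlap_pct(adj_prior, adj_true),
                 params = list(p = p, density = density, overlap = overlap,
                               perturb = perturb, subset_pct = subset_pct,
                               type = type, seed = seed)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  up <- upper.tri(x$adjacency_true)
  cat("sim_truth: p = ", nrow(x$adjacency_true), ", true edges = ",
      sum(x$adjacency_true[up]), ", realized overlap = ",
      round(x$overlap_pct, 1), "%\n", sep = "")
  invisible(x)
}
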