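#' Constrained maximum-likelihood precision estimation
#'
#' Maximizes the Gaussian log-likelihood \eqn{\log\det\Omega -
#' \mathrm{tr}(S\Omega)} subject to \eqn{\omega_{ij} = 0} for every non-edge
#' of the skeleton. The solution satisfies the stationarity condition
#' \eqn{(\hat\Omega^{-1})_{ij} = S_{ij}} on all skeleton edges and the
#' diagonal. Computed by cyclic per-node regressions over the working
#' covariance (compiled inner loop); if a regression submatrix fails to
#' factorize a diagonal jitter of \code{1e-8 * trace(S)/p} is added and
#' reported.
#'
#' @param S Sample covariance (here typically correlation) matrix, symmetric
#'   with positive diagonal.
#' @param skeleton Symmetric binary adjacency matrix with zero diagonal.
#' @param tol Convergence tolerance on the maximum entrywise change of the
#'   working covariance per sweep. Default \code{1e-5}.
#' @param max_iter Maximum number of outer sweeps. Default 500.
#' @return An object of class \code{precision_estimate}: list with
#'   \code{Omega} (precision estimate, exact zeros off the skeleton),
#'   \code{Sigma} (its inverse, matching \code{S} on edges and diagonal),
#'   \code{skeleton}, \code{converged}, \code{n_iter}.
#' @export
constrained_mle <- function(S, skeleton, tol = 1e-5, max_iter = 500) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (!all(is.finite(S))) stop("S contains non-finite values")
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  if (any(diag(S) <= 0)) stop("S must have a positive diagonal")
  skeleton <- as.matrix(skeleton)
  if (!identical(dim(skeleton), dim(S))) stop("skeleton/S dimension mismatch")
  if (any(diag(skeleton) != 0)) stop("skeleton must have a zero diagonal")
  S <- (S + t(S)) / 2
  storage.mode(skeleton) <- "integer"
  res <- .cmle_cpp(S, skeleton, tol, as.integer(max_iter))
  if (res$jittered) {
    message("constrained_mle: diagonal jitter applied during factorization")
  }
  structure(list(Omega = res$Omega, Sigma = res$Sigma, skeleton = skeleton,
                 converged = res$converged, n_iter = res$n_iter,
                 delta = res$delta),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- nrow(x$Omega)
  cat("precision_estimate: p = ", p, ", edges = ",
      sum(x$skeleton[upper.tri(x$skeleton)]), ", converged = ",
      x$converged, " (", x$n_iter, " sweeps)\n", sep = "")
  invisible(x)
}

#' Partial correlations from a precision matrix
#'
#' Converts a precision matrix to the conditional (partial) correlation
#' matrix via \eqn{e_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}};
#' the diagonal is set to 0 by convention.
#'
#' @param Omega A \code{precision_estimate} or a numeric precision matrix
#'   with positive diagonal.
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @export
partial_correlations <- function(Omega) {
  if (inherits(Omega, "precision_estimate")) Omega <- Omega$Omega
  Omega <- as.matrix(Omega)
  d <- diag(Omega)
  if (any(d <= 0)) stop("precision matrix must have a positive diagonal")
  s <- 1 / sqrt(d)
  E <- -Omega * tcrossprod(s)
  diag(E) <- 0
  E
}

# Standardize columns to mean 0 and unit sample variance.
#' Standardize an expression matrix
#'
#' Centers each column and scales it to unit sample variance (denominator
#' n - 1), the scale on which correlation screening and the Lasso penalty are
#' commensurate.
#'
#' @param D Numeric n x p matrix.
#' @return Matrix of the same shape with attribute \code{standardized = TRUE}.
#' @export
standardize_expression <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 samples")
  sds <- apply(D, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant column(s): ",
         paste(colnames(D)[sds < 1e-12], collapse = ", "))
  }
  out <- scale(D)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

# Per-lambda skeletons for a decreasing lambda grid; one glmnet path call per
# node. Used by fit_ahglasso (length-1 grid) and the CV loop.
.skeletons_path <- function(Dstd, prior, lambdas, rule = "OR", screen = TRUE) {
  p <- ncol(Dstd)
  lambdas <- sort(lambdas, decreasing = TRUE)
  nl <- length(lambdas)
  sel <- lapply(seq_len(nl), function(k) matrix(0L, p, p))
  for (i in seq_len(p)) {
    nb <- prior$neighbor_sets[[i]]
    res <- .node_lasso_path(Dstd, i, lambdas, prior_neighbors = nb,
                            prior_weights = prior$W[i, nb], screen = screen)
    for (k in seq_len(nl)) {
      sup <- res$fits[[k]]$support
      if (length(sup)) sel[[k]][i, sup] <- 1L
    }
  }
  lapply(sel, function(M) {
    A <- if (rule == "OR") pmax(M, t(M)) else M * t(M)
    diag(A) <- 0L
    A
  })
}

#' Fit the prior-augmented graphical model at a fixed penalty
#'
#' Full estimation pipeline for one penalty level: correlation screening and
#' weighted Lasso neighborhood selection per node (prior neighbors penalized
#' at \eqn{\lambda(1 - w_{ij})}, everything else at \eqn{\lambda}), skeleton
#' assembly, constrained maximum-likelihood precision estimation on the
#' sample correlation matrix, and conversion to partial correlations.
#'
#' @param D n x p expression matrix (samples in rows). Standardized
#'   internally.
#' @param prior A \code{prior_network} over the same features in the same
#'   order (see [prior_network()]); pass a zero matrix for the no-prior
#'   baseline.
#' @param lam Penalty level.
#' @param rule Neighborhood combination rule, \code{"OR"} (default) or
#'   \code{"AND"}.
#' @param screen Apply correlation screening at threshold \code{lam}
#'   (default \code{TRUE}).
#' @param tol,max_iter Convergence controls for [constrained_mle()].
#' @return List of class \code{ahglasso_fit}: \code{skeleton},
#'   \code{precision} (a \code{precision_estimate}), \code{partial_cor},
#'   \code{lambda}, \code{feature_names}.
#' @export
fit_ahglasso <- function(D, prior, lam, rule = c("OR", "AND"), screen = TRUE,
                         tol = 1e-5, max_iter = 500) {
  rule <- match.arg(rule)
  D <- as.matrix(D)
  p <- ncol(D)
  if (nrow(prior$W) != p) stop("prior and expression dimensions differ")
  nms <- colnames(D)
  if (!is.null(nms) && !is.null(prior$node_names) &&
      any(nms != prior$node_names)) {
    stop("prior node order does not match expression feature order")
  }
  Dstd <- standardize_expression(D)
  S <- crossprod(Dstd) / (nrow(Dstd) - 1)
  A <- .skeletons_path(Dstd, prior, lam, rule = rule, screen = screen)[[1]]
  est <- constrained_mle(S, A, tol = tol, max_iter = max_iter)
  E <- partial_correlations(est)
  structure(list(skeleton = A, precision = est, partial_cor = E,
                 lambda = lam, feature_names = nms),
            class = "ahglasso_fit")
}

#' @export
print.ahglasso_fit <- function(x, ...) {
  cat("ahglasso_fit: p = ", ncol(x$skeleton), ", lambda = ",
      signif(x$lambda, 4), ", edges = ",
      sum(x$skeleton[upper.tri(x$skeleton)]), "\n", sep = "")
  invisible(x)
}
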