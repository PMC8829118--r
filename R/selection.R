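#' Screen candidate neighbors by marginal correlation
#'
#' Correlation screening: before the per-node Lasso, nodes whose absolute
#' Pearson correlation with the target node does not exceed the current
#' penalty level are removed from the candidate set. Prior neighbors can be
#' protected from the screen via \code{forced_keep}, so prior knowledge is
#' never discarded by a marginal-correlation filter.
#'
#' @param corr_row Length-p vector of correlations of every node with the
#'   target node (entry \code{node} is ignored).
#' @param node Index of the target node.
#' @param threshold Screening threshold (typically the current lambda).
#' @param forced_keep Integer vector of indices kept regardless of
#'   correlation.
#' @return Sorted integer vector of candidate indices (never contains
#'   \code{node}).
#' @export
screen_candidates <- function(corr_row, node, threshold, forced_keep = integer(0)) {
  stopifnot(threshold >= 0)
  if (any(abs(corr_row) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  keep <- which(abs(corr_row) > threshold)
  out <- sort(unique(c(keep, as.integer(forced_keep))))
  setdiff(out, node)
}

# Weighted Lasso for one node across a decreasing lambda sequence.
# X: n x p standardized matrix. Returns per-lambda supports/coefficients over
# candidates screened at min(lambdas) (prior neighbors always kept); each
# lambda's support is additionally restricted to that lambda's own screen.
# glmnet rescales penalty.factor to sum to nvars, so the lambda sequence is
# multiplied by sum(pf)/nvars to realize a penalty of exactly lambda * pf_j.
.node_lasso_path <- function(X, node, lambdas, prior_neighbors = integer(0),
                             prior_weights = NULL, screen = TRUE) {
  n <- nrow(X); p <- ncol(X)
  lambdas <- sort(lambdas, decreasing = TRUE)
  y <- X[, node]
  r <- as.vector(crossprod(X, y)) / (n - 1)
  prior_neighbors <- setdiff(as.integer(prior_neighbors), node)
  cand <- if (screen) {
    screen_candidates(r, node, min(lambdas), forced_keep = prior_neighbors)
  } else {
    setdiff(seq_len(p), node)
  }
  # zero-variance candidates cannot enter a regression
  if (length(cand)) {
    sds <- sqrt(colSums(X[, cand, drop = FALSE]^2) / (n - 1))
    if (any(sds < 1e-12)) {
      warning("excluding ", sum(sds < 1e-12), " zero-variance candidate column(s)")
      cand <- cand[sds >= 1e-12]
    }
  }
  nl <- length(lambdas)
  empty <- list(support = integer(0), beta = numeric(0))
  if (length(cand) == 0L) {
    return(list(candidates = cand, fits = rep(list(empty), nl)))
  }
  pf <- rep(1, length(cand))
  if (length(prior_neighbors)) {
    w <- prior_weights[match(cand, prior_neighbors)]
    is_pn <- !is.na(w)
    pf[is_pn] <- 1 - w[is_pn]
  }
  fits <- vector("list", nl)
  if (length(cand) == 1L) {
    # closed-form soft-threshold; glmnet needs >= 2 columns
    x <- X[, cand]
    xy <- sum(x * y) / n
    xx <- sum(x * x) / n
    for (k in seq_len(nl)) {
      th <- lambdas[k] * pf[1]
      b <- sign(xy) * max(abs(xy) - th, 0) / xx
      fits[[k]] <- if (b != 0) list(support = cand, beta = b) else empty
    }
  } else if (sum(pf) == 0) {
    # all penalties vanish: ordinary least squares for every lambda
    b <- stats::lm.fit(X[, cand, drop = FALSE], y)$coefficients
    b[is.na(b)] <- 0
    sup <- cand[b != 0]
    fit <- list(support = sup, beta = b[b != 0])
    fits <- rep(list(fit), nl)
  } else {
    scale_pf <- sum(pf) / length(pf)
    gfit <- glmnet::glmnet(X[, cand, drop = FALSE], y, family = "gaussian",
                           alpha = 1, lambda = lambdas * scale_pf,
                           penalty.factor = pf, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-8, maxit = 1e5)
    B <- as.matrix(gfit$beta)
    # glmnet may return fewer columns than requested on early saturation
    got <- ncol(B)
    for (k in seq_len(nl)) {
      b <- if (k <= got) B[, k] else B[, got]
      nz <- which(b != 0)
      fits[[k]] <- list(support = cand[nz], beta = unname(b[nz]))
    }
  }
  if (screen) {
    for (k in seq_len(nl)) {
      ok_set <- c(which(abs(r) > lambdas[k]), prior_neighbors)
      keep <- fits[[k]]$support %in% ok_set
      fits[[k]] <- list(support = fits[[k]]$support[keep],
                        beta = fits[[k]]$beta[keep])
    }
  }
  list(candidates = cand, fits = fits)
}

#' Weighted Lasso neighborhood selection for a single node
#'
#' Regresses the node's expression on its screened candidate neighbors with an
#' L1 penalty. Prior neighbors \eqn{j \in J_i} receive the reduced penalty
#' \eqn{\lambda (1 - w_{ij})}; all other candidates are penalized at
#' \eqn{\lambda}. An edge weight of 1 therefore makes the covariate
#' effectively unpenalized, while a weight of 0 recovers the plain Lasso.
#'
#' @param D n x p expression matrix with standardized columns (see
#'   [standardize_expression()]).
#' @param node Target node index.
#' @param lam Nonnegative penalty level.
#' @param prior_neighbors Integer indices of the node's prior neighbors
#'   (exempt from screening).
#' @param prior_weights Numeric vector of prior edge weights aligned with
#'   \code{prior_neighbors}.
#' @param screen If \code{TRUE} (default), apply correlation screening at
#'   threshold \code{lam} before the regression.
#' @return A list of class \code{neighborhood_fit} with elements \code{node},
#'   \code{candidates}, \code{support} and \code{coefficients}.
#' @export
neighborhood_lasso <- function(D, node, lam, prior_neighbors = integer(0),
                               prior_weights = NULL, screen = TRUE) {
  stopifnot(lam >= 0)
  res <- .node_lasso_path(D, node, lam, prior_neighbors, prior_weights,
                          screen = screen)
  structure(list(node = node, candidates = res$candidates,
                 support = res$fits[[1]]$support,
                 coefficients = res$fits[[1]]$beta),
            class = "neighborhood_fit")
}

#' Combine per-node neighborhoods into a graph skeleton
#'
#' @param fits List of p objects from [neighborhood_lasso()] (or any list
#'   with \code{node} and \code{support} elements), one per node.
#' @param p Number of nodes.
#' @param rule \code{"OR"} (default): edge (i, j) if either node selects the
#'   other; \code{"AND"}: both must select each other.
#' @return Symmetric binary p x p adjacency matrix with zero diagonal.
#' @export
build_skeleton <- function(fits, p, rule = c("OR", "AND")) {
  rule <- match.arg(rule)
  nodes <- vapply(fits, function(f) as.integer(f$node), integer(1))
  if (!setequal(nodes, seq_len(p))) {
    stop("need exactly one neighborhood fit per node")
  }
  sel <- matrix(0L, p, p)
  for (f in fits) {
    if (length(f$support)) sel[f$node, f$support] <- 1L
  }
  A <- if (rule == "OR") pmax(sel, t(sel)) else sel * t(sel)
  diag(A) <- 0L
  A
}
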