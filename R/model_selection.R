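#' Build a log-spaced penalty grid
#'
#' \eqn{\lambda_{max}} is the largest absolute off-diagonal sample
#' correlation (the smallest penalty at which every neighborhood is empty);
#' \eqn{\lambda_{min} = } \code{min_ratio} \eqn{\cdot \lambda_{max}}. The
#' grid is log-spaced and returned in decreasing order.
#'
#' @param S Sample correlation matrix (p >= 2).
#' @param n_lambda Number of grid points (default 40).
#' @param min_ratio Ratio defining the lower endpoint (default 0.01).
#' @return Object of class \code{lambda_grid}: list with \code{values}
#'   (decreasing), \code{lambda_max}, \code{min_ratio}, \code{n_lambda}.
#' @export
lambda_grid <- function(S, n_lambda = 40, min_ratio = 0.01) {
  S <- as.matrix(S)
  if (nrow(S) < 2) stop("need p >= 2")
  lmax <- max(abs(S[upper.tri(S) | lower.tri(S)]))
  if (lmax == 0) stop("degenerate input: all off-diagonal correlations are 0")
  vals <- exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
  structure(list(values = vals, lambda_max = lmax, min_ratio = min_ratio,
                 n_lambda = n_lambda),
            class = "lambda_grid")
}

#' Information criterion on the penalized Gaussian log-likelihood
#'
#' The penalized log-likelihood is
#' \deqn{\ell_{pen} = (n/2)\,[\log\det\Omega - \mathrm{tr}(S\Omega) -
#'   \lambda \sum_{i \neq j} |\omega_{ij}|],}
#' (both off-diagonal triangles enter the penalty sum). With k the number of
#' skeleton edges: AIC = \eqn{-2\ell_{pen} + 2k}, BIC =
#' \eqn{-2\ell_{pen} + k \log n}, EBIC = BIC \eqn{+ 4\gamma k \log p}.
#' Note that for a skeleton-constrained maximum-likelihood fit the relevant
#' per-entry penalty level is 0 (zero penalty on skeleton edges, exact zeros
#' elsewhere), in which case \eqn{\ell_{pen}} is the plain log-likelihood;
#' the model-selection routines call this function accordingly.
#'
#' @param Omega A \code{precision_estimate} or precision matrix.
#' @param S_eval Covariance/correlation matrix of the evaluation data.
#' @param n_eval Number of evaluation samples (>= 2).
#' @param lam Penalty level entering the penalized log-likelihood.
#' @param criterion One of \code{"AIC"}, \code{"BIC"}, \code{"EBIC"}.
#' @param ebic_gamma EBIC complexity weight, default 0.5.
#' @return Scalar criterion value (\code{NA} if \code{Omega} is not positive
#'   definite).
#' @export
criterion_score <- function(Omega, S_eval, n_eval, lam,
                            criterion = c("BIC", "AIC", "EBIC"),
                            ebic_gamma = 0.5) {
  criterion <- match.arg(criterion)
  if (n_eval < 2) stop("n_eval must be at least 2")
  if (inherits(Omega, "precision_estimate")) Omega <- Omega$Omega
  Omega <- as.matrix(Omega)
  p <- nrow(Omega)
  R <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  logdet <- 2 * sum(log(diag(R)))
  off <- Omega; diag(off) <- 0
  k <- sum(off[upper.tri(off)] != 0)
  ll <- (n_eval / 2) * (logdet - sum(S_eval * Omega) - lam * sum(abs(off)))
  -2 * ll + .ic_penalty(k, n_eval, p, criterion, ebic_gamma)
}

#' Apply the one-standard-error rule to a tuning table
#'
#' Given per-lambda mean criterion values and standard errors, returns the
#' chosen lambda: with \code{one_se}, the largest (sparsest) lambda whose
#' mean lies within one standard error of the minimizing lambda's mean;
#' otherwise the minimizer itself.
#'
#' @param lambdas Decreasing penalty values.
#' @param means Mean criterion per lambda (NA allowed; excluded).
#' @param ses Standard error per lambda (same length).
#' @param one_se Logical flag.
#' @return The chosen lambda value.
#' @export
choose_lambda <- function(lambdas, means, ses, one_se = TRUE) {
  ok <- which(is.finite(means))
  if (!length(ok)) stop("no usable lambda values")
  i_min <- ok[which.min(means[ok])]
  if (!one_se) return(lambdas[i_min])
  bound <- means[i_min] + ses[i_min]
  cand <- ok[means[ok] <= bound]
  lambdas[cand[which.max(lambdas[cand])]]
}

# Complexity penalty of the information criterion for k edges.
.ic_penalty <- function(k, n, p, criterion, ebic_gamma) {
  switch(criterion,
         AIC = 2 * k,
         BIC = k * log(n),
         EBIC = k * log(n) + 4 * ebic_gamma * k * log(p))
}

# Fit skeletons over a grid on one data set and return the per-lambda
# goodness-of-fit term logdet(Omega) - tr(S_eval Omega), edge counts and
# convergence flags. S_eval = NULL evaluates against the training
# correlation itself. No penalty term remains at scoring time: the
# constrained MLE is the graphical-lasso solution with zero penalty on
# skeleton edges and exact zeros elsewhere.
.score_grid <- function(Dtrain, prior, lambdas, S_eval, rule, screen, tol,
                        max_iter) {
  Dstd <- standardize_expression(Dtrain)
  S_tr <- crossprod(Dstd) / (nrow(Dstd) - 1)
  if (is.null(S_eval)) S_eval <- S_tr
  skels <- .skeletons_path(Dstd, prior, lambdas, rule = rule, screen = screen)
  nl <- length(lambdas)
  out <- data.frame(lambda = lambdas, ll = NA_real_, k = NA_integer_,
                    converged = FALSE)
  for (j in seq_len(nl)) {
    A <- skels[[j]]
    est <- constrained_mle(S_tr, A, tol = tol, max_iter = max_iter)
    out$k[j] <- sum(A[upper.tri(A)])
    out$converged[j] <- est$converged
    if (est$converged) {
      R <- tryCatch(chol(est$Omega), error = function(e) NULL)
      if (!is.null(R)) {
        out$ll[j] <- 2 * sum(log(diag(R))) - sum(S_eval * est$Omega)
      }
    }
  }
  out
}

#' Select lambda by K-fold cross-validated information criterion
#'
#' Rows are partitioned into K folds by a seeded shuffle. For every lambda
#' and fold the model is fit on that fold's training rows and the Gaussian
#' log-likelihood is evaluated with the held-out fold's sample correlation
#' matrix. The cross-validated criterion is the complexity-penalized
#' aggregate of the held-out fits,
#' \deqn{CV\mbox{-}BIC(\lambda) = -2 \sum_f (n_f/2) [\log\det\hat\Omega_f -
#'   \mathrm{tr}(S_f \hat\Omega_f)] + k \log n,}
#' (analogously for AIC/EBIC), i.e. the information criterion applied to the
#' out-of-sample estimate of the expected log-likelihood; k is the mean
#' training-skeleton edge count. Fold-level contributions supply the
#' standard error (SD/\eqn{\sqrt K}) for the one-standard-error rule.
#'
#' @param D n x p expression matrix.
#' @param prior \code{prior_network} over the same features.
#' @param grid A \code{lambda_grid} (or numeric vector of penalties).
#' @param K Number of folds (default 5; must not exceed n).
#' @param criterion \code{"BIC"} (default), \code{"AIC"} or \code{"EBIC"}.
#' @param one_se Apply the one-standard-error rule (default \code{TRUE}).
#' @param ebic_gamma EBIC complexity weight.
#' @param seed Integer seed for the fold shuffle.
#' @param rule,screen Passed to the neighborhood-selection stage.
#' @param tol,max_iter Convergence controls for the per-fold constrained MLE
#'   (defaults are looser than the final fit: the criterion is insensitive
#'   to late-stage refinement).
#' @return Object of class \code{selection_table}: data.frame with columns
#'   \code{lambda}, \code{mean}, \code{se}, \code{k} (mean training edge
#'   count), \code{n_folds_ok}, \code{chosen}; attributes
#'   \code{chosen_lambda}, \code{criterion}, \code{K}, \code{one_se},
#'   \code{fold_values}, \code{n_skipped_folds}.
#' @export
cv_select_lambda <- function(D, prior, grid, K = 5,
                             criterion = c("BIC", "AIC", "EBIC"),
                             one_se = TRUE, ebic_gamma = 0.5, seed = 1,
                             rule = "OR", screen = TRUE, tol = 1e-4,
                             max_iter = 100) {
  criterion <- match.arg(criterion)
  D <- as.matrix(D)
  n <- nrow(D)
  p <- ncol(D)
  if (K > n) stop("K must not exceed the number of samples")
  if (K < 2) stop("need at least 2 folds (use ic_select_lambda otherwise)")
  lambdas <- if (inherits(grid, "lambda_grid")) grid$values else
    sort(as.numeric(grid), decreasing = TRUE)
  nl <- length(lambdas)
  if (!nl) stop("empty lambda grid")
  fold_id <- .with_seed(seed, sample(rep_len(seq_len(K), n)))
  vals <- matrix(NA_real_, nl, K)  # per-fold criterion contributions
  ks <- matrix(NA_real_, nl, K)
  for (f in seq_len(K)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    Dte <- standardize_expression(D[test, , drop = FALSE])
    S_eval <- crossprod(Dte) / (length(test) - 1)
    sc <- .score_grid(D[train, , drop = FALSE], prior, lambdas, S_eval,
                      rule, screen, tol, max_iter)
    pen <- .ic_penalty(sc$k, n, p, criterion, ebic_gamma)
    vals[, f] <- -length(test) * sc$ll + pen / K
    ks[, f] <- sc$k
  }
  n_ok <- rowSums(is.finite(vals))
  n_skipped <- sum(!is.finite(vals))
  if (n_skipped > 0) {
    message("cv_select_lambda: ", n_skipped,
            " (lambda, fold) fit(s) skipped (non-converged or unstable)")
  }
  means <- ifelse(n_ok == K, rowMeans(vals), NA_real_)
  ses <- apply(vals, 1, function(v) stats::sd(v) / sqrt(K))
  if (all(!is.finite(means))) stop("no lambda converged in every fold")
  chosen <- choose_lambda(lambdas, means, ses, one_se = one_se)
  tab <- data.frame(lambda = lambdas, mean = means, se = ses,
                    k = rowMeans(ks), n_folds_ok = n_ok,
                    chosen = lambdas == chosen)
  structure(tab, class = c("selection_table", "data.frame"),
            chosen_lambda = chosen, criterion = criterion, K = K,
            one_se = one_se, fold_values = vals, n_skipped_folds = n_skipped)
}

#' Select lambda by a whole-data information criterion (no folds)
#'
#' Fits on the full data and evaluates the criterion with the full-data
#' sample correlation and sample size; the classical (non-cross-validated)
#' BIC path.
#'
#' @inheritParams cv_select_lambda
#' @return A \code{selection_table} with one "fold"; SEs are 0, so the
#'   one-SE rule reduces to the argmin.
#' @export
ic_select_lambda <- function(D, prior, grid,
                             criterion = c("BIC", "AIC", "EBIC"),
                             ebic_gamma = 0.5, rule = "OR", screen = TRUE,
                             tol = 1e-4, max_iter = 100) {
  criterion <- match.arg(criterion)
  D <- as.matrix(D)
  n <- nrow(D)
  p <- ncol(D)
  lambdas <- if (inherits(grid, "lambda_grid")) grid$values else
    sort(as.numeric(grid), decreasing = TRUE)
  sc <- .score_grid(D, prior, lambdas, NULL, rule, screen, tol, max_iter)
  value <- -n * sc$ll + .ic_penalty(sc$k, n, p, criterion, ebic_gamma)
  chosen <- choose_lambda(lambdas, value, rep(0, length(lambdas)),
                          one_se = FALSE)
  tab <- data.frame(lambda = lambdas, mean = value,
                    se = rep(0, length(lambdas)), k = sc$k,
                    n_folds_ok = as.integer(sc$converged),
                    chosen = lambdas == chosen)
  structure(tab, class = c("selection_table", "data.frame"),
            chosen_lambda = chosen, criterion = criterion, K = 1,
            one_se = FALSE, fold_values = matrix(value, ncol = 1),
            n_skipped_folds = sum(!sc$converged))
}

#' @export
print.selection_table <- function(x, ...) {
  cat("selection_table (", attr(x, "criterion"), ", K = ", attr(x, "K"),
      if (attr(x, "one_se")) ", one-SE" else "", "): chosen lambda = ",
      signif(attr(x, "chosen_lambda"), 4), "\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
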