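#' Replicated simulation experiment: prior versus no-prior
#'
#' Runs the full evaluation loop: simulate a ground-truth network and
#' expression data, derive the prior weights, tune lambda by (cross-validated)
#' information criterion, fit the final model with and without the prior, and
#' score the recovered skeleton against the truth. Every replicate draws its
#' stage seeds from the master \code{seed} by a fixed counter scheme, so any
#' single replicate can be re-run in isolation.
#'
#' @param p,density,type Network simulation parameters
#'   (see [simulate_scale_free()]).
#' @param n Sample size per replicate.
#' @param overlap Target prior/target overlap percentage (see
#'   [simulate_truth()]); \code{NULL} leaves the prior equal to the truth.
#' @param subset_pct Optional incomplete-prior fraction (see
#'   [simulate_truth()]).
#' @param replicates Number of independent replicates.
#' @param n_lambda,min_ratio Penalty grid controls (see [lambda_grid()]).
#' @param K Cross-validation folds; \code{K = 0} switches to the whole-data
#'   criterion ([ic_select_lambda()]).
#' @param criterion,one_se,ebic_gamma Model-selection controls.
#' @param methods Character subset of \code{c("prior", "no_prior")}.
#' @param rule,screen Neighborhood-selection controls.
#' @param seed Master seed.
#' @param verbose Print per-replicate progress.
#' @return Object of class \code{ahglasso_experiment}: tidy data.frame with
#'   one row per (replicate, method) holding the chosen lambda, edge counts,
#'   realized overlap and all recovery metrics.
#' @export
run_experiment <- function(p = 500, density = 0.02, n = 200, overlap = 80,
                           subset_pct = NULL, replicates = 5,
                           n_lambda = 40, min_ratio = 0.01, K = 5,
                           criterion = "BIC", one_se = TRUE,
                           ebic_gamma = 0.5,
                           methods = c("prior", "no_prior"),
                           rule = "OR", screen = TRUE, seed = 1,
                           type = "scale_free", verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- derive_seed(seed, 100 + r)
    sim <- simulate_truth(p, density, overlap = overlap,
                          subset_pct = subset_pct, type = type,
                          seed = rep_seed)
    D <- sample_expression(sim$Sigma_true, n, derive_seed(rep_seed, 11))
    Dstd <- standardize_expression(D)
    S <- crossprod(Dstd) / (n - 1)
    grid <- lambda_grid(S, n_lambda = n_lambda, min_ratio = min_ratio)
    zero_prior <- prior_network(matrix(0, p, p))
    for (m in methods) {
      pr <- if (m == "prior") prior_network(sim$prior_W) else zero_prior
      tune <- if (K > 0) {
        cv_select_lambda(D, pr, grid, K = K, criterion = criterion,
                         one_se = one_se, ebic_gamma = ebic_gamma,
                         seed = derive_seed(rep_seed, 21), rule = rule,
                         screen = screen)
      } else {
        ic_select_lambda(D, pr, grid, criterion = criterion,
                         ebic_gamma = ebic_gamma, rule = rule,
                         screen = screen)
      }
      lam <- attr(tune, "chosen_lambda")
      fit <- fit_ahglasso(D, pr, lam, rule = rule, screen = screen)
      ev <- evaluate_network(fit, sim)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(replicate = r, method = m, seed = rep_seed,
                   lambda = lam, lambda_max = grid$lambda_max,
                   edges_est = sum(fit$skeleton[upper.tri(fit$skeleton)]),
                   edges_true = sum(sim$adjacency_true[
                     upper.tri(sim$adjacency_true)]),
                   overlap = sim$overlap_pct),
        ev)
      if (verbose) {
        message(sprintf("rep %d %-8s lambda=%.3f edges=%d F1=%.3f", r, m,
                        lam, rows[[length(rows)]]$edges_est,
                        rows[[length(rows)]]$F1))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ahglasso_experiment", "data.frame")
  attr(out, "config") <- list(p = p, density = density, n = n,
                              overlap = overlap, subset_pct = subset_pct,
                              replicates = replicates, n_lambda = n_lambda,
                              min_ratio = min_ratio, K = K,
                              criterion = criterion, one_se = one_se,
                              seed = seed, type = type)
  out
}

#' Summarize an experiment as per-method means and standard errors
#'
#' @param object An \code{ahglasso_experiment}.
#' @param ... Unused.
#' @return data.frame with one row per method: mean and SE of sensitivity,
#'   specificity, precision, F1 and MCC over replicates.
#' @export
summary.ahglasso_experiment <- function(object, ...) {
  metrics <- c("sensitivity", "specificity", "precision", "F1", "MCC")
  out <- do.call(rbind, lapply(split(object, object$method), function(d) {
    row <- data.frame(method = d$method[1], replicates = nrow(d))
    for (m in metrics) {
      row[[paste0("mean_", m)]] <- mean(d[[m]])
      row[[paste0("se_", m)]] <- stats::sd(d[[m]]) / sqrt(nrow(d))
    }
    row
  }))
  rownames(out) <- NULL
  out
}
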