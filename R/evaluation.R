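#' Edge confusion counts against a ground-truth network
#'
#' Binarizes both matrices at exactly-nonzero and counts true/false
#' positives/negatives over the strict upper triangle (each undirected edge
#' counted once).
#'
#' @param est_adj Estimated adjacency (any nonzero entry is an edge).
#' @param true_adj Ground-truth adjacency, same shape.
#' @return List of class \code{confusion_counts} with integer fields
#'   \code{TP}, \code{FP}, \code{TN}, \code{FN}; they sum to
#'   \code{p(p-1)/2}.
#' @export
confusion_counts <- function(est_adj, true_adj) {
  A <- as.matrix(est_adj); B <- as.matrix(true_adj)
  if (!identical(dim(A), dim(B))) stop("shape mismatch")
  up <- upper.tri(A)
  e <- A[up] != 0
  t <- B[up] != 0
  structure(list(TP = sum(e & t), FP = sum(e & !t),
                 TN = sum(!e & !t), FN = sum(!e & t)),
            class = "confusion_counts")
}

#' Classification metrics for edge recovery
#'
#' Computes sensitivity (recall), specificity, precision,
#' \eqn{F1 = 2TP / (2TP + FP + FN)} and the Matthews correlation coefficient
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' Any ratio with a zero denominator is returned as 0 and flagged via the
#' \code{degenerate} attribute (this occurs e.g. for an empty estimate at
#' \eqn{\lambda_{max}}).
#'
#' @param c A \code{confusion_counts} object (or list with TP/FP/TN/FN).
#' @return Named numeric vector with elements \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{F1}, \code{MCC}.
#' @export
classification_metrics <- function(c) {
  TP <- as.numeric(c$TP); FP <- as.numeric(c$FP)
  TN <- as.numeric(c$TN); FN <- as.numeric(c$FN)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  prec <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- safe_div(TP * TN - FP * FN, mcc_den)
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           F1 = f1, MCC = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' Evaluate an estimated network against the simulation truth
#'
#' Convenience wrapper producing one tidy row of metrics.
#'
#' @param est_adj Estimated adjacency or an \code{ahglasso_fit}.
#' @param true_adj Ground-truth adjacency or a \code{sim_truth}.
#' @return One-row data.frame with the confusion counts and all metrics.
#' @export
evaluate_network <- function(est_adj, true_adj) {
  if (inherits(est_adj, "ahglasso_fit")) est_adj <- est_adj$skeleton
  if (inherits(true_adj, "sim_truth")) true_adj <- true_adj$adjacency_true
  cc <- confusion_counts(est_adj, true_adj)
  m <- classification_metrics(cc)
  data.frame(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
             sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
             precision = m[["precision"]], F1 = m[["F1"]], MCC = m[["MCC"]])
}
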