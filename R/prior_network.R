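#' Read a STRING-style edge list
#'
#' Parses a delimited edge list with columns \code{node_a}, \code{node_b},
#' \code{score}. STRING exports its combined confidence score as an integer on
#' a 0--1000 scale; if any score exceeds 1 the whole column is divided by 1000
#' so that weights land in \code{[0, 1]}. Rows with normalized weight below
#' \code{score_min} are discarded (low-confidence interactions), self-pairs are
#' dropped, and duplicate pairs (in either order) are collapsed to their
#' maximum weight.
#'
#' @param path Path to a tab- or comma-delimited text file with at least three
#'   columns. A header row is detected by a non-numeric third field.
#' @param score_min Minimum retained weight on the 0--1 scale. Default 0.2,
#'   the conventional cutoff below which STRING associations are considered
#'   low confidence.
#' @return A data.frame with columns \code{node_a}, \code{node_b},
#'   \code{weight}, one row per undirected edge.
#' @export
load_string_edges <- function(path, score_min = 0.2) {
  if (!file.exists(path)) {
    stop("cannot read edge list: '", path, "' does not exist")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- length(fields) >= 3 &&
    is.na(suppressWarnings(as.numeric(fields[3])))
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = has_header,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed edge list: ", conditionMessage(e)))
  if (ncol(tab) < 3) {
    stop("edge list must have at least 3 columns (node_a, node_b, score)")
  }
  node_a <- as.character(tab[[1]])
  node_b <- as.character(tab[[2]])
  score <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(score)) stop("non-numeric score values in edge list")
  # STRING native scale is integer 0-1000; detect and normalize
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0) || any(score > 1)) {
    stop("edge weights outside [0, 1] after normalization")
  }
  keep <- score >= score_min & node_a != node_b
  node_a <- node_a[keep]; node_b <- node_b[keep]; score <- score[keep]
  # collapse duplicates (either order) to the maximum weight
  key <- ifelse(node_a < node_b,
                paste(node_a, node_b, sep = "\r"),
                paste(node_b, node_a, sep = "\r"))
  ord <- order(key, -score)
  key <- key[ord]; node_a <- node_a[ord]; node_b <- node_b[ord]
  score <- score[ord]
  first_of_key <- !duplicated(key)
  data.frame(node_a = node_a[first_of_key],
             node_b = node_b[first_of_key],
             weight = score[first_of_key],
             stringsAsFactors = FALSE)
}

#' Build a prior weight matrix over the expression features
#'
#' Arranges prior edge weights into the symmetric \eqn{p \times p} matrix
#' \eqn{W} used to weight the Lasso penalty. Edges whose endpoints are not
#' both among \code{feature_names} are dropped (their count is reported via
#' \code{message}); the graph is defined over the expression features only.
#'
#' @param edges A data.frame as returned by [load_string_edges()], or any
#'   data.frame with columns \code{node_a}, \code{node_b}, \code{weight}.
#' @param feature_names Character vector of feature (protein/gene) names in
#'   the column order of the expression matrix. Must be free of duplicates.
#' @return A \code{prior_network} object; see [prior_network()].
#' @export
build_prior_matrix <- function(edges, feature_names) {
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names")
  }
  p <- length(feature_names)
  W <- matrix(0, p, p, dimnames = list(feature_names, feature_names))
  if (nrow(edges) > 0) {
    ia <- match(edges$node_a, feature_names)
    ib <- match(edges$node_b, feature_names)
    ok <- !is.na(ia) & !is.na(ib)
    n_dropped <- sum(!ok)
    if (n_dropped > 0) {
      message(n_dropped, " prior edge(s) dropped: endpoint(s) absent from expression features")
    }
    W[cbind(ia[ok], ib[ok])] <- edges$weight[ok]
    W[cbind(ib[ok], ia[ok])] <- edges$weight[ok]
  }
  prior_network(W, feature_names)
}

#' Construct a prior network object
#'
#' Validates a weight matrix and partitions the nodes into the
#' prior-connected set \eqn{J} and the isolated set \eqn{J^\complement}.
#'
#' @param W Symmetric \eqn{p \times p} matrix of edge weights in
#'   \code{[0, 1]} with zero diagonal.
#' @param node_names Optional character vector of node names (defaults to the
#'   rownames of \code{W}).
#' @return An object of class \code{prior_network} with components \code{W},
#'   \code{node_names}, \code{J} (indices with at least one prior neighbor),
#'   \code{J_complement}, and \code{neighbor_sets} (list mapping each node to
#'   its prior neighbor indices).
#' @export
prior_network <- function(W, node_names = rownames(W)) {
  W <- as.matrix(W)
  p <- nrow(W)
  if (ncol(W) != p) stop("W must be square")
  if (is.null(node_names)) node_names <- paste0("V", seq_len(p))
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (any(W < 0) || any(W > 1)) stop("prior weights must lie in [0, 1]")
  part <- partition_nodes(W)
  structure(list(W = W, node_names = node_names, J = part$J,
                 J_complement = part$J_complement,
                 neighbor_sets = part$neighbor_sets),
            class = "prior_network")
}

#' Partition nodes by prior connectivity
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @return A list with \code{J} (nodes with at least one positive-weight
#'   prior edge), \code{J_complement} (isolated nodes), and
#'   \code{neighbor_sets} (per-node integer vectors of prior neighbors).
#' @export
partition_nodes <- function(W) {
  W <- as.matrix(W)
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  p <- nrow(W)
  neighbor_sets <- lapply(seq_len(p), function(i) which(W[i, ] > 0))
  deg <- vapply(neighbor_sets, length, integer(1))
  list(J = which(deg > 0L),
       J_complement = which(deg == 0L),
       neighbor_sets = neighbor_sets)
}

#' @export
print.prior_network <- function(x, ...) {
  cat("prior_network: ", length(x$node_names), " nodes, ",
      sum(x$W[upper.tri(x$W)] > 0), " weighted edges, |J| = ",
      length(x$J), "\n", sep = "")
  invisible(x)
}

#' Read a square prior weight matrix from delimited text
#'
#' Expects a header row and an index column of feature names (the format
#' written by [write_matrix()]).
#'
#' @param path File path.
#' @return A \code{prior_network} object.
#' @export
load_prior_matrix <- function(path) {
  W <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE,
                                   comment.char = "#"))
  # symmetrize away print-precision asymmetry
  W <- (W + t(W)) / 2
  prior_network(W, rownames(W))
}
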