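# Comment header embedded at the top of every output file: package version,
# master seed and a hash of the generating configuration.
.file_header <- function(seed = NULL, config = NULL) {
  h <- if (is.null(config)) "none" else
    format(sum(utf8ToInt(paste(deparse(config), collapse = "")) *
                 seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %%
             2147483647)
  paste0("# ahglasso ", as.character(utils::packageVersion("ahglasso")),
         " seed=", if (is.null(seed)) "NA" else seed, " config=", h)
}

#' Load an expression matrix from delimited text
#'
#' Expects a header row of feature names and one row per sample; tab, comma
#' or whitespace delimited (auto-detected). Non-numeric cells and missing
#' values are rejected with the offending position; constant columns are
#' rejected by name because they cannot be standardized.
#'
#' @param path File path.
#' @param standardize If \code{TRUE}, return columns centered and scaled to
#'   unit sample variance.
#' @return Numeric n x p matrix with column names.
#' @export
load_expression <- function(path, standardize = FALSE) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  M <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) M <- matrix(M, 1, dimnames = list(NULL, names(tab)))
  bad <- which(is.na(M) & !is.na(as.matrix(tab)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at row ", bad[1, 1], ", column '",
         colnames(M)[bad[1, 2]], "'")
  }
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)
    stop("missing value at row ", miss[1, 1], ", column '",
         colnames(M)[miss[1, 2]], "'")
  }
  sds <- apply(M, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant column(s): ", paste(colnames(M)[sds < 1e-12], collapse = ", "))
  }
  if (standardize) M <- standardize_expression(M)
  M
}

#' Write a matrix as tab-delimited text
#'
#' Header row and index column of names; 6 significant digits; a comment
#' header records the package version and seed.
#'
#' @param M Matrix with dimnames (names are generated if absent).
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the comment header.
#' @export
write_matrix <- function(M, path, seed = NULL, config = NULL) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("V", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- rownames(M)[seq_len(ncol(M))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config), con)
  writeLines(paste(c("name", colnames(M)), collapse = "\t"), con)
  body <- apply(signif(M, 6), 1, paste, collapse = "\t")
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           comment.char = "#", check.names = FALSE)
  as.matrix(tab)
}

#' Write an estimated network to disk
#'
#' Writes the full partial-correlation matrix and an edge list
#' (\code{node_a}, \code{node_b}, \code{partial_correlation}) for entries
#' with \code{|e| > threshold}, sorted by decreasing magnitude (ties broken
#' by node indices, so the ordering is deterministic).
#'
#' @param E Partial-correlation matrix (or \code{ahglasso_fit}).
#' @param names Feature names (defaults to the matrix dimnames).
#' @param threshold Minimum absolute partial correlation for the edge list.
#' @param matrix_path,edges_path Output paths.
#' @param seed,config Optional provenance for the comment headers.
#' @export
write_network <- function(E, names = NULL, threshold = 0,
                          matrix_path, edges_path, seed = NULL,
                          config = NULL) {
  if (inherits(E, "ahglasso_fit")) {
    if (is.null(names)) names <- E$feature_names
    E <- E$partial_cor
  }
  E <- as.matrix(E)
  p <- nrow(E)
  if (is.null(names)) names <- rownames(E)
  if (is.null(names)) names <- paste0("V", seq_len(p))
  dimnames(E) <- list(names, names)
  write_matrix(E, matrix_path, seed = seed, config = config)
  idx <- which(upper.tri(E) & abs(E) > threshold, arr.ind = TRUE)
  ord <- order(-abs(E[idx]), idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  edges <- data.frame(node_a = names[idx[, 1]], node_b = names[idx[, 2]],
                      partial_correlation = signif(E[idx], 6))
  con <- file(edges_path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config), con)
  writeLines("node_a\tnode_b\tpartial_correlation", con)
  if (nrow(edges)) {
    writeLines(paste(edges$node_a, edges$node_b, edges$partial_correlation,
                     sep = "\t"), con)
  }
  invisible(edges)
}

#' Serialize a simulated ground-truth instance to a directory
#'
#' Adjacency, precision, covariance and prior weights as delimited matrices,
#' the expression draw (if given) as an expression TSV, and the generating
#' parameters as a YAML-like key-value file.
#'
#' @param sim A \code{sim_truth}.
#' @param dir Output directory (created if missing).
#' @param expression Optional expression matrix to store alongside.
#' @export
save_sim_truth <- function(sim, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$params$seed
  write_matrix(sim$adjacency_true, file.path(dir, "adjacency_true.tsv"),
               seed, sim$params)
  write_matrix(sim$Omega_true, file.path(dir, "omega_true.tsv"), seed,
               sim$params)
  write_matrix(sim$prior_W, file.path(dir, "prior_weights.tsv"), seed,
               sim$params)
  if (!is.null(expression)) {
    con <- file(file.path(dir, "expression.tsv"), "w")
    writeLines(.file_header(seed, sim$params), con)
    nms <- colnames(expression)
    if (is.null(nms)) nms <- paste0("V", seq_len(ncol(expression)))
    writeLines(paste(nms, collapse = "\t"), con)
    writeLines(apply(signif(expression, 6), 1, paste, collapse = "\t"), con)
    close(con)
  }
  par_lines <- vapply(names(sim$params), function(k) {
    v <- sim$params[[k]]
    paste0(k, ": ", if (is.null(v)) "null" else as.character(v))
  }, character(1))
  writeLines(c(.file_header(seed, sim$params),
               par_lines,
               paste0("realized_overlap: ", sim$overlap_pct)),
             file.path(dir, "params.yml"))
  invisible(dir)
}

#' Write a tuning table as delimited text
#'
#' @param tab A \code{selection_table}.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @export
write_selection_table <- function(tab, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, attr(tab, "criterion")), con)
  writeLines(paste0("# chosen_lambda=", attr(tab, "chosen_lambda"),
                    " criterion=", attr(tab, "criterion"),
                    " K=", attr(tab, "K"),
                    " one_se=", attr(tab, "one_se")), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
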