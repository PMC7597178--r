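#' Construct a weighted network from a symmetric adjacency matrix
#'
#' A weighted network is a dense symmetric real matrix of edge weights,
#' typically correlations in `[-1, 1]` (e.g. functional connectivity between
#' brain regions).  The constructor validates squareness, symmetry (within
#' `sym_tol`, symmetrizing by averaging), finiteness and a minimum size of
#' three nodes, below which the embedded point pattern is degenerate.
#'
#' @param weights square numeric matrix of edge weights.
#' @param node_labels optional character vector of node identifiers; defaults
#'   to existing dimnames or `V1..Vn`.
#' @param sym_tol maximum tolerated absolute asymmetry, default `1e-8`.
#'   Asymmetry above this is an error; below it the matrix is symmetrized by
#'   averaging with its transpose.
#' @return an object of class `weighted_network`: a list with elements
#'   `weights` (the validated matrix) and `node_labels`.
#' @examples
#' w <- diag(3); w[1, 2] <- w[2, 1] <- 0.5
#' net <- weighted_network(w)
#' n_nodes(net)
#' @export
weighted_network <- function(weights, node_labels = NULL, sym_tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(weights) != ncol(weights)) {
    stop(sprintf("adjacency matrix must be square, got %d x %d",
                 nrow(weights), ncol(weights)), call. = FALSE)
  }
  n <- nrow(weights)
  if (n < 3L) {
    stop("a weighted network needs at least 3 nodes; fewer cannot yield a ",
         "nondegenerate point pattern", call. = FALSE)
  }
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite entries at [%s]",
                 paste(sprintf("%d,%d", bad[, 1], bad[, 2])[seq_len(min(5, nrow(bad)))],
                       collapse = "; ")), call. = FALSE)
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > sym_tol) {
    off <- which(asym == max(asym), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("matrix is not symmetric: |w[%d,%d] - w[%d,%d]| = %.3g exceeds %.1g",
                 off[1], off[2], off[2], off[1], max(asym), sym_tol), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  if (is.null(node_labels)) {
    node_labels <- rownames(weights) %||% paste0("V", seq_len(n))
  }
  stopifnot(length(node_labels) == n)
  dimnames(weights) <- NULL
  structure(list(weights = weights, node_labels = as.character(node_labels)),
            class = "weighted_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname weighted_network
#' @param x object to test or coerce.
#' @export
is_weighted_network <- function(x) inherits(x, "weighted_network")

#' @rdname weighted_network
#' @param ... passed on to [weighted_network()].
#' @export
as_weighted_network <- function(x, ...) {
  if (is_weighted_network(x)) return(x)
  weighted_network(as.matrix(x), ...)
}

#' @rdname weighted_network
#' @export
n_nodes <- function(x) {
  stopifnot(is_weighted_network(x))
  nrow(x$weights)
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- n_nodes(x)
  rng <- range(x$weights[upper.tri(x$weights)])
  cat(sprintf("<weighted_network> %d nodes, off-diagonal weights in [%.3f, %.3f]\n",
              n, rng[1], rng[2]))
  invisible(x)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a weighted adjacency matrix from delimited text
#'
#' Reads a dense square matrix from comma- or tab-separated text (delimiter
#' auto-detected from the first line when not given).  An optional header row
#' and leading label column carry node labels; by default their presence is
#' auto-detected from whether the first field parses as a number.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` (default) auto-detects comma/tab.
#' @param has_labels logical; does the file carry a header row plus label
#'   column?  `NA` (default) auto-detects.
#' @param sym_tol symmetry tolerance passed to [weighted_network()].
#' @return a [weighted_network()].
#' @export
read_adjacency <- function(path, delimiter = NULL, has_labels = NA,
                           sym_tol = 1e-8) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delimiter <- delimiter %||% detect_delimiter(path)
  first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1]]
  if (is.na(has_labels)) {
    probe <- first[length(first)]
    has_labels <- is.na(suppressWarnings(as.numeric(probe)))
  }
  raw <- read.table(path, sep = delimiter, header = has_labels,
                    row.names = if (has_labels) 1L else NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  labels <- if (has_labels) rownames(raw) else NULL
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" at row %d, column %d", bad[1, 1], bad[1, 2]) else ""
    stop(sprintf("non-numeric cell%s in %s", loc, path), call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("expected a square matrix in %s, got %d x %d",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  weighted_network(unname(m), node_labels = labels, sym_tol = sym_tol)
}

#' Write a weighted adjacency matrix as delimited text
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @param delimiter field separator, default comma.
#' @param labels include node labels as header row + leading column?
#' @param digits significant digits written (default 10, so re-runs are
#'   comparable across platforms).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path, delimiter = ",", labels = TRUE,
                            digits = 10) {
  stopifnot(is_weighted_network(net))
  m <- signif(net$weights, digits)
  if (labels) {
    dimnames(m) <- list(net$node_labels, net$node_labels)
    write.table(m, path, sep = delimiter, quote = FALSE,
                row.names = TRUE, col.names = NA)
  } else {
    write.table(m, path, sep = delimiter, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a node-by-time multivariate time-series matrix
#'
#' @param path file path to a rectangular numeric matrix in delimited text.
#' @param delimiter field separator; `NULL` auto-detects comma/tab.
#' @param orientation `"nodes_rows"` (default) if rows are nodes, or
#'   `"nodes_cols"` if columns are nodes; the result is always nodes x time.
#' @return numeric matrix, nodes in rows.
#' @export
read_timeseries <- function(path, delimiter = NULL,
                            orientation = c("nodes_rows", "nodes_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  delimiter <- delimiter %||% detect_delimiter(path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(unique(widths), collapse = ", ")), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              nrow = length(lines), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d in %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  if (orientation == "nodes_cols") m <- t(m)
  m
}
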