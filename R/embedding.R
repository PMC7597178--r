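#' Double-centered Gram matrix of a weighted network
#'
#' Computes `B = (1/2) J W J` with the centering projector
#' `J = I - (1/n) 1 1'`.  Because `J` annihilates constant vectors, every row
#' and column of `B` sums to zero, and the spectral factorization of `B`
#' supplies the embedding coordinates.  For a similarity matrix such as a
#' correlation network, `B` itself (not its negation) is the near-positive-
#' semidefinite target; the factor 1/2 is a global rescaling of coordinates
#' kept for definiteness.
#'
#' @param net a [weighted_network()].
#' @return a `gram_matrix`: the `n x n` numeric matrix with attribute
#'   `centering_applied = TRUE`.
#' @examples
#' w <- diag(3)
#' b <- double_center_gram(weighted_network(w))
#' rowSums(b)  # ~0
#' @export
double_center_gram <- function(net) {
  net <- as_weighted_network(net)
  w <- net$weights
  rm <- rowMeans(w)
  gm <- mean(w)
  ## J W J = W - r 1' - 1 r' + g 1 1' with r the row-mean vector
  b <- 0.5 * (w - outer(rm, rep(1, length(rm))) -
                outer(rep(1, length(rm)), rm) + gm)
  b <- (b + t(b)) / 2
  structure(b, centering_applied = TRUE, class = c("gram_matrix", "matrix", "array"))
}

#' Embed a weighted network in a low-dimensional Euclidean space
#'
#' Eigendecomposes the double-centered Gram matrix `B` and maps each node to
#' the point whose coordinates are the top-`k` eigenvectors scaled by the
#' square roots of the corresponding eigenvalues, so that the coordinate
#' inner products form the best rank-`k` nonnegative approximation of `B` in
#' Frobenius norm.  Negative eigenvalues (which arise when `W` is not
#' positive semidefinite, e.g. after noise or a Fisher z transform) are
#' clipped to zero; their total magnitude is recorded and a warning is issued
#' when it exceeds 5% of the total absolute spectral mass.  Each
#' eigenvector's sign is fixed so its largest-magnitude entry is positive,
#' making the output deterministic; pairwise distances (all the complexity
#' metric uses) are unaffected by this convention.
#'
#' @param net a [weighted_network()].
#' @param k embedding dimension, `1 <= k <= n - 1`.  Default 2.
#' @return a `geme_points` object: list with `coordinates` (`k x n` matrix,
#'   one column per node), `k`, `eigenvalues_kept` (nonnegative, descending),
#'   `discarded_negative_mass`, and `node_labels`.
#' @examples
#' w <- diag(4)
#' w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 0.8
#' pts <- embed_network(weighted_network(w), k = 2)
#' pts$eigenvalues_kept
#' @export
embed_network <- function(net, k = 2L) {
  net <- as_weighted_network(net)
  n <- n_nodes(net)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L) {
    stop(sprintf("k must satisfy 1 <= k <= n - 1 (n = %d), got %d", n, k),
         call. = FALSE)
  }
  b <- double_center_gram(net)
  eg <- eigen(unclass(b), symmetric = TRUE)
  vals <- eg$values
  if (max(vals) <= 1e-12 && any(vals < -1e-12)) {
    stop("degenerate embedding: no positive eigenvalue in the centered Gram ",
         "matrix, the network has no embeddable structure", call. = FALSE)
  }
  neg_mass <- sum(abs(vals[vals < 0]))
  total_mass <- sum(abs(vals))
  if (total_mass > 0 && neg_mass / total_mass > 0.05) {
    warning(sprintf(
      "discarded negative spectral mass is %.1f%% of total; the adjacency is far from positive semidefinite",
      100 * neg_mass / total_mass), call. = FALSE)
  }
  lam <- pmax(vals[seq_len(k)], 0)
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    pivot <- which.max(abs(vec[, j]))
    if (vec[pivot, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- t(vec) * sqrt(lam)  # k x n: row j is sqrt(lam_j) * v_j'
  structure(list(coordinates = coords,
                 k = k,
                 eigenvalues_kept = lam,
                 discarded_negative_mass = neg_mass,
                 node_labels = net$node_labels),
            class = "geme_points")
}

#' @export
print.geme_points <- function(x, ...) {
  cat(sprintf("<geme_points> %d points in R^%d; kept eigenvalues: %s\n",
              ncol(x$coordinates), x$k,
              paste(signif(x$eigenvalues_kept, 4), collapse = ", ")))
  if (x$discarded_negative_mass > 0) {
    cat(sprintf("  discarded negative spectral mass: %.4g\n",
                x$discarded_negative_mass))
  }
  invisible(x)
}

## Accept geme_points or a plain matrix of points in rows; return n x k.
point_matrix <- function(points) {
  if (inherits(points, "geme_points")) return(t(points$coordinates))
  m <- as.matrix(points)
  stopifnot(is.numeric(m), all(is.finite(m)))
  m
}

#' Euclidean distance matrix of an embedded point set
#'
#' @param points a `geme_points` object from [embed_network()], or a plain
#'   numeric matrix with one point per row.
#' @return symmetric nonnegative `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(points) {
  as.matrix(dist(point_matrix(points)))
}

#' Write embedded coordinates as delimited text
#'
#' One row per node: label followed by the `k` coordinates, 10 significant
#' digits.
#'
#' @param points a `geme_points` object.
#' @param path output path.
#' @param delimiter field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(points, path, delimiter = ",") {
  stopifnot(inherits(points, "geme_points"))
  df <- data.frame(node = points$node_labels,
                   signif(t(points$coordinates), 10))
  names(df) <- c("node", paste0("x", seq_len(points$k)))
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
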