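#' Specification of a block-covariance network simulation
#'
#' Describes one group of a synthetic cohort: each subject's node-by-time
#' signal matrix is drawn from a zero-mean (by default) multivariate normal
#' whose covariance is block diagonal with compound-symmetry community
#' blocks — block `i` of size `block_sizes[i]` has unit diagonal and constant
#' off-diagonal correlation `block_correlations[i]`; the remaining
#' `n - sum(block_sizes)` nodes are mutually independent (identity tail).
#' Larger blocks mean a more organized, more complex network; lower
#' correlations mean weaker signal relative to noise.
#'
#' @param n_nodes total node count `n`.
#' @param block_sizes integer vector of community sizes, sum at most `n`.
#'   May be empty (pure-noise networks).
#' @param block_correlations within-block correlations in `[0, 1)`, one per
#'   block.
#' @param n_time number of time points `T` per subject (at least 3 so sample
#'   correlations are defined).  Default 150, a typical resting-state fMRI
#'   volume count.
#' @param n_subjects subjects in the group.
#' @param mean common mean of the signals, default 0.
#' @param seed master seed for the group; per-subject substreams are derived
#'   from it so any subject is reproducible in isolation.
#' @return a `simulation_spec`.
#' @examples
#' spec <- simulation_spec(100, c(20, 30), c(0.5, 0.6), n_subjects = 10)
#' @export
simulation_spec <- function(n_nodes, block_sizes, block_correlations,
                            n_time = 150L, n_subjects = 100L, mean = 0,
                            seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  block_correlations <- as.numeric(block_correlations)
  if (length(block_sizes) != length(block_correlations)) {
    stop("`block_sizes` and `block_correlations` must have equal length",
         call. = FALSE)
  }
  if (length(block_sizes) && any(block_sizes < 1L)) {
    stop("block sizes must be positive", call. = FALSE)
  }
  if (sum(block_sizes) > n_nodes) {
    stop(sprintf("block sizes sum to %d, exceeding n = %d",
                 sum(block_sizes), n_nodes), call. = FALSE)
  }
  if (length(block_correlations) &&
      (any(block_correlations < 0) || any(block_correlations >= 1))) {
    stop("block correlations must lie in [0, 1)", call. = FALSE)
  }
  if (n_time < 3L) stop("need at least 3 time points", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes),
                 block_sizes = block_sizes,
                 block_correlations = block_correlations,
                 n_time = as.integer(n_time),
                 n_subjects = as.integer(n_subjects),
                 mean = mean,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> n = %d nodes, blocks (%s) with correlations (%s), T = %d, %d subjects, seed %d\n",
    x$n_nodes, paste(x$block_sizes, collapse = ", "),
    paste(x$block_correlations, collapse = ", "),
    x$n_time, x$n_subjects, x$seed))
  invisible(x)
}

#' Block-diagonal compound-symmetry covariance matrix
#'
#' Builds the covariance implied by a [simulation_spec()]: for each block of
#' size `a` with correlation `rho`, the block is `I_a (1 - rho) + J_a rho`
#' (unit diagonal, constant off-diagonal `rho`); off-block entries are zero
#' and unassigned nodes get the identity.  The result is symmetric positive
#' definite for correlations in `[0, 1)`.
#'
#' @param spec a [simulation_spec()].
#' @return `n x n` covariance matrix.
#' @export
block_covariance <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_nodes
  sigma <- diag(n)
  at <- 0L
  for (b in seq_along(spec$block_sizes)) {
    a <- spec$block_sizes[b]
    rho <- spec$block_correlations[b]
    idx <- at + seq_len(a)
    sigma[idx, idx] <- rho
    at <- at + a
  }
  diag(sigma) <- 1
  sigma
}

## Draw one subject's n x T signal matrix given a precomputed upper-Cholesky
## factor of the covariance (crossprod(R) == Sigma) and a fully resolved seed.
sample_from_chol <- function(chol_upper, n, n_time, mean, seed) {
  set.seed(seed)
  mean + crossprod(chol_upper, matrix(rnorm(n * n_time), n, n_time))
}

#' Simulate one subject's node-by-time signal matrix
#'
#' Draws `T` independent columns from `N(mean, Sigma)` with `Sigma` from
#' [block_covariance()].  The random stream is fully determined by the spec's
#' seed, the subject index, and the group tag, so any subject can be
#' regenerated in isolation.
#'
#' @param spec a [simulation_spec()].
#' @param subject_index positive integer.
#' @param group integer tag separating the substreams of different groups
#'   sharing a master seed (default 1).
#' @return `n x T` numeric matrix.
#' @export
sample_timeseries <- function(spec, subject_index, group = 1L) {
  stopifnot(inherits(spec, "simulation_spec"), subject_index >= 1L)
  sigma <- block_covariance(spec)
  r <- chol(sigma)
  sample_from_chol(r, spec$n_nodes, spec$n_time, spec$mean,
                   mix_seed(spec$seed, group, subject_index))
}

#' Correlation network from a node-by-time signal matrix
#'
#' Forms the second-moment matrix `U = Z Z' / (T - 1)` (about the known zero
#' mean by default; set `center = TRUE` to subtract row means for real data)
#' and normalizes it to unit diagonal,
#' `W = diag(U)^(-1/2) U diag(U)^(-1/2)`.  The result has entries in
#' `[-1, 1]`, unit diagonal, and is positive semidefinite by construction.
#'
#' @param z `n x T` numeric matrix, nodes in rows.
#' @param center subtract row means before forming `U`?  Default `FALSE`,
#'   matching the zero-mean simulation design.
#' @return a [weighted_network()].
#' @export
correlation_network <- function(z, center = FALSE) {
  stopifnot(is.matrix(z), is.numeric(z), ncol(z) >= 3L)
  if (center) z <- z - rowMeans(z)
  u <- tcrossprod(z) / (ncol(z) - 1)
  du <- diag(u)
  if (any(du <= 0)) {
    stop(sprintf("node %d has zero variance; its correlations are undefined",
                 which(du <= 0)[1]), call. = FALSE)
  }
  s <- 1 / sqrt(du)
  w <- u * outer(s, s)
  w <- pmin(pmax(w, -1), 1)
  diag(w) <- 1
  weighted_network(w, node_labels = rownames(z))
}

#' Fisher z transform of a correlation network
#'
#' Maps each off-diagonal weight through `atanh` after clipping magnitudes at
#' `clip` (so perfect correlations stay finite); the diagonal is set to
#' `atanh(clip)` uniformly.  A variance-stabilizing transform commonly
#' applied to functional connectivity edges.
#'
#' @param net a [weighted_network()] with entries in `[-1, 1]`.
#' @param clip magnitude cap in `(0, 1)`, default 0.999.
#' @return a [weighted_network()] of transformed weights.
#' @export
fisher_z_transform <- function(net, clip = 0.999) {
  net <- as_weighted_network(net)
  stopifnot(clip > 0, clip < 1)
  w <- net$weights
  if (max(abs(w)) > 1 + 1e-8) {
    stop("entries must lie in [-1, 1] for the Fisher z transform",
         call. = FALSE)
  }
  z <- atanh(pmin(pmax(w, -clip), clip))
  diag(z) <- atanh(clip)
  weighted_network(z, node_labels = net$node_labels)
}

#' Simulate a two-group study of correlation networks
#'
#' Generates `spec1$n_subjects` networks from the first design and
#' `spec2$n_subjects` from the second, each subject via
#' [sample_timeseries()] then [correlation_network()].  Subject substreams
#' are disjoint across groups (distinct group tags), and the whole study is
#' reproducible from `seed`.
#'
#' @param spec1,spec2 [simulation_spec()] objects with equal `n_nodes`.
#' @param seed master seed; defaults to `spec1$seed`.
#' @return list with elements `group1` and `group2`, each a list of
#'   [weighted_network()] objects.
#' @export
simulate_group_study <- function(spec1, spec2, seed = spec1$seed) {
  stopifnot(inherits(spec1, "simulation_spec"),
            inherits(spec2, "simulation_spec"))
  if (spec1$n_nodes != spec2$n_nodes) {
    stop("both groups must share the node count", call. = FALSE)
  }
  gen <- function(spec, tag) {
    r <- chol(block_covariance(spec))
    lapply(seq_len(spec$n_subjects), function(s) {
      z <- sample_from_chol(r, spec$n_nodes, spec$n_time, spec$mean,
                            mix_seed(seed, tag, s))
      correlation_network(z)
    })
  }
  list(group1 = gen(spec1, 1L), group2 = gen(spec2, 2L))
}

#' Marginally-matched random rewiring of a weighted network
#'
#' Builds an unstructured reference network whose edge weights share the
#' marginal distribution of the input: the off-diagonal weights are drawn
#' i.i.d. from the input's empirical off-diagonal distribution (`resample`,
#' default) or shuffled without replacement (`permute`), then mirrored to
#' keep symmetry; the diagonal is preserved.  The embedded points of such a
#' network approximate complete spatial randomness, making it the natural
#' null reference for the complexity score.
#'
#' @param net a [weighted_network()].
#' @param seed integer seed.
#' @param method `"resample"` (i.i.d. with replacement) or `"permute"`.
#' @return a [weighted_network()] with the same diagonal and node labels.
#' @export
randomize_network <- function(net, seed, method = c("resample", "permute")) {
  net <- as_weighted_network(net)
  method <- match.arg(method)
  w <- net$weights
  up <- upper.tri(w)
  vals <- w[up]
  set.seed(seed)
  new_vals <- switch(method,
                     resample = sample(vals, length(vals), replace = TRUE),
                     permute = sample(vals))
  r <- w
  r[up] <- new_vals
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  weighted_network(r, node_labels = net$node_labels)
}
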