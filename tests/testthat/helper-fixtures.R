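# Fixture generators and independent oracles shared across test files.

# Random positive-semidefinite correlation network (n x n), embeddable.
rand_corr_net <- function(n, seed, t_obs = n + 10) {
  set.seed(seed)
  z <- matrix(rnorm(n * t_obs), t_obs, n)
  weighted_network(stats::cor(z))
}

# Random symmetric matrix with unit diagonal, not necessarily PSD.
rand_sym_net <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, -1, 1)
  w <- w + t(w)
  diag(w) <- 1
  weighted_network(w)
}

random_permutation <- function(n, seed) {
  set.seed(seed)
  p <- diag(n)[sample(n), , drop = FALSE]
  p
}

permute_net <- function(net, p) {
  weighted_network(p %*% net$weights %*% t(p))
}

# Naive double-loop K estimator (correction "none"), the brute-force oracle.
brute_k_none <- function(pts, window, radii) {
  n <- nrow(pts)
  lambda <- n / window$volume
  vapply(radii, function(r) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt(sum((pts[i, ] - pts[j, ])^2)) < r) cnt <- cnt + 1
    }
    cnt / (n * lambda)
  }, numeric(1))
}

# Angular-grid oracle for the fraction of a circle inside a rectangle.
arc_fraction_oracle <- function(center, r, window, n_angles = 20000L) {
  th <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi
  x <- center[1] + r * cos(th)
  y <- center[2] + r * sin(th)
  mean(x >= window$lower[1] & x <= window$upper[1] &
         y >= window$lower[2] & y <= window$upper[2])
}

# Plain average silhouette width for labelled points (rows).
mean_silhouette <- function(pts, labels) {
  d <- as.matrix(dist(pts))
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(pts)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(lv) mean(d[i, labels == lv]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Small two-group specs used to keep simulation tests fast.
tiny_spec <- function(n_subjects = 4L, seed = 7L, sizes = c(4L, 4L),
                      rho = c(0.5, 0.6), n = 16L, n_time = 40L) {
  simulation_spec(n, sizes, rho, n_time = n_time, n_subjects = n_subjects,
                  seed = seed)
}
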