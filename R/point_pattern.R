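#' Axis-aligned observation windows
#'
#' The K-function estimator needs an observation window: the region the point
#' pattern is considered to occupy, which defines the intensity and the edge
#' correction.  `observation_window()` builds one explicitly;
#' `bounding_window()` takes the axis-aligned bounding box of a point set,
#' optionally expanded symmetrically by a fraction of each side length.
#'
#' @param lower,upper numeric vectors of box bounds, `upper > lower`
#'   elementwise.
#' @return a `geme_window`: list with `lower`, `upper`, `side_lengths`,
#'   `volume`, `k`.
#' @export
observation_window <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))))
  if (any(upper <= lower)) {
    stop("window must have positive volume: `upper` must exceed `lower` on ",
         "every axis", call. = FALSE)
  }
  sides <- upper - lower
  structure(list(lower = lower, upper = upper, side_lengths = sides,
                 volume = prod(sides), k = length(lower)),
            class = "geme_window")
}

#' @rdname observation_window
#' @param points a `geme_points` object or matrix of points in rows.
#' @param expand_fraction nonnegative scalar; each side is expanded
#'   symmetrically by this fraction of its length (default 0, the tight box).
#' @export
bounding_window <- function(points, expand_fraction = 0) {
  m <- point_matrix(points)
  stopifnot(expand_fraction >= 0)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  len <- hi - lo
  pad <- expand_fraction * len / 2
  lo <- lo - pad
  hi <- hi + pad
  if (any(hi <= lo)) {
    ax <- which(hi <= lo)[1]
    stop(sprintf(paste0(
      "all points coincide on axis %d, giving a zero-volume window; ",
      "raise `expand_fraction` or reduce the embedding dimension k"), ax),
      call. = FALSE)
  }
  observation_window(lo, hi)
}

#' @export
print.geme_window <- function(x, ...) {
  cat(sprintf("<geme_window> %s, volume %.6g\n",
              paste(sprintf("[%.4g, %.4g]", x$lower, x$upper), collapse = " x "),
              x$volume))
  invisible(x)
}

window_contains <- function(window, m, tol = 1e-9) {
  all(sweep(m, 2, window$lower, `-`) >= -tol) &&
    all(sweep(m, 2, window$upper, `-`) <= tol)
}

#' Empirical intensity of a point pattern
#'
#' The homogeneous-process intensity estimate: number of points per unit
#' window volume, `lambda = n / |W|`.
#'
#' @inheritParams bounding_window
#' @param window a `geme_window` containing all points.
#' @return positive scalar.
#' @export
intensity <- function(points, window) {
  m <- point_matrix(points)
  stopifnot(inherits(window, "geme_window"))
  if (window$volume <= 0) stop("zero-volume window", call. = FALSE)
  if (!window_contains(window, m)) {
    stop("window does not contain every point", call. = FALSE)
  }
  nrow(m) / window$volume
}

## Translation edge-correction weights for an axis-aligned box, any dimension:
## eta_ij = |W| / |W intersect (W + x_j - x_i)|, closed form
## prod_l (s_l - |dx_l|).  Returns the full n x n matrix (symmetric, diag 1).
translation_weights <- function(m, window) {
  n <- nrow(m)
  denom <- matrix(1, n, n)
  for (l in seq_len(ncol(m))) {
    dx <- abs(outer(m[, l], m[, l], `-`))
    denom <- denom * pmax(window$side_lengths[l] - dx, 0)
  }
  eta <- window$volume / denom
  diag(eta) <- 1
  eta
}

## Ripley isotropic correction for a rectangle (2-D only): eta_ij is the
## reciprocal of the fraction of the circle of radius d_ij centred at x_i
## that lies inside the window.  Exterior arc per edge is 2*acos(d_e/r);
## arcs protruding past a corner (d1^2 + d2^2 < r^2) overlap by
## pi/2 - asin(d1/r) - asin(d2/r), subtracted once per corner.
isotropic_fraction_inside <- function(center, r, window) {
  if (r <= 0) return(1)
  d <- c(center[1] - window$lower[1], window$upper[1] - center[1],
         center[2] - window$lower[2], window$upper[2] - center[2])
  d <- pmax(d, 0)
  out <- 0
  for (e in 1:4) if (d[e] < r) out <- out + 2 * acos(min(d[e] / r, 1))
  corners <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  for (cidx in 1:4) {
    d1 <- d[corners[cidx, 1]]; d2 <- d[corners[cidx, 2]]
    if (d1 * d1 + d2 * d2 < r * r) {
      out <- out - (pi / 2 - asin(min(d1 / r, 1)) - asin(min(d2 / r, 1)))
    }
  }
  max(1 - out / (2 * pi), .Machine$double.eps)
}

#' Default radii grid for the K function
#'
#' 100 equally spaced radii from `r_max/100` to `r_max`, where `r_max` is a
#' quarter of the shortest window side — the usual Ripley practice that keeps
#' boundary bias small.
#'
#' @param window a `geme_window`.
#' @param n_radii number of grid points, default 100.
#' @param r_max largest radius; default `min(side_lengths) / 4`.
#' @return strictly increasing numeric vector.
#' @export
default_radii <- function(window, n_radii = 100L, r_max = NULL) {
  r_max <- r_max %||% (min(window$side_lengths) / 4)
  stopifnot(r_max > 0, n_radii >= 1L)
  seq(r_max / n_radii, r_max, length.out = n_radii)
}

#' Edge-corrected Ripley K function of a point pattern
#'
#' Estimates `K(r) = lambda^-1 (1/n) sum_i sum_{j != i} eta_ij I(d_ij < r)`
#' over a radii grid, where `eta_ij` is the edge-correction weight:
#' `none` (1), `translation` (reciprocal overlap fraction of the window with
#' its shifted copy; valid in any dimension; the default elsewhere in the
#' package), or `isotropic2d` (reciprocal of the fraction of the circle of
#' radius `d_ij` around point `i` inside the window; 2-D only).  The
#' indicator is strict (`d_ij < r`), so coincident points count at every
#' positive radius.  The companion curve `L(r) = K(r) / c` and its integral
#' give the Geme complexity score; see [geme()].
#'
#' @inheritParams intensity
#' @param radii strictly increasing positive radii; default [default_radii()].
#'   A radius beyond half the window diameter triggers a boundary-bias
#'   warning (not an error).
#' @param correction `"translation"`, `"none"`, or `"isotropic2d"`.
#' @param c_constant the constant relating the cross-entropy curve `L` to
#'   `K`, `L = K / c`; default 1.
#' @return a `geme_kcurve`: list with `radii`, `k_hat`, `l_hat`, `intensity`,
#'   `c_constant`, `correction`, `n`.
#' @examples
#' set.seed(1)
#' pts <- matrix(runif(100), ncol = 2)
#' win <- observation_window(c(0, 0), c(1, 1))
#' kc <- k_function(pts, win, radii = c(0.05, 0.1))
#' kc$k_hat / (pi * c(0.05, 0.1)^2)  # near 1 under spatial randomness
#' @export
k_function <- function(points, window = bounding_window(points),
                       radii = default_radii(window),
                       correction = c("translation", "none", "isotropic2d"),
                       c_constant = 1) {
  correction <- match.arg(correction)
  m <- point_matrix(points)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 points for a K function", call. = FALSE)
  radii <- as.numeric(radii)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("`radii` must be strictly increasing and positive", call. = FALSE)
  }
  half_diam <- sqrt(sum(window$side_lengths^2)) / 2
  if (max(radii) > half_diam + 1e-12) {
    warning("largest radius exceeds half the window diameter; boundary bias ",
            "may be severe", call. = FALSE)
  }
  if (correction == "isotropic2d" && ncol(m) != 2L) {
    stop("isotropic2d correction is only available for 2-D point sets",
         call. = FALSE)
  }
  lambda <- intensity(m, window)
  d <- as.matrix(dist(m))
  eta <- switch(correction,
    none = matrix(1, n, n),
    translation = translation_weights(m, window),
    isotropic2d = {
      e <- matrix(1, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j) e[i, j] <- 1 / isotropic_fraction_inside(m[i, ], d[i, j], window)
      }
      e
    })
  off <- upper.tri(d) | lower.tri(d)
  dv <- d[off]
  wv <- eta[off]
  ord <- order(dv)
  csum <- c(0, cumsum(wv[ord]))
  idx <- findInterval(radii, dv[ord], left.open = TRUE)  # strict d < r
  k_hat <- csum[idx + 1L] / (lambda * n)
  structure(list(radii = radii, k_hat = k_hat, l_hat = k_hat / c_constant,
                 intensity = lambda, c_constant = c_constant,
                 correction = correction, n = n),
            class = "geme_kcurve")
}

#' @export
print.geme_kcurve <- function(x, ...) {
  cat(sprintf(
    "<geme_kcurve> %d radii in [%.4g, %.4g], correction = %s, lambda = %.4g\n",
    length(x$radii), min(x$radii), max(x$radii), x$correction, x$intensity))
  invisible(x)
}

#' Direct cross-entropy curve of a 2-D point pattern
#'
#' Literal transcription of the cross-entropy between the observed pattern
#' and a homogeneous Poisson reference:
#' `L(r) = -(1/n) sum_i sum_{j != i} I(d_ij < r) log(pi r^2 lambda)`,
#' where `pi r^2 lambda` is the expected point count in a disc of radius `r`.
#' Exposed for inspection and comparison; the default complexity pipeline
#' uses the K-based estimator in [k_function()] instead, because the
#' `log(pi r^2 lambda)` factor depends on `r` and cannot equal a constant
#' multiple of `K(r)`.
#'
#' @inheritParams k_function
#' @return tibble with columns `r` and `l_hat`.
#' @export
cross_entropy_direct <- function(points, window = bounding_window(points),
                                 radii = default_radii(window)) {
  m <- point_matrix(points)
  if (ncol(m) != 2L) {
    stop("the direct cross-entropy curve uses the planar disc area pi*r^2 ",
         "and requires k = 2", call. = FALSE)
  }
  radii <- as.numeric(radii)
  stopifnot(all(radii > 0))
  lambda <- intensity(m, window)
  n <- nrow(m)
  d <- as.matrix(dist(m))
  dv <- sort(d[upper.tri(d) | lower.tri(d)])
  counts <- findInterval(radii, dv, left.open = TRUE)
  tibble::tibble(r = radii,
                 l_hat = -(counts / n) * log(pi * radii^2 * lambda))
}

#' Configuration for the Geme pipeline
#'
#' Bundles the tunable parameters of the complexity metric with their
#' defaults: embedding dimension `k = 2`, translation edge correction, 100
#' radii up to a quarter of the shortest window side, `c = 1` (so the score
#' is the area under the corrected K curve), and a tight bounding window.
#'
#' @param k embedding dimension.
#' @param correction edge correction, see [k_function()].
#' @param n_radii number of radii in the grid.
#' @param r_max largest radius, or `NULL` for the quarter-side rule.
#' @param c_constant constant relating `L` and `K` (`L = K / c`).
#' @param expand_fraction window expansion, see [bounding_window()].
#' @return a `geme_config` list.
#' @export
geme_config <- function(k = 2L, correction = "translation", n_radii = 100L,
                        r_max = NULL, c_constant = 1, expand_fraction = 0) {
  stopifnot(k >= 1L, n_radii >= 2L, c_constant > 0, expand_fraction >= 0)
  structure(list(k = as.integer(k), correction = correction,
                 n_radii = as.integer(n_radii), r_max = r_max,
                 c_constant = c_constant, expand_fraction = expand_fraction),
            class = "geme_config")
}

## Fast internal core: raw symmetric matrix -> list(geme, curve fields).
## Shared by geme() and the simulation/power loops, which skip the S3
## wrappers for speed.
geme_core <- function(w, cfg) {
  n <- nrow(w)
  rm <- rowMeans(w)
  b <- 0.5 * (w - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(w))
  eg <- eigen(b, symmetric = TRUE)
  vals <- eg$values
  if (max(vals) <= 1e-12) {
    stop("degenerate embedding: no positive eigenvalue", call. = FALSE)
  }
  lam <- pmax(vals[seq_len(cfg$k)], 0)
  vec <- eg$vectors[, seq_len(cfg$k), drop = FALSE]
  for (j in seq_len(cfg$k)) {
    pivot <- which.max(abs(vec[, j]))
    if (vec[pivot, j] < 0) vec[, j] <- -vec[, j]
  }
  m <- vec * rep(sqrt(lam), each = n)  # n x k points
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  len <- hi - lo
  pad <- cfg$expand_fraction * len / 2
  lo <- lo - pad; hi <- hi + pad
  sides <- hi - lo
  if (any(sides <= 0)) {
    stop("all embedded points coincide on an axis; raise `expand_fraction` ",
         "or reduce k", call. = FALSE)
  }
  vol <- prod(sides)
  lambda <- n / vol
  r_max <- cfg$r_max %||% (min(sides) / 4)
  radii <- seq(r_max / cfg$n_radii, r_max, length.out = cfg$n_radii)
  d <- as.matrix(dist(m))
  off <- upper.tri(d)
  dv <- d[off]
  wv <- switch(cfg$correction,
    none = rep(1, length(dv)),
    translation = {
      denom <- rep(1, length(dv))
      for (l in seq_len(ncol(m))) {
        dx <- abs(outer(m[, l], m[, l], `-`))[off]
        denom <- denom * pmax(sides[l] - dx, 0)
      }
      vol / denom
    },
    stop(sprintf("unsupported correction in fast path: %s", cfg$correction),
         call. = FALSE))
  ord <- order(dv)
  csum <- c(0, cumsum(wv[ord]))
  idx <- findInterval(radii, dv[ord], left.open = TRUE)
  k_hat <- 2 * csum[idx + 1L] / (lambda * n)  # x2: unordered -> ordered pairs
  l_hat <- k_hat / cfg$c_constant
  list(geme = trapezoid(radii, l_hat), radii = radii, k_hat = k_hat,
       l_hat = l_hat, lambda = lambda,
       neg_mass = sum(abs(vals[vals < 0])))
}

#' Geme: graph-embedding complexity of a weighted network
#'
#' The full pipeline: embed the network in `R^k` ([embed_network()]), take
#' the bounding window of the embedded points, estimate the edge-corrected K
#' function on the radii grid, form `L(r) = K(r) / c`, and integrate the
#' curve over the grid with the trapezoidal rule.  The resulting scalar is
#' large when the embedded points cluster (an organized network) and small
#' when they resemble complete spatial randomness (an unstructured random
#' graph).  The score depends only on interpoint distances and the window,
#' so it is invariant to node permutation.
#'
#' @param net a [weighted_network()] (or square matrix coercible to one).
#' @param config a [geme_config()].
#' @return a `geme_result`: list with `geme` (the scalar score), `curve`
#'   (a `geme_kcurve`), `embedding_dim`, `n_points`,
#'   `discarded_negative_mass`.
#' @examples
#' w <- diag(6)
#' w[1:3, 1:3] <- 0.7; w[4:6, 4:6] <- 0.7; diag(w) <- 1
#' res <- geme(weighted_network(w), geme_config(n_radii = 50))
#' res$geme
#' @export
geme <- function(net, config = geme_config()) {
  net <- as_weighted_network(net)
  stopifnot(inherits(config, "geme_config"))
  if (config$correction == "isotropic2d") {
    ## slower generic path for the 2-D cross-check correction
    pts <- embed_network(net, config$k)
    win <- bounding_window(pts, config$expand_fraction)
    radii <- default_radii(win, config$n_radii, config$r_max)
    curve <- k_function(pts, win, radii, correction = "isotropic2d",
                        c_constant = config$c_constant)
    score <- trapezoid(curve$radii, curve$l_hat)
    neg <- pts$discarded_negative_mass
  } else {
    core <- geme_core(net$weights, config)
    curve <- structure(list(radii = core$radii, k_hat = core$k_hat,
                            l_hat = core$l_hat, intensity = core$lambda,
                            c_constant = config$c_constant,
                            correction = config$correction,
                            n = n_nodes(net)),
                       class = "geme_kcurve")
    score <- core$geme
    neg <- core$neg_mass
  }
  structure(list(geme = score, curve = curve, embedding_dim = config$k,
                 n_points = n_nodes(net), discarded_negative_mass = neg),
            class = "geme_result")
}

#' @export
print.geme_result <- function(x, ...) {
  cat(sprintf("<geme_result> Geme = %.6g (n = %d nodes, k = %d, correction = %s)\n",
              x$geme, x$n_points, x$embedding_dim, x$curve$correction))
  invisible(x)
}

#' Geme scores for a batch of networks
#'
#' Applies [geme()] to each network, preserving order; per-network failures
#' are caught and reported in the `error` column while the batch continues.
#' Results are independent of evaluation order.
#'
#' @param networks list of [weighted_network()] objects (or matrices); names
#'   become the `id` column.
#' @param config a [geme_config()].
#' @return tibble with columns `id`, `n`, `k`, `geme`, `error`.
#' @export
geme_batch <- function(networks, config = geme_config()) {
  stopifnot(length(networks) > 0L)
  ids <- names(networks) %||% as.character(seq_along(networks))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  rows <- purrr::imap(networks, function(net, i) {
    out <- tryCatch(
      list(val = geme(net, config), err = NA_character_),
      error = function(e) list(val = NULL, err = conditionMessage(e)))
    tibble::tibble(
      n = if (is.null(out$val)) NA_integer_ else out$val$n_points,
      k = config$k,
      geme = if (is.null(out$val)) NA_real_ else out$val$geme,
      error = out$err)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(id = ids, .before = 1)
}
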