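#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the K/L curve of a Geme result
#'
#' @param x a `geme_result`.
#' @param ... unused.
#' @return tibble with one row per radius: `r`, `k_hat`, `l_hat`.
#' @export
tidy.geme_result <- function(x, ...) tidy(x$curve)

#' @rdname tidy.geme_result
#' @export
tidy.geme_kcurve <- function(x, ...) {
  tibble::tibble(r = x$radii, k_hat = x$k_hat, l_hat = x$l_hat)
}

#' One-row summary of a Geme result
#'
#' @param x a `geme_result`.
#' @param ... unused.
#' @return tibble with `geme`, `n`, `k`, `correction`, `intensity`,
#'   `discarded_negative_mass`.
#' @export
glance.geme_result <- function(x, ...) {
  tibble::tibble(geme = x$geme, n = x$n_points, k = x$embedding_dim,
                 correction = x$curve$correction,
                 intensity = x$curve$intensity,
                 discarded_negative_mass = x$discarded_negative_mass)
}

#' Tidy a two-group Geme test
#'
#' @param x a `geme_test`.
#' @param ... unused.
#' @return one-row tibble: `statistic`, `p.value`, `alpha`, `reject`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `method`.
#' @export
tidy.geme_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 alpha = x$alpha, reject = x$reject,
                 mean_a = x$group_means[1], mean_b = x$group_means[2],
                 n_a = x$group_sizes[1], n_b = x$group_sizes[2],
                 method = x$method)
}

#' Tidy a Monte-Carlo power estimate
#'
#' @param x a `power_estimate`.
#' @param ... unused.
#' @return one-row tibble: `power`, `se`, `n_replicates`, `alpha`, `method`.
#' @export
tidy.power_estimate <- function(x, ...) {
  tibble::tibble(power = x$rejection_rate, se = x$standard_error,
                 n_replicates = x$n_replicates, alpha = x$alpha,
                 method = x$method)
}

#' @rdname tidy.power_estimate
#' @export
glance.power_estimate <- tidy.power_estimate

#' Tidy a covariate regression of complexity scores
#'
#' @param x a `geme_regression`.
#' @param ... unused.
#' @return the coefficient tibble (term, estimate, std.error, statistic,
#'   p.value).
#' @export
tidy.geme_regression <- function(x, ...) x$coefficients

#' Tidy an embedded point set into a per-node tibble
#'
#' @param x a `geme_points` object.
#' @param ... unused.
#' @return tibble with `node` and coordinate columns `x1..xk`.
#' @export
tidy.geme_points <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(t(x$coordinates)),
                           .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(x$k))
  dplyr::bind_cols(tibble::tibble(node = x$node_labels), out)
}
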