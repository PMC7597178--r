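#' Two-group comparison of Geme scores
#'
#' Compares per-subject complexity scores between two groups with Welch's
#' unequal-variance t-test (default; robust to the variance differences that
#' different network structures induce) or the Wilcoxon rank-sum test as a
#' sensitivity alternative.  Two-sided p-value; rejection at level `alpha`.
#'
#' @param geme_a,geme_b numeric vectors of scores, at least 2 finite values
#'   each.
#' @param alpha significance level, default 0.05.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return a `geme_test`: list with `statistic`, `p_value`, `alpha`,
#'   `reject`, `group_means`, `group_sizes`, `method`.
#' @examples
#' two_group_test(rnorm(20), rnorm(20, 1))
#' @export
two_group_test <- function(geme_a, geme_b, alpha = 0.05,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  geme_a <- as.numeric(geme_a); geme_b <- as.numeric(geme_b)
  if (length(geme_a) < 2L || length(geme_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(geme_a)) || !all(is.finite(geme_b))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (method == "welch") {
    ht <- tryCatch(t.test(geme_a, geme_b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(ht)) {
      ## both groups constant: equal means -> no evidence, unequal -> certain
      if (isTRUE(all.equal(mean(geme_a), mean(geme_b)))) {
        stat <- 0; pval <- 1
      } else {
        stat <- sign(mean(geme_a) - mean(geme_b)) * Inf; pval <- 0
      }
    } else {
      stat <- unname(ht$statistic); pval <- ht$p.value
    }
  } else {
    ht <- suppressWarnings(wilcox.test(geme_a, geme_b, exact = FALSE))
    stat <- unname(ht$statistic); pval <- ht$p.value
  }
  structure(list(statistic = stat, p_value = pval, alpha = alpha,
                 reject = pval < alpha,
                 group_means = c(mean(geme_a), mean(geme_b)),
                 group_sizes = c(length(geme_a), length(geme_b)),
                 method = method),
            class = "geme_test")
}

#' @export
print.geme_test <- function(x, ...) {
  cat(sprintf(
    "<geme_test> %s: statistic = %.4g, p = %.4g (%s at alpha = %g)\n  group means %.5g vs %.5g (n = %d, %d)\n",
    x$method, x$statistic, x$p_value,
    if (x$reject) "reject" else "fail to reject", x$alpha,
    x$group_means[1], x$group_means[2], x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

## One replicate study: per-subject Geme vectors for both groups, computed on
## the fast core.  Subject substream: mix(seed, group tag, subject).
replicate_geme <- function(spec1, spec2, seed, config) {
  gen <- function(spec, tag, chol_upper) {
    vapply(seq_len(spec$n_subjects), function(s) {
      z <- sample_from_chol(chol_upper, spec$n_nodes, spec$n_time, spec$mean,
                            mix_seed(seed, tag, s))
      u <- tcrossprod(z) / (spec$n_time - 1)
      sc <- 1 / sqrt(diag(u))
      w <- u * outer(sc, sc)
      diag(w) <- 1
      geme_core(w, config)$geme
    }, numeric(1))
  }
  list(g1 = gen(spec1, 1L, chol(block_covariance(spec1))),
       g2 = gen(spec2, 2L, chol(block_covariance(spec2))))
}

#' Monte-Carlo power of the two-group Geme comparison
#'
#' Repeats the full study `n_replicates` times: simulate both groups of
#' correlation networks ([simulate_group_study()] design), score every
#' subject with [geme()], and apply [two_group_test()] at level `alpha`.
#' The estimated power is the fraction of replicates rejecting, with the
#' binomial standard error `sqrt(p (1 - p) / n_replicates)`.  Replicate
#' substreams derive from `seed`, so the whole estimate is reproducible.
#'
#' @param spec1,spec2 [simulation_spec()] objects (equal `n_nodes`).
#' @param n_replicates number of replicate studies, default 100.
#' @param alpha significance level, default 0.05.
#' @param seed master seed; defaults to `spec1$seed`.
#' @param config a [geme_config()].
#' @param method test passed to [two_group_test()].
#' @return a `power_estimate`: list with `rejection_rate`, `standard_error`,
#'   `n_replicates`, `alpha`, `spec_pair`, `method`, `p_values`.
#' @export
power_simulation <- function(spec1, spec2, n_replicates = 100L, alpha = 0.05,
                             seed = spec1$seed, config = geme_config(),
                             method = "welch") {
  stopifnot(inherits(spec1, "simulation_spec"),
            inherits(spec2, "simulation_spec"), n_replicates >= 1L)
  if (spec1$n_nodes != spec2$n_nodes) {
    stop("both groups must share the node count", call. = FALSE)
  }
  pvals <- vapply(seq_len(n_replicates), function(rep) {
    scores <- tryCatch(
      replicate_geme(spec1, spec2, mix_seed(seed, rep), config),
      error = function(e) stop(sprintf("replicate %d failed: %s", rep,
                                       conditionMessage(e)), call. = FALSE))
    two_group_test(scores$g1, scores$g2, alpha, method)$p_value
  }, numeric(1))
  rate <- mean(pvals < alpha)
  structure(list(rejection_rate = rate,
                 standard_error = sqrt(rate * (1 - rate) / n_replicates),
                 n_replicates = as.integer(n_replicates),
                 alpha = alpha,
                 spec_pair = list(spec1, spec2),
                 method = method,
                 p_values = pvals),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> %.1f%% +/- %.1f%% rejection over %d replicates (alpha = %g)\n",
              100 * x$rejection_rate, 100 * x$standard_error,
              x$n_replicates, x$alpha))
  invisible(x)
}

#' Power grid over group-two designs
#'
#' Fixes group one and sweeps group two over a grid of block-size pairs and
#' correlation pairs, estimating power in each cell.  All cells share the
#' same master seed (common random numbers), which sharpens comparisons of
#' power across cells.
#'
#' @param spec1 group-one [simulation_spec()].
#' @param size_pairs list of group-two block-size vectors (grid columns).
#' @param corr_pairs list of group-two correlation vectors (grid rows).
#' @param n_subjects2 group-two subjects per study; defaults to group one's.
#' @inheritParams power_simulation
#' @return tibble with one row per cell: `correlations`, `sizes` (label
#'   strings), `power`, `se`, `n_replicates`.
#' @export
power_grid <- function(spec1, size_pairs, corr_pairs,
                       n_subjects2 = spec1$n_subjects,
                       n_replicates = 100L, alpha = 0.05, seed = spec1$seed,
                       config = geme_config(), method = "welch") {
  cells <- expand.grid(ci = seq_along(corr_pairs),
                       si = seq_along(size_pairs))
  rows <- purrr::pmap(cells, function(ci, si) {
    spec2 <- simulation_spec(spec1$n_nodes, size_pairs[[si]], corr_pairs[[ci]],
                             n_time = spec1$n_time, n_subjects = n_subjects2,
                             mean = spec1$mean, seed = spec1$seed)
    pe <- power_simulation(spec1, spec2, n_replicates, alpha, seed, config,
                           method)
    tibble::tibble(
      correlations = paste0("(", paste(corr_pairs[[ci]], collapse = ", "), ")"),
      sizes = paste0("(", paste(size_pairs[[si]], collapse = ", "), ")"),
      power = pe$rejection_rate,
      se = pe$standard_error,
      n_replicates = pe$n_replicates)
  })
  dplyr::bind_rows(rows)
}

#' Covariate regression of complexity scores on group, sex and age
#'
#' Fits the ordinary linear model
#' `geme ~ group + sex + age + group:sex` by least squares and reports the
#' coefficient table plus sex-stratified group contrasts (`geme ~ group +
#' age` within each sex level) — the typical adjusted group-comparison
#' workflow for per-subject network complexity in a clinical cohort.
#'
#' @param data data frame with columns `geme` (numeric), `group` (factor, at
#'   least 2 levels), `sex` (factor), `age` (numeric).
#' @return a `geme_regression`: list with `coefficients` (tibble: term,
#'   estimate, std.error, statistic, p.value), `stratified` (tibble: sex
#'   level, group estimate, p.value, n), and `model` (the `lm` fit).
#' @export
covariate_regression <- function(data) {
  need <- c("geme", "sex", "group", "age")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop(sprintf("`data` lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  data <- as.data.frame(data)
  data$group <- as.factor(data$group)
  data$sex <- as.factor(data$sex)
  if (nlevels(data$group) < 2L) {
    stop("`group` needs at least 2 levels", call. = FALSE)
  }
  fit <- lm(geme ~ group + sex + age + group:sex, data = data)
  if (anyNA(coef(fit))) {
    stop(sprintf("rank-deficient design: collinear term(s) %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = rownames(sm),
                          estimate = unname(sm[, 1]),
                          std.error = unname(sm[, 2]),
                          statistic = unname(sm[, 3]),
                          p.value = unname(sm[, 4]))
  strat <- purrr::map(levels(data$sex), function(lv) {
    sub <- data[data$sex == lv, , drop = FALSE]
    if (nrow(sub) < 4L || nlevels(droplevels(sub$group)) < 2L) {
      return(tibble::tibble(sex = lv, estimate = NA_real_,
                            p.value = NA_real_, n = nrow(sub)))
    }
    sfit <- summary(lm(geme ~ group + age, data = sub))$coefficients
    grow <- grep("^group", rownames(sfit))[1]
    tibble::tibble(sex = lv, estimate = sfit[grow, 1],
                   p.value = sfit[grow, 4], n = nrow(sub))
  }) |> dplyr::bind_rows()
  structure(list(coefficients = coefs, stratified = strat, model = fit),
            class = "geme_regression")
}

#' @export
print.geme_regression <- function(x, ...) {
  cat("<geme_regression> geme ~ group + sex + age + group:sex\n")
  print(as.data.frame(x$coefficients), digits = 4)
  cat("stratified group contrasts:\n")
  print(as.data.frame(x$stratified), digits = 4)
  invisible(x)
}

#' Synthetic cohort of complexity scores with a planted group-by-sex effect
#'
#' Generates subject covariates (balanced group and sex, uniform ages) and
#' complexity scores from the linear model
#' `geme = intercept + b_group + b_sex + b_age * age + b_interaction + noise`
#' with independent normal noise — a score-level emulation of a clinical
#' cohort used to validate [covariate_regression()] by parameter recovery.
#'
#' @param n_subjects cohort size.
#' @param effects named numeric vector with entries `intercept`, `group`,
#'   `sex`, `age`, `interaction`.
#' @param sd_noise residual standard deviation.
#' @param seed integer seed.
#' @return tibble with columns `geme`, `group`, `sex`, `age`.
#' @export
simulate_cohort <- function(n_subjects = 200L,
                            effects = c(intercept = 1, group = 0.3,
                                        sex = 0.1, age = 0.01,
                                        interaction = 0.5),
                            sd_noise = 0.5, seed = 1L) {
  stopifnot(all(c("intercept", "group", "sex", "age", "interaction") %in%
                  names(effects)))
  set.seed(seed)
  group <- factor(sample(rep(c("control", "case"), length.out = n_subjects)),
                  levels = c("control", "case"))
  sex <- factor(sample(rep(c("F", "M"), length.out = n_subjects)),
                levels = c("F", "M"))
  age <- stats::runif(n_subjects, 18, 65)
  gi <- as.numeric(group == "case")
  si <- as.numeric(sex == "M")
  score <- effects[["intercept"]] + effects[["group"]] * gi +
    effects[["sex"]] * si + effects[["age"]] * age +
    effects[["interaction"]] * gi * si + rnorm(n_subjects, 0, sd_noise)
  tibble::tibble(geme = score, group = group, sex = sex, age = age)
}
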