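test_that("Welch test matches the hand-computed formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  res <- two_group_test(a, b)
  # direct Welch arithmetic: t = (xbar - ybar) / sqrt(s1^2/n1 + s2^2/n2),
  # Welch-Satterthwaite degrees of freedom
  se2 <- var(a) / 5 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  expect_equal(res$group_means, c(3, 4))
  expect_equal(res$group_sizes, c(5L, 5L))
  expect_false(res$reject)
})

test_that("degenerate two-group inputs are handled per contract", {
  x <- c(1, 2, 3)
  res <- two_group_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  const <- two_group_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  expect_false(const$reject)

  expect_error(two_group_test(1, c(1, 2)), "at least 2")
  expect_error(two_group_test(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("type-I error of the Welch test sits at the nominal level", {
  set.seed(314)
  rej <- vapply(seq_len(1000), function(i) {
    two_group_test(rnorm(15), rnorm(15))$reject
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("the rank-sum alternative is available behind a flag", {
  set.seed(21)
  a <- rnorm(20)
  b <- rnorm(20, 2)
  res <- two_group_test(a, b, method = "wilcoxon")
  expect_true(res$reject)
  expect_equal(res$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE))$p.value)
})

test_that("power simulation is deterministic, bounded and correctly summarized", {
  s1 <- tiny_spec(n_subjects = 5L)
  s2 <- tiny_spec(n_subjects = 5L, sizes = c(4L, 6L))
  cfg <- geme_config(n_radii = 30)
  p1 <- power_simulation(s1, s2, n_replicates = 4, seed = 9, config = cfg)
  p2 <- power_simulation(s1, s2, n_replicates = 4, seed = 9, config = cfg)
  expect_identical(p1$p_values, p2$p_values)
  expect_gte(p1$rejection_rate, 0)
  expect_lte(p1$rejection_rate, 1)
  expect_equal(p1$standard_error,
               sqrt(p1$rejection_rate * (1 - p1$rejection_rate) / 4))

  # alpha = 0 can never reject
  p0 <- power_simulation(s1, s1, n_replicates = 3, alpha = 0, seed = 9,
                         config = cfg)
  expect_equal(p0$rejection_rate, 0)

  td <- tidy(p1)
  expect_equal(td$power, p1$rejection_rate)
  expect_equal(td$n_replicates, 4L)
})

test_that("power grids carry one labelled row per cell", {
  s1 <- tiny_spec(n_subjects = 4L)
  gd <- power_grid(s1, size_pairs = list(c(4L, 4L), c(4L, 6L)),
                   corr_pairs = list(c(0.5, 0.6)),
                   n_replicates = 2, seed = 2,
                   config = geme_config(n_radii = 25))
  expect_equal(nrow(gd), 2)
  expect_setequal(gd$sizes, c("(4, 4)", "(4, 6)"))
  expect_equal(gd$correlations, rep("(0.5, 0.6)", 2))
  expect_true(all(gd$power >= 0 & gd$power <= 1))
  expect_s3_class(plot_power_grid(gd), "ggplot")
})

test_that("covariate regression recovers trivial and symmetric structure", {
  set.seed(6)
  df <- simulate_cohort(60, effects = c(intercept = 2, group = 0, sex = 0,
                                        age = 0, interaction = 0),
                        sd_noise = 0, seed = 8)
  df$geme <- 2  # constant outcome; lm warns about the perfect fit
  fit <- suppressWarnings(covariate_regression(df))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-10)
  expect_true(all(abs(est[names(est) != "(Intercept)"]) < 1e-10))

  # swapping group labels negates the group effect, p-value unchanged
  df2 <- simulate_cohort(80, seed = 10)
  f1 <- covariate_regression(df2)
  df3 <- df2
  df3$group <- factor(df3$group, levels = rev(levels(df2$group)))
  f2 <- covariate_regression(df3)
  g1 <- f1$coefficients[grepl("^group", f1$coefficients$term) &
                          !grepl(":", f1$coefficients$term), ]
  g2 <- f2$coefficients[grepl("^group", f2$coefficients$term) &
                          !grepl(":", f2$coefficients$term), ]
  expect_equal(g1$estimate, -g2$estimate, tolerance = 1e-10)
  expect_equal(g1$p.value, g2$p.value, tolerance = 1e-10)

  expect_error(covariate_regression(df2[, c("geme", "group")]),
               "lacks column")
  dfc <- df2
  dfc$sex <- dfc$group  # collinear factors break the interaction design
  expect_error(covariate_regression(dfc), "collinear|contrasts")
})

test_that("the planted group-by-sex interaction is recovered across cohorts", {
  planted <- 0.5
  hits <- vapply(seq_len(100), function(s) {
    df <- simulate_cohort(200, effects = c(intercept = 1, group = 0.3,
                                           sex = 0.1, age = 0.01,
                                           interaction = planted),
                          sd_noise = 0.5, seed = 5000 + s)
    co <- covariate_regression(df)$coefficients
    row <- co[grepl(":", co$term), ]
    abs(row$estimate - planted) <= 2 * row$std.error
  }, logical(1))
  # 2-SE coverage is ~95%; allow 3 binomial SDs of slack at 100 cohorts
  expect_gte(mean(hits), 0.88)

  # stratified contrasts surface the sex-specific group difference
  df <- simulate_cohort(400, effects = c(intercept = 1, group = 0, sex = 0,
                                         age = 0, interaction = 1),
                        sd_noise = 0.3, seed = 99)
  strat <- covariate_regression(df)$stratified
  expect_lt(strat$p.value[strat$sex == "M"], 0.01)
  expect_gt(strat$p.value[strat$sex == "F"], 0.01)
})
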