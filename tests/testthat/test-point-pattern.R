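test_that("bounding windows expand symmetrically and reject degenerate clouds", {
  pts <- rbind(c(0, 0), c(1, 1))
  w0 <- bounding_window(pts)
  expect_equal(w0$lower, c(0, 0))
  expect_equal(w0$upper, c(1, 1))
  expect_equal(w0$volume, 1)

  w1 <- bounding_window(pts, expand_fraction = 0.1)
  expect_equal(w1$lower, c(-0.05, -0.05))
  expect_equal(w1$upper, c(1.05, 1.05))
  expect_equal(w1$volume, 1.21)

  expect_error(bounding_window(matrix(0, 4, 2)), "zero-volume")
  expect_error(observation_window(c(0, 0), c(1, 0)), "positive volume")
})

test_that("intensity is points per unit volume and conserves counts", {
  unit_sq <- observation_window(c(0, 0), c(1, 1))
  expect_equal(intensity(matrix(runif(8), 4, 2), unit_sq), 4)
  big <- observation_window(c(0, 0), c(2, 2))
  expect_equal(intensity(matrix(runif(18, 0, 2), 9, 2), big), 2.25)
  set.seed(2)
  m <- matrix(runif(26), 13, 2)
  win <- bounding_window(m)
  expect_equal(intensity(m, win) * win$volume, 13)
  expect_error(intensity(matrix(2, 3, 2), unit_sq), "does not contain")
})

test_that("K estimates match hand-derived counts", {
  # two points at distance 1 inside a large window: no pair within r < 1
  far <- rbind(c(5, 5), c(6, 5))
  big <- observation_window(c(0, 0), c(11, 11))
  kc <- k_function(far, big, radii = c(0.3, 0.6, 0.9), correction = "none")
  expect_equal(kc$k_hat, c(0, 0, 0))

  # 3x3 unit grid in [0,2]^2: 24 ordered unit-distance pairs at r = 1.1
  grid9 <- as.matrix(expand.grid(0:2, 0:2))
  win <- observation_window(c(0, 0), c(2, 2))
  kc9 <- k_function(grid9, win, radii = 1.1, correction = "none")
  expect_equal(kc9$intensity, 2.25)
  expect_equal(kc9$k_hat, 32 / 27, tolerance = 1e-12)
})

test_that("uncorrected K equals the brute-force double loop exactly", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:40, 1)
    pts <- matrix(runif(2 * n), n, 2)
    win <- observation_window(c(0, 0), c(1, 1))
    radii <- seq(0.02, 0.3, length.out = 12)
    kc <- k_function(pts, win, radii, correction = "none")
    expect_equal(kc$k_hat, brute_k_none(pts, win, radii), tolerance = 1e-13)
  }
})

test_that("K is non-decreasing in r and edge correction only inflates it", {
  for (s in 1:8) {
    set.seed(100 + s)
    pts <- matrix(runif(60), 30, 2)
    win <- observation_window(c(0, 0), c(1, 1))
    radii <- seq(0.01, 0.25, length.out = 25)
    k_none <- k_function(pts, win, radii, correction = "none")
    k_trans <- k_function(pts, win, radii, correction = "translation")
    expect_true(all(diff(k_none$k_hat) >= 0))
    expect_true(all(diff(k_trans$k_hat) >= 0))
    # eta_ij >= 1, so corrected counts dominate pointwise
    expect_true(all(k_trans$k_hat >= k_none$k_hat - 1e-12))
    expect_equal(k_trans$l_hat, k_trans$k_hat / k_trans$c_constant)
  }
})

test_that("translation-corrected K is unbiased for pi r^2 under spatial randomness", {
  set.seed(42)
  radii <- c(0.05, 0.1)
  draws <- 200L
  win <- observation_window(c(0, 0), c(1, 1))
  ks <- vapply(seq_len(draws), function(i) {
    k_function(matrix(runif(200), 100, 2), win, radii,
               correction = "translation")$k_hat
  }, numeric(2))
  for (j in 1:2) {
    se <- sd(ks[j, ]) / sqrt(draws)
    expect_lt(abs(mean(ks[j, ]) - pi * radii[j]^2), 3 * se)
  }
})

test_that("isotropic correction matches an angular-grid oracle and is 2-D only", {
  win <- observation_window(c(0, 0), c(1, 2))
  set.seed(9)
  for (i in 1:20) {
    center <- c(runif(1), runif(1, 0, 2))
    r <- runif(1, 0.05, 0.6)
    expect_equal(geme:::isotropic_fraction_inside(center, r, win),
                 arc_fraction_oracle(center, r, win), tolerance = 5e-4)
  }
  pts3 <- matrix(runif(30), 10, 3)
  expect_error(k_function(pts3, bounding_window(pts3), c(0.1),
                          correction = "isotropic2d"), "2-D")
})

test_that("isotropic correction is exactly neutral away from the boundary", {
  # circles of radius d_ij lie inside the window, so every weight is 1
  set.seed(77)
  pts <- matrix(runif(40, 0.45, 0.55), 20, 2)
  win <- observation_window(c(0, 0), c(1, 1))
  radii <- seq(0.01, 0.12, length.out = 8)
  k_none <- k_function(pts, win, radii, correction = "none")$k_hat
  k_iso <- k_function(pts, win, radii, correction = "isotropic2d")$k_hat
  expect_equal(k_iso, k_none, tolerance = 1e-12)
})

test_that("radius beyond half the window diameter warns but still computes", {
  pts <- matrix(runif(30), 15, 2)
  win <- observation_window(c(0, 0), c(1, 1))
  expect_warning(k_function(pts, win, radii = c(0.5, 1.2)), "half the window")
  expect_error(k_function(pts, win, radii = c(0.2, 0.1)), "strictly increasing")
})

test_that("direct cross-entropy transcribes the printed formula", {
  win <- observation_window(c(0, 0), c(1, 1))
  # two points at distance 0.5, lambda = 2: L(0.6) = -log(pi * 0.36 * 2)
  duo <- rbind(c(0.25, 0.5), c(0.75, 0.5))
  ce <- cross_entropy_direct(duo, win, radii = 0.6)
  expect_equal(ce$l_hat, -log(pi * 0.36 * 2), tolerance = 1e-12)

  # no pairs within range: curve identically zero
  ce0 <- cross_entropy_direct(duo, win, radii = c(0.1, 0.3))
  expect_equal(ce0$l_hat, c(0, 0))

  # the curve changes sign where pi r^2 lambda crosses 1
  set.seed(12)
  pts <- matrix(runif(80), 40, 2)
  lam <- intensity(pts, win)
  r_cross <- 1 / sqrt(pi * lam)
  ce2 <- cross_entropy_direct(pts, win,
                              radii = c(r_cross * 0.9, r_cross * 1.1))
  expect_gt(ce2$l_hat[1], 0)
  expect_lt(ce2$l_hat[2], 0)

  expect_error(cross_entropy_direct(matrix(runif(30), 10, 3)), "k = 2")
})
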