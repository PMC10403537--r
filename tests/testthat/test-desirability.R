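test_that("desirability scores follow the Derringer-Suich definitions", {
  g_max <- goal("maximize", low = 0, target = 10)
  expect_equal(desirability_value(c(-5, 0, 5, 10, 20), g_max),
               c(0, 0, 0.5, 1, 1))
  g_min <- goal("minimize", target = 0, high = 10)
  expect_equal(desirability_value(c(-5, 0, 5, 10, 20), g_min),
               c(1, 1, 0.5, 0, 0))
  g_t <- goal("target", low = 0, target = 4, high = 10)
  expect_equal(desirability_value(4, g_t), 1)   # exactly on target
  expect_equal(desirability_value(c(2, 7), g_t), c(0.5, 0.5))
  expect_equal(desirability_value(c(-1, 11), g_t), c(0, 0))
  # weights bend the ramp but keep the 0/1 anchors
  g_w <- goal("maximize", low = 0, target = 10, weight = 2)
  expect_equal(desirability_value(c(0, 5, 10), g_w), c(0, 0.25, 1))
  expect_error(goal("target", low = 5, target = 1, high = 10), "low <= target")
})

test_that("a concave toy surface is maximised at its vertex", {
  fs <- toy_factors(2)
  des <- make_ccd(fs, n_center = 3, alpha = 1)
  cm <- coded_matrix(des)
  des$response <- -cm[, 1]^2 + 0 * cm[, 2]
  attr(des, "factors") <- fs
  fit <- fit_model(des, "quadratic")
  opt <- optimize_desirability(
    fit, goal("maximize"),
    bounds = cbind(lower = c(-1, 0), upper = c(1, 0)), seed = 3)
  expect_equal(unname(opt$coded[1]), 0, tolerance = 1e-5)
  expect_equal(opt$predicted, 0, tolerance = 1e-8)
})

test_that("optimizer matches a dense grid-search oracle on the yield surface", {
  fit <- study_fit()
  opt <- optimize_desirability(fit, seed = 1)
  expect_gte(opt$predicted, 845.4)
  expect_true(all(abs(opt$coded) <= 2 + 1e-9))
  expect_gte(opt$desirability, 0)
  expect_lte(opt$desirability, 1)

  # exhaustive oracle: 21^4 lattice over the coded region
  ax <- seq(-2, 2, length.out = 21)
  grid <- as.matrix(expand.grid(ax, ax, ax, ax))
  best_grid <- max(predict(fit, grid))
  expect_lte(abs(opt$predicted - best_grid), 1)
  expect_gte(opt$predicted, best_grid - 1e-6)  # optimizer at least as good
})

test_that("optimizer matches 2D grid oracles on every factor-pair slice", {
  fit <- study_fit()
  ax <- seq(-2, 2, length.out = 101)
  pairs <- combn(4, 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    lo <- rep(0, 4); hi <- rep(0, 4)
    lo[c(i, j)] <- -2; hi[c(i, j)] <- 2
    opt <- optimize_desirability(fit, bounds = cbind(lo, hi),
                                 n_starts = 16, seed = 11)
    pts <- matrix(0, nrow = length(ax)^2, ncol = 4)
    pts[, c(i, j)] <- as.matrix(expand.grid(ax, ax))
    best_grid <- max(predict(fit, pts))
    expect_lte(abs(opt$predicted - best_grid), 1)
  }
})

test_that("multi-start optimum never worsens with more starts", {
  fit <- study_fit()
  d_prev <- -Inf
  for (ns in c(2, 8, 32)) {
    opt <- optimize_desirability(fit, n_starts = ns, seed = 5)
    expect_gte(opt$desirability + 1e-12, d_prev)
    d_prev <- opt$desirability
  }
})

test_that("degenerate bounds are rejected", {
  fit <- study_fit()
  b <- cbind(lower = c(1, -2, -2, -2), upper = c(-1, 2, 2, 2))
  expect_error(optimize_desirability(fit, bounds = b), "degenerate")
})

test_that("surface grids agree with pointwise prediction", {
  fit <- study_fit()
  sg <- surface_grid(fit, 1, 2, resolution = 21)
  # centre of the grid sits at the coded origin: the intercept
  expect_equal(sg$z[11, 11], 575.71, tolerance = 1e-5)
  # every cell equals predict() at that point
  for (idx in list(c(1, 1), c(5, 17), c(21, 3))) {
    pt <- c(sg$x[idx[1]], sg$y[idx[2]], 0, 0)
    expect_equal(sg$z[idx[1], idx[2]], predict(fit, pt))
  }
  # fixed levels propagate
  sg2 <- surface_grid(fit, 1, 2, fixed = c(X3 = 2, X4 = 0), resolution = 5)
  expect_equal(sg2$z[3, 3], predict(fit, c(0, 0, 2, 0)))
  expect_error(surface_grid(fit, 2, 2), "different")
})

test_that("a surface with no dependence on the plotted pair is flat", {
  fs <- toy_factors(3)
  des <- make_ccd(fs, n_center = 3)
  cm <- coded_matrix(des)
  des$response <- 5 + 2 * cm[, 3]
  attr(des, "factors") <- fs
  fit <- fit_model(des, "linear")
  sg <- surface_grid(fit, 1, 2, resolution = 7)
  expect_lt(diff(range(sg$z)), 1e-9)
})
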