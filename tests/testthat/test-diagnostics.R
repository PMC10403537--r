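test_that("raw residuals follow the actual-minus-predicted convention", {
  fit <- study_fit()
  d <- residual_diagnostics(fit)
  tab <- d$table
  # run 1 (std 2): actual 356.17, predicted 328.06 -> residual +28.11
  expect_equal(tab$residual[tab$std == 2], 28.11, tolerance = 1e-3)
  # with an intercept, residuals sum to zero
  expect_lt(abs(sum(tab$residual)), 1e-8 * sum(abs(study_data()$response)))
  # leverages sum to the number of coefficients
  expect_equal(sum(tab$leverage), 15, tolerance = 1e-9)
  # the whole residual column matches the published one to print precision
  expect_equal(tab$residual, as.data.frame(study_data())$ref_resid_ccd,
               tolerance = 5e-3)
})

test_that("studentized residuals match their definitions and the LOO oracle", {
  tab <- study_data()
  fit <- study_fit()
  d <- residual_diagnostics(fit)$table
  expect_equal(d$student_internal,
               d$residual / sqrt(fit$mse * (1 - d$leverage)))

  # brute-force oracle: refit without run i and standardize the
  # held-out prediction error by its delete-one predictive variance
  ext <- vapply(seq_len(nrow(tab)), function(i) {
    sub <- tab[-i, ]
    attr(sub, "factors") <- attr(tab, "factors")
    f_i <- fit_model(sub, "quadratic")
    Xloo <- stats::model.matrix(f_i$lm)
    xi <- rsmnet:::build_term_matrix(
      matrix(coded_matrix(tab)[i, ], 1), f_i$spec)
    h_loo <- drop(xi %*% solve(crossprod(Xloo), t(xi)))
    (tab$response[i] - predict(f_i, coded_matrix(tab)[i, ])) /
      sqrt(f_i$mse * (1 + h_loo))
  }, 0)
  expect_equal(d$student_external, ext, tolerance = 1e-8)
})

test_that("normal-probability data use the (i - 3/8)/(n + 1/4) positions", {
  d <- residual_diagnostics(study_fit())
  n <- nrow(d$table)
  expect_equal(d$npp$expected_quantile,
               qnorm((seq_len(n) - 0.375) / (n + 0.25)))
  expect_false(is.unsorted(d$npp$residual))
  expect_setequal(round(d$npp$residual, 10),
                  round(d$table$student_internal, 10))
})

test_that("Box-Cox profile supports no transformation of the yield data", {
  tab <- study_data()
  bc <- box_cox(tab)
  expect_true(bc$ci[1] <= 1 && 1 <= bc$ci[2])
  expect_equal(bc$lambda_hat, bc$lambda[which.max(bc$loglik)])
  # the likelihood-ratio interval reproduces the published one
  expect_equal(bc$ci, c(0.75, 1.67), tolerance = 5e-3)

  # independent reference route: MASS's ML profile on a fresh lm. The
  # package's residual-df profile is an affine transform of it (factor
  # n/df in the log-RSS term), so the scaled difference is constant and
  # the argmax coincides.
  mb <- MASS::boxcox(
    response ~ X1 * X2 + X1 * X3 + X1 * X4 + X2 * X3 + X2 * X4 +
      X3 * X4 + I(X1^2) + I(X2^2) + I(X3^2) + I(X4^2),
    data = as.data.frame(tab), lambda = bc$lambda, plotit = FALSE)
  shift <- (30 / 15) * bc$loglik - mb$y
  expect_lt(diff(range(shift)), 1e-6)
  expect_equal(bc$lambda_hat, mb$x[which.max(mb$y)])
})

test_that("Box-Cox estimate is stable under grid refinement and rescaling", {
  tab <- study_data()
  coarse <- box_cox(tab, lambda = seq(-1, 3, 0.02))
  fine <- box_cox(tab, lambda = seq(-1, 3, 0.002))
  expect_lt(abs(coarse$lambda_hat - fine$lambda_hat), 0.02 + 1e-12)

  scaled <- tab
  scaled$response <- scaled$response * 3.7
  attr(scaled, "factors") <- attr(tab, "factors")
  expect_equal(box_cox(scaled)$lambda_hat, box_cox(tab)$lambda_hat)

  neg <- tab
  neg$response[1] <- -1
  attr(neg, "factors") <- attr(tab, "factors")
  expect_error(box_cox(neg), "positive")
})
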