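test_that("quadratic fit reproduces the reported coded-unit coefficients", {
  fit <- study_fit()
  co <- coef(fit)
  expect_equal(co[["(Intercept)"]], 575.71, tolerance = 1e-4)
  expect_equal(co[["X1"]], 20.00, tolerance = 1e-3)
  expect_equal(co[["X2"]], -39.19, tolerance = 1e-4)
  expect_equal(co[["X3"]], 152.55, tolerance = 1e-4)
  expect_equal(co[["X4"]], 47.37, tolerance = 1e-4)
  expect_equal(co[["X1:X3"]], 43.36, tolerance = 1e-4)
  expect_equal(co[["X2:X4"]], 37.35, tolerance = 1e-3)
  expect_equal(co[["X4^2"]], -74.24, tolerance = 1e-4)
  # the X1^2 estimate: -1.80 (the table's -1.88 disagrees with the data)
  expect_equal(co[["X1^2"]], -1.80, tolerance = 1e-3)
})

test_that("prediction evaluates the fitted polynomial at coded points", {
  fit <- study_fit()
  expect_equal(predict(fit, c(0, 0, 2, 0)), 845.4, tolerance = 1e-5)
  expect_equal(predict(fit, c(0, 0, -2, 0)), 235.19, tolerance = 1e-4)
  expect_equal(predict(fit, c(0, 0, 0, 0)), 575.71, tolerance = 1e-5)
  # matrix input, and agreement with direct polynomial evaluation
  pts <- rbind(c(1, -1, 0.5, 2), c(-2, 0, 0, 1))
  direct <- apply(pts, 1L, eval_quadratic, beta = as.list(coef(fit)))
  expect_equal(predict(fit, pts), direct)
  expect_error(predict(fit, c(0, 0)), "length 4")
})

test_that("ANOVA reproduces the published variance decomposition", {
  fit <- study_fit()
  av <- anova(fit)
  row <- function(s) av[av$source == s, ]

  expect_equal(row("Model")$f_value, 92.17, tolerance = 1e-3)
  expect_lt(row("Model")$p_value, 1e-4)
  expect_equal(row("Model")$estimate, 575.71, tolerance = 1e-4)

  expect_equal(row("X3")$ss, 558500, tolerance = 1e-3)
  expect_equal(row("X3")$f_value, 797.39, tolerance = 1e-3)
  expect_equal(row("X1")$f_value, 13.71, tolerance = 1e-3)
  expect_equal(row("X1^2")$f_value, 0.1268, tolerance = 1e-2)
  expect_equal(row("X1^2")$p_value, 0.7267, tolerance = 1e-3)

  expect_equal(row("Pure error")$ss, 1146.64, tolerance = 1e-3)
  expect_equal(row("Pure error")$df, 5)
  expect_equal(row("Lack of fit")$f_value, 4.08, tolerance = 1e-3)
  expect_equal(row("Lack of fit")$p_value, 0.067, tolerance = 1e-2)
  expect_equal(row("Lack of fit")$df, 10)
})

test_that("ANOVA sums of squares and degrees of freedom are additive", {
  # on the bundled data and on random synthetic datasets
  tabs <- c(list(study_data()), lapply(1:5, function(s) {
    simulate_response(make_ccd(aunps_factors(), n_center = 6),
                      true_model(reported_beta(), noise_sd = 40, seed = s))
  }))
  for (tab in tabs) {
    av <- anova(fit_model(tab, "quadratic"))
    row <- function(s) av[av$source == s, ]
    expect_equal(row("Model")$ss + row("Residual")$ss,
                 row("Corrected total")$ss, tolerance = 1e-9)
    expect_equal(row("Lack of fit")$ss + row("Pure error")$ss,
                 row("Residual")$ss, tolerance = 1e-9)
    expect_equal(row("Model")$df + row("Residual")$df,
                 row("Corrected total")$df)
    expect_equal(row("Lack of fit")$df + row("Pure error")$df,
                 row("Residual")$df)
  }
})

test_that("Type-III term SS match beta^2 * sum(x^2) on orthogonal columns", {
  fit <- study_fit()
  av <- anova(fit)
  co <- coef(fit)
  # linear and interaction columns of a full CCD are orthogonal to the
  # rest of the model, so the partial SS has a closed form
  for (tm in c("X1", "X2", "X3", "X4")) {
    expect_equal(av$ss[av$source == tm], co[[tm]]^2 * 24, tolerance = 1e-9)
  }
  for (tm in c("X1:X2", "X1:X3", "X3:X4")) {
    expect_equal(av$ss[av$source == tm], co[[tm]]^2 * 16, tolerance = 1e-9)
  }
})

test_that("Type-III SS agree with an independent implementation", {
  fit <- study_fit()
  av <- anova(fit)
  ca <- car::Anova(fit$lm, type = 3)
  rn <- gsub("`", "", rownames(ca), fixed = TRUE)
  for (tm in fit$spec$terms) {
    expect_equal(av$ss[av$source == tm],
                 ca[rn == tm, "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("term and model p-values match the F survival function", {
  av <- anova(study_fit())
  keep <- !is.na(av$f_value) & av$source != "Lack of fit"
  # independent route: F survival probability through the beta CDF
  p_beta <- with(av[keep, ],
    pbeta(15 / (15 + df * f_value), 15 / 2, df / 2))
  expect_equal(av$p_value[keep], p_beta, tolerance = 1e-12)
})

test_that("adequacy metrics reproduce the published model summary", {
  ad <- adequacy(study_fit())
  expect_equal(ad$r2, 0.9885, tolerance = 1e-4)
  expect_equal(ad$adj_r2, 0.9778, tolerance = 1e-4)
  expect_equal(ad$pred_r2, 0.9392, tolerance = 1e-4)
  expect_equal(ad$press, 55565.78, tolerance = 1e-3)
  expect_equal(ad$std_dev, 26.47, tolerance = 1e-3)
  expect_equal(ad$adeq_precision, 35.3418, tolerance = 1e-3)
})

test_that("PRESS shortcut equals brute-force leave-one-out refitting", {
  tab <- study_data()
  fit <- study_fit()
  press_loo <- sum(vapply(seq_len(nrow(tab)), function(i) {
    sub <- tab[-i, ]
    attr(sub, "factors") <- attr(tab, "factors")
    f_i <- fit_model(sub, "quadratic")
    (tab$response[i] - predict(f_i, coded_matrix(tab)[i, ]))^2
  }, 0))
  expect_equal(adequacy(fit)$press, press_loo, tolerance = 1e-6)
})

test_that("noiseless data give a perfect fit", {
  sim <- simulate_response(make_ccd(aunps_factors(), n_center = 6),
                           true_model(reported_beta(), noise_sd = 0))
  ad <- adequacy(fit_model(sim, "quadratic"))
  expect_equal(ad$r2, 1, tolerance = 1e-12)
  expect_lt(ad$press, 1e-12)
})

test_that("fit summary reproduces the three-model comparison", {
  fs <- fit_summary(study_data())
  lin <- fs[fs$order == "linear", ]
  tfi <- fs[fs$order == "2fi", ]
  qua <- fs[fs$order == "quadratic", ]

  expect_equal(lin$r2, 0.7206, tolerance = 1e-4)
  expect_equal(lin$pred_r2, 0.5828, tolerance = 1e-3)
  expect_equal(lin$press, 381500, tolerance = 1e-3)
  expect_equal(lin$std_dev, 101.10, tolerance = 1e-3)
  expect_equal(tfi$r2, 0.8207, tolerance = 1e-4)
  expect_equal(tfi$lof_f, 50.69, tolerance = 1e-3)
  expect_equal(qua$press, 55565.78, tolerance = 1e-3)

  # nested models: R2 can only grow with the term set
  expect_true(lin$r2 <= tfi$r2 && tfi$r2 <= qua$r2)
})

test_that("degenerate fits are rejected with informative errors", {
  tab <- study_data()
  # factorial + centre points only: X1^2 and X2^2 columns coincide
  fs <- toy_factors(2)
  df <- data.frame(
    std = 1:7, run = 1:7,
    type = c(rep("factorial", 4), rep("center", 3)),
    X1 = c(-1, 1, -1, 1, 0, 0, 0),
    X2 = c(-1, -1, 1, 1, 0, 0, 0),
    response = c(1, 2, 3, 4, 2.5, 2.4, 2.6))
  dup <- rsmnet:::new_experiment_table(df, fs)
  expect_error(fit_model(dup, "quadratic"), "collinear.*X2\\^2")

  small <- make_ccd(toy_factors(2), n_center = 1)[1:5, ]
  small$response <- rnorm(5)
  attr(small, "factors") <- toy_factors(2)
  expect_error(fit_model(small, "quadratic"), "more runs")

  na_tab <- tab
  na_tab$response[3] <- NA
  attr(na_tab, "factors") <- attr(tab, "factors")
  expect_error(fit_model(na_tab), "missing responses")
})
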