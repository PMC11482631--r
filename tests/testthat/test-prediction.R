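pt <- predictor_table(fx$ingredients)
sid_lys <- row_values(fx$sid, "Lys")
sid_cp <- row_values(fx$sid, "CP")
sid_val <- row_values(fx$sid, "Val")

test_that("pearson_matrix agrees with cor() and flags degenerate columns", {
  vars <- data.frame(NDF = pt$NDF, HT = pt$HT, SID_Lys = sid_lys)
  pm <- pearson_matrix(vars)
  expect_equal(diag(pm$r), c(NDF = 1, HT = 1, SID_Lys = 1))
  expect_equal(pm$r["NDF", "SID_Lys"], cor(pt$NDF, sid_lys), tolerance = 1e-12)
  expect_equal(pm$r["NDF", "SID_Lys"], -0.97, tolerance = 0.005)
  expect_equal(pm$p["NDF", "SID_Lys"],
               cor.test(pt$NDF, sid_lys)$p.value, tolerance = 1e-9)
  expect_equal(pm$stars["NDF", "SID_Lys"], "**")
  # orthogonal pattern -> zero correlation
  z <- pearson_matrix(data.frame(a = c(1, 0, -1, 0), b = c(0, 1, 0, -1)))
  expect_equal(z$r["a", "b"], 0, tolerance = 1e-12)
  # zero-variance column is marked absent, not an error
  cv <- pearson_matrix(data.frame(x = 1:5, const = rep(2, 5)))
  expect_true(is.na(cv$r["x", "const"]))
  expect_error(pearson_matrix(data.frame(x = 1:2, y = 2:1)), ">= 3")
})

test_that("ols_fit reproduces the published single-predictor equations", {
  m <- ols_fit(pt["NDF"], sid_lys, response = "SID_Lys")
  expect_near(m$intercept, 100.107, 0.05)
  expect_near(unname(m$coefficients["NDF"]), -1.229, 0.005)
  expect_near(m$r2, 0.94, 0.005)
  expect_near(m$rsd, 2.88, 0.05)
  expect_lt(m$p_value, 0.01)

  m <- ols_fit(pt["NDF"], sid_cp, response = "SID_CP")
  expect_near(m$intercept, 90.124, 0.05)
  expect_near(unname(m$coefficients["NDF"]), -0.540, 0.005)
  expect_near(m$r2, 0.58, 0.005)
  expect_near(m$rsd, 4.39, 0.05)

  m <- ols_fit(pt["TGS"], sid_val, response = "SID_Val")
  expect_near(unname(m$coefficients["TGS"]), -2.990, 0.005)
  expect_near(m$r2, 0.57, 0.005)
  expect_near(m$rsd, 4.69, 0.05)

  m <- ols_fit(pt["HT"], sid_lys, response = "SID_Lys")
  expect_near(unname(m$coefficients["HT"]), -0.234, 0.005)
  expect_near(m$rsd, 8.04, 0.05)
  expect_near(m$adj_r2, 0.51, 0.005)  # the published 0.51 is adjusted
})

test_that("ols_fit basics: exact fit, degenerate inputs, collinearity", {
  x <- data.frame(x = 1:10)
  m <- ols_fit(x, 2 * (1:10) + 1)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(m$r2, 1)
  expect_equal(m$rsd, 0, tolerance = 1e-10)
  expect_error(ols_fit(data.frame(a = 1:10, b = 2 * (1:10)), rnorm(10)),
               "collinearity.*b")
  expect_error(ols_fit(data.frame(a = 1:3, b = c(1, 5, 2)), rnorm(3)), "n >")
})

test_that("stepwise selection enters NDF first for lysine SID", {
  m <- stepwise_select(pt, sid_lys, response = "SID_Lys")
  expect_equal(m$predictors[1], "NDF")
  # NDF has the largest |r| among all candidates (exhaustive check)
  rs <- vapply(pt, function(v) abs(cor(v, sid_lys)), numeric(1))
  expect_equal(names(which.max(rs)), "NDF")
})

test_that("stepwise handles no-entry and planted-signal cases", {
  # Walsh-pattern candidates exactly orthogonal to the response: nothing enters
  xw <- data.frame(x1 = rep(c(1, 1, -1, -1), 2), x2 = rep(c(1, -1, -1, 1), 2),
                   x3 = rep(c(1, -1), each = 4))
  m0 <- stepwise_select(xw, rep(c(1, -1), 4) + 5)
  expect_length(m0$predictors, 0)
  expect_equal(m0$intercept, 5)

  set.seed(23)
  x <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  y <- 3 - 2 * x$x1 + rnorm(30, sd = 0.1)
  m <- stepwise_select(x, y)
  expect_equal(m$predictors, "x1")
  expect_equal(unname(m$coefficients["x1"]), -2, tolerance = 0.1)
  expect_error(stepwise_select(x, y, p_enter = 0.1, p_remove = 0.05),
               "configuration")
})

test_that("single-predictor stepwise coincides with ols_fit", {
  direct <- ols_fit(pt["NDF"], sid_lys)
  step <- stepwise_select(pt["NDF"], sid_lys)
  expect_equal(step$intercept, direct$intercept, tolerance = 1e-12)
  expect_equal(step$coefficients, direct$coefficients, tolerance = 1e-12)
  expect_equal(step$r2, direct$r2, tolerance = 1e-12)
  expect_equal(step$rsd, direct$rsd, tolerance = 1e-12)
})

test_that("model algebra: r, centroid, self-prediction", {
  m <- ols_fit(pt["NDF"], sid_lys, response = "SID_Lys")
  # r2 equals the squared correlation
  expect_equal(m$r2, cor(pt$NDF, sid_lys)^2, tolerance = 1e-12)
  # fitted line passes through the centroid
  expect_equal(predict_from_model(m, c(NDF = mean(pt$NDF))), mean(sid_lys),
               tolerance = 1e-9)
  expect_equal(predict_from_model(m, c(NDF = 30.188)), 63.01, tolerance = 0.05)
  # refit on own predictions: perfect fit
  preds <- predict(m, data.frame(NDF = pt$NDF))
  m2 <- ols_fit(pt["NDF"], preds)
  expect_equal(m2$r2, 1)
  expect_equal(m2$rsd, 0, tolerance = 1e-9)
})

test_that("predict_from_model: read-offs, intercept-only, missing keys", {
  m_cp <- ols_fit(pt["NDF"], sid_cp, response = "SID_CP")
  expect_equal(predict_from_model(m_cp, c(NDF = 0)), 90.124, tolerance = 0.05)
  m0 <- stepwise_select(data.frame(x = rep(c(1, 2), 5)),
                        rep(5, 10) + rnorm(10, 0, 1e-8))
  expect_length(m0$predictors, 0)
  expect_equal(predict_from_model(m0, list()), m0$intercept)
  m <- ols_fit(pt[c("NDF", "TGS")], sid_lys)
  expect_error(predict_from_model(m, c(NDF = 30)), "TGS")
  expect_equal(equation_text(m_cp), "SID_CP = 90.125 - 0.540*NDF")
})

test_that("slope recovery over repeated synthetic regressions is unbiased", {
  set.seed(31)
  n_rep <- 200
  slopes <- replicate(n_rep, {
    y <- 100 - 1.2 * pt$NDF + rnorm(10, sd = 3)
    unname(coef(lm(y ~ pt$NDF))[2])
  })
  mc_se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) + 1.2), 2 * mc_se)
})
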