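test_that("ICC arithmetic identities hold exactly", {
  expect_equal(within_person_share(0.5), 50)
  u <- fit_unconditional(small_days, "stress")
  expect_equal(u$icc, u$tau0^2 / (u$tau0^2 + u$sigma^2))
  expect_equal(u$within_share, 100 * (1 - u$icc))
  expect_error(within_person_share(1.2))
})

test_that("unconditional model recovers a known variance split", {
  set.seed(31)
  n <- 198L; nd <- 12L
  tau0 <- sqrt(0.366); sigma <- sqrt(0.392)  # generating ICC 0.4828
  y <- rep(rnorm(n, 0, tau0), each = nd) + rnorm(n * nd, 2.4, sigma)
  d <- data.frame(pid = rep(sprintf("p%03d", 1:n), each = nd),
                  stress_daily = y)
  u <- fit_unconditional(d, "stress")
  expect_lt(abs(u$icc - tau0^2 / (tau0^2 + sigma^2)), 0.05)
  expect_error(fit_unconditional(data.frame(pid = "a", stress_daily = 1:3)),
               "2 participants")
})

test_that("the fixed part is invariant to the ilr rotation", {
  f1 <- fit_hypothesis_model(small_days, "stress", "H1", random_slope = "none")
  f4 <- fit_hypothesis_model(small_days, "stress", "H4", random_slope = "none")
  expect_equal(f1$loglik, f4$loglik, tolerance = 1e-6)
  expect_all_close(fitted(f1$fit), fitted(f4$fit), 1e-8)
  # covariate estimates agree; composition coordinates differ by rotation
  co1 <- f1$coefficients; co4 <- f4$coefficients
  for (term in c("age", "bmi", "sexmale", "cse_cov")) {
    expect_equal(co1$estimate[co1$term == term],
                 co4$estimate[co4$term == term], tolerance = 1e-6)
  }
})

test_that("null composition effects are estimated near zero", {
  params <- h4_stress_params()
  params$gamma[c("ilr1", "ilr2", "ilr3")] <- 0
  for (s in 1:3) {
    d <- simulate_model_data(n_participants = 80L, n_days = 8L,
                             params = params, seed = 400 + s)
    f <- fit_hypothesis_model(d, "stress", "H4", random_slope = "none")
    co <- f$coefficients
    ilr_rows <- grepl("^ilr", co$term)
    expect_true(all(abs(co$estimate[ilr_rows]) < 4 * co$se[ilr_rows]))
  }
})

test_that("fixed-effect inference uses the residual-df convention", {
  f <- fit_hypothesis_model(small_days, "cse", "H2", random_slope = "none")
  co <- f$coefficients
  expect_true(all(co$df == f$n_obs - nrow(co)))
  expect_equal(co$t, co$estimate / co$se)
  expect_equal(co$p, 2 * pt(-abs(co$t), co$df))
  # standardized beta convention: B * SD(x) / SD(y)
  X <- model.matrix(f$fit)
  k <- which(co$term == "ilr3_c")
  expect_equal(co$std_beta[k],
               co$estimate[k] * sd(X[, "ilr3_c"]) / sd(f$data$y))
  expect_true(is.na(co$std_beta[co$term == "(Intercept)"]))
  expect_identical(standardize_coefficients(f)$std_beta, co$std_beta)
})

test_that("random-slope selection respects its boundary cases", {
  sel <- select_random_slope(small_days, "stress", "H1",
                             candidates = character(0))
  expect_identical(sel$slope, "none")
  expect_equal(nrow(sel$tests), 0L)
})

test_that("slope selection has level under the null and power under a slope", {
  # null: no generated slope; retention should be rare
  null_params <- h4_stress_params()
  retained_null <- 0L
  for (s in 1:25) {
    d <- simulate_model_data(n_participants = 40L, n_days = 6L,
                             params = null_params, seed = 600 + s)
    sel <- select_random_slope(d, "stress", "H4",
                               candidates = c("ilr3"))
    retained_null <- retained_null + (sel$slope != "none")
  }
  expect_lte(retained_null / 25, 0.16)
  # a substantial generated slope on ilr3 should usually be retained
  slope_params <- h4_stress_params()
  slope_params$tau1 <- 0.3
  slope_params$slope_coord <- "ilr3"
  # many days per participant make the slope variance identifiable
  retained <- 0L
  for (s in 1:15) {
    d <- simulate_model_data(n_participants = 80L, n_days = 30L,
                             params = slope_params, seed = 700 + s)
    sel <- select_random_slope(d, "stress", "H4",
                               candidates = c("ilr1", "ilr2", "ilr3"))
    retained <- retained + (sel$slope == "ilr3")
  }
  expect_gt(retained / 15, 0.5)
})

test_that("diagnostics flag perfect collinearity and report sane VIFs", {
  f <- fit_hypothesis_model(small_days, "stress", "H1", random_slope = "none")
  dg <- model_diagnostics(f)
  expect_true(all(is.finite(dg$vif)))
  expect_true(all(dg$vif >= 1))
  expect_false(dg$collinearity_flag)
  expect_equal(nrow(dg$qq), f$n_obs)
  # duplicated predictor
  d2 <- small_days
  d2$age2 <- d2$age
  f2 <- suppressWarnings(suppressMessages(
    fit_hypothesis_model(d2, "stress", "H1", random_slope = "none",
                         extra = "age2")))
  dg2 <- model_diagnostics(f2)
  expect_true(dg2$collinearity_flag)
  expect_true(any(!is.finite(dg2$vif)))
})

test_that("residual normality flagging is calibrated on Gaussian data", {
  flags <- 0L
  for (s in 1:20) {
    d <- simulate_model_data(n_participants = 30L, n_days = 5L,
                             seed = 800 + s)
    f <- fit_hypothesis_model(d, "stress", "H4", random_slope = "none")
    flags <- flags + model_diagnostics(f)$normality_flag
  }
  expect_lte(flags, 5L)
})
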