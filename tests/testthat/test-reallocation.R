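# Independent scalar evaluation of the pivot coordinates for the delta
# oracle: explicit formulas, not the package's basis machinery.
hand_ilr_h4 <- function(x) {
  c(sqrt(3 / 4) * log(x["mvpa"] / (x["lpa"] * x["sleep"] * x["sb"])^(1 / 3)),
    sqrt(2 / 3) * log(x["lpa"] / sqrt(x["sleep"] * x["sb"])),
    sqrt(1 / 2) * log(x["sleep"] / x["sb"]))
}

mean_day_base <- c(sleep = 490, sb = 649, lpa = 227, mvpa = 74)

test_that("reallocate moves minutes and preserves the day total", {
  out <- reallocate(mean_day_base, from = "sb", to = "sleep", minutes = 60)
  expect_equal(unname(out), c(550, 589, 227, 74))
  expect_equal(sum(out), sum(mean_day_base))
  expect_equal(reallocate(mean_day_base, "sb", "mvpa", 0), mean_day_base)
  expect_error(reallocate(mean_day_base, "sb", "mvpa", 700), "available")
  expect_error(reallocate(mean_day_base, "sb", "sb", 10), "differ")
  expect_error(reallocate(mean_day_base, "sb", "mvpa", -5), "non-negative")
})

test_that("predicted delta equals the hand-computed ilr contrast", {
  # reference fixed effects of the sleep-vs-SB stress model
  gamma <- c(ilr1 = 0.03, ilr2 = 0.00, ilr3 = -0.10)
  fake <- structure(list(
    coefficients = data.frame(term = c("(Intercept)", "ilr1_c", "ilr2_c",
                                       "ilr3_c"),
                              estimate = c(2.26, gamma)),
    ordering = "H4", outcome = "stress"), class = "hypothesis_fit")
  for (mins in c(0, 20, 40, 60)) {
    new <- reallocate(mean_day_base, "sb", "sleep", mins)
    oracle <- sum(gamma * (hand_ilr_h4(new) - hand_ilr_h4(mean_day_base)))
    expect_equal(predict_delta(fake, mean_day_base, "sb", "sleep", mins),
                 oracle, tolerance = 1e-12)
  }
  # zero composition effects give zero delta for any move
  fake0 <- fake
  fake0$coefficients$estimate[-1] <- 0
  expect_identical(predict_delta(fake0, mean_day_base, "sb", "lpa", 40), 0)
})

test_that("delta is antisymmetric and reallocations stay closed", {
  f <- fit_hypothesis_model(small_days, "stress", "H1", random_slope = "none")
  for (pair in list(c("sb", "sleep"), c("sb", "mvpa"), c("lpa", "sb"))) {
    for (mins in c(20, 60)) {
      fwd <- predict_delta(f, mean_day_base, pair[1], pair[2], mins)
      moved <- reallocate(mean_day_base, pair[1], pair[2], mins)
      expect_equal(sum(moved), 1440)
      back <- predict_delta(f, moved, pair[2], pair[1], mins)
      expect_equal(fwd, -back, tolerance = 1e-12)
    }
  }
})

test_that("reallocation grid uses the mean day and includes the zero point", {
  f <- fit_hypothesis_model(small_days, "cse", "H1", random_slope = "none")
  grid <- reallocation_grid(f)
  expect_setequal(unique(grid$minutes), c(0, 20, 40, 60))
  expect_true(all(grid$delta[grid$minutes == 0] == 0))
  expect_equal(nrow(grid), 12L)
  expect_true(all(grid$outcome == "cse"))
})

test_that("bootstrap confidence intervals are deterministic under the seed", {
  run <- function() {
    bootstrap_delta_ci(small_days, outcome = "stress", ordering = "H1",
                       random_slope = "none",
                       pairs = data.frame(from = "sb", to = "sleep"),
                       minutes = c(0, 60), n_boot = 25L, seed = 5L)
  }
  a <- run(); b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
  zero <- a[a$minutes == 0, ]
  expect_identical(unname(unlist(zero[c("delta", "ci_low", "ci_high")])),
                   c(0, 0, 0))
  expect_true(all(a$ci_low <= a$delta & a$delta <= a$ci_high))
})
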