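make_days <- function(wear, walking, sleep) {
  data.frame(pid = sprintf("p%d", seq_along(wear)),
             day_index = rep(1L, length(wear)),
             wear_hours = wear, walking_bouts = walking, sleep_min = sleep)
}

test_that("valid-day rules apply at their exact boundaries", {
  d <- flag_valid_days(make_days(c(19.9, 23.8, 20.0, 24.0),
                                 c(5L, 0L, 1L, 3L),
                                 c(480, 480, 1, 0)))
  expect_identical(d$valid, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(flag_valid_days(data.frame(wear_hours = 20)), "lacks columns")
})

test_that("participants need at least three valid days", {
  d <- data.frame(pid = rep(c("a", "b", "c"), times = c(4, 3, 4)),
                  day_index = c(1:4, 1:3, 1:4),
                  wear_hours = c(23, 23, 23, 15, 23, 23, 23, 23, 23, 15, 15),
                  walking_bouts = 2L, sleep_min = 400)
  d <- flag_valid_days(d)
  fp <- filter_participants(d)
  expect_setequal(unique(fp$days$pid), c("a", "b"))  # c has 2 valid days
  expect_identical(fp$excluded_pids, "c")
  empty <- filter_participants(flag_valid_days(make_days(numeric(0),
                                                         integer(0),
                                                         numeric(0))))
  expect_equal(nrow(empty$days), 0L)
})

test_that("daily aggregation takes arithmetic means and drops rating-free days", {
  days <- data.frame(pid = c("a", "a", "b"), day_index = c(1L, 2L, 1L))
  prompts <- data.frame(pid = c("a", "a", "a"), day_index = c(1L, 1L, 1L),
                        stress = c(2, 3, 4), cse = c(5, NA, 3))
  agg <- aggregate_daily_ratings(prompts, days)
  expect_equal(nrow(agg$days), 1L)
  expect_equal(agg$days$stress_daily, 3)
  expect_equal(agg$days$cse_daily, 4)
  expect_equal(agg$days$n_ratings, 3L)
  expect_equal(agg$n_rating_free, 2L)
  expect_setequal(agg$dropped_pids, "b")
  bad <- data.frame(pid = "a", day_index = 1L, stress = 6, cse = 3)
  expect_error(aggregate_daily_ratings(bad, days), "1-5")
})

test_that("screening is idempotent and monotone in the wear threshold", {
  co <- small_cohort
  once <- screen_cohort(co$days, co$prompts)
  twice <- screen_cohort(once$days, co$prompts)
  expect_equal(twice$days$stress_daily, once$days$stress_daily)
  expect_equal(nrow(twice$days), nrow(once$days))
  # relaxing the wear rule can only add days
  relaxed <- co$days
  relaxed$wear_hours <- pmax(relaxed$wear_hours, 20)
  more <- screen_cohort(relaxed, co$prompts)
  expect_gte(nrow(more$days), nrow(once$days))
})

test_that("every input day lands in exactly one screening bucket", {
  cfg <- generator_config(n_participants = 60L, n_days = 5L,
                          shortwear_rate = 0.3, compliance = 0.75,
                          seed = 17L)
  co <- simulate_cohort(cfg)
  scr <- screen_cohort(co$days, co$prompts)
  r <- scr$report
  expect_identical(r$n_days_input,
                   r$n_days_excluded_participants + r$n_days_wear_invalid +
                     r$n_days_rating_free + r$n_days_retained)
  # the injected rates exercise every rule
  expect_gt(r$n_days_wear_invalid, 0L)
  expect_gt(r$n_days_rating_free, 0L)
  expect_gt(r$n_participants_excluded_wear, 0L)
  expect_identical(r$n_participants_retained,
                   length(unique(scr$days$pid)))
})
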