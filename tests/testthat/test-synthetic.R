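test_that("generation is deterministic and stable under cohort extension", {
  cfg <- generator_config(n_participants = 12L, n_days = 5L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$days, b$days)
  expect_identical(a$prompts, b$prompts)
  # adding participants does not perturb earlier ones
  big <- generate_participants(generator_config(n_participants = 24L,
                                                n_days = 5L, seed = 99L))
  expect_identical(a$participants, big[1:12, ])
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(n_participants = 0), "positive count")
  expect_error(generator_config(compliance = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(sigma_within = matrix(c(1, 2, 2, 1, 1, 1, 1, 1, 1), 3)),
               "semi-definite")
})

test_that("participant covariates match their generating distributions", {
  cfg <- generator_config(n_participants = 5000L, seed = 7L)
  p <- generate_participants(cfg)
  expect_equal(nrow(p), 5000L)
  expect_false(any(duplicated(p$pid)))
  expect_true(all(p$age >= 20 & p$age <= 65))
  expect_true(all(p$bmi >= 17.9 & p$bmi <= 35.3))
  # Monte-Carlo checks against the generating (truncated-normal) targets
  expect_lt(abs(mean(p$age) - 35.87), 3 * 10.76 / sqrt(5000))
  expect_lt(abs(mean(p$bmi) - 23.99), 3 * 3.28 / sqrt(5000))
  expect_lt(abs(mean(p$sex == "female") - 0.548), 3 * 0.5 / sqrt(5000))
})

test_that("zero-variance configuration reproduces the mean day exactly", {
  cfg <- generator_config(n_participants = 4L, n_days = 3L,
                          sigma_between = matrix(0, 3, 3),
                          sigma_within = matrix(0, 3, 3),
                          zero_rate = 0, seed = 3L)
  days <- generate_day_compositions(generate_participants(cfg), cfg)
  target <- ilr_inverse(cfg$mean_ilr, "H1", total = 1440)
  m <- as.matrix(days[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])
  expect_all_close(m, matrix(target, nrow(m), 4, byrow = TRUE), 1e-9)
})

test_that("every generated day is closed to 1440 minutes", {
  days <- small_cohort$days
  tot <- days$sleep_min + days$sb_min + days$lpa_min + days$mvpa_min
  expect_all_close(tot, rep(1440, length(tot)), 1e-6)
})

test_that("default cohort hits the emulated descriptive targets", {
  co <- default_cohort()
  comp <- co$days[!co$days$mvpa_zero,
                  c("sleep_min", "sb_min", "lpa_min", "mvpa_min")]
  names(comp) <- behavior_parts
  gm <- geometric_mean_composition(comp) / 60
  expect_all_close(gm, c(8.1, 10.8, 3.8, 1.2), 0.3)
  # ~4.4 answered prompts per day with at least one rating
  per_day <- table(paste(co$prompts$pid, co$prompts$day_index))
  expect_lt(abs(mean(per_day) - 4.4), 0.5)
  # below-detection MVPA days are rare (a handful per cohort) and keep
  # closure because the minutes land in SB
  nz <- sum(co$days$mvpa_zero)
  expect_lte(nz, 12)
  if (nz > 0) {
    expect_all_close(with(co$days[co$days$mvpa_zero, ],
                          sleep_min + sb_min + lpa_min + mvpa_min),
                     rep(1440, nz), 1e-6)
  }
})

test_that("noiseless prompts reproduce the rounded daily latent", {
  cfg <- generator_config(n_participants = 6L, n_days = 4L,
                          prompt_noise_sd = 0, compliance = 1, seed = 21L)
  co <- simulate_cohort(cfg)
  key <- paste(co$days$pid, co$days$day_index)
  lat <- setNames(co$days$latent_stress, key)
  expected <- pmin(5, pmax(1, round(lat[paste(co$prompts$pid,
                                              co$prompts$day_index)])))
  expect_equal(co$prompts$stress, unname(expected))
})

test_that("zero compliance yields an empty screen", {
  cfg <- generator_config(n_participants = 5L, n_days = 4L,
                          compliance = 0, seed = 13L)
  co <- simulate_cohort(cfg)
  expect_true(is.null(co$prompts) || nrow(co$prompts) == 0L)
  prompts <- data.frame(pid = character(0), day_index = integer(0),
                        stress = numeric(0), cse = numeric(0))
  scr <- screen_cohort(co$days, prompts)
  expect_equal(nrow(scr$days), 0L)
  expect_equal(scr$report$n_participants_retained, 0L)
})

test_that("cohort CSV round trip preserves the tables", {
  dir <- withr::local_tempdir()
  write_cohort_csv(small_cohort, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$participants$age, small_cohort$participants$age)
  expect_equal(back$days$sleep_min, small_cohort$days$sleep_min)
  expect_false("latent_stress" %in% names(back$days))
  expect_equal(nrow(back$prompts), nrow(small_cohort$prompts))
})
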