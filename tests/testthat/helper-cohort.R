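# Shared fixtures, built in code once per test run.

# Small cohort for fast structural tests.
small_cfg <- generator_config(n_participants = 40L, n_days = 10L, seed = 42L)
small_cohort <- simulate_cohort(small_cfg)
small_days <- local({
  scr <- screen_cohort(small_cohort$days, small_cohort$prompts)
  prepare_analysis_days(scr$days, small_cohort$participants)
})

# Full-size cohort at the generator defaults (lazy: built on first use).
.default_cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.default_cohort_cache$co)) {
    .default_cohort_cache$co <- simulate_cohort(generator_config(seed = 7L))
  }
  .default_cohort_cache$co
}

# Random strictly-positive compositions closed to 1440, seeded.
random_compositions <- function(n, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * 3, 0, 1.2), n, 3)
  ilr_inverse(z, "H1")
}

expect_all_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
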