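#' Reference generating values for the sleep-vs-SB stress model
#'
#' Fixed effects, random-intercept SD and residual SD of the daily stress
#' model under rotation `H4` (whose third coordinate is the sleep-to-SB
#' balance), as estimated in the emulated study. Used as the default
#' generating truth for parameter-recovery simulations.
#'
#' @return List with `gamma` (named fixed effects), `tau0`, `tau1`,
#'   `rho01`, `slope_coord`, `sigma`.
#' @export
h4_stress_params <- function() {
  list(gamma = c(intercept = 2.26, sex = -0.10, age = -0.01, bmi = 0.02,
                 cse = -0.57, ilr1 = 0.03, ilr2 = 0.00, ilr3 = -0.10),
       tau0 = 0.61, tau1 = 0, rho01 = 0, slope_coord = "none", sigma = 0.55)
}

#' Simulate daily-level data from a known two-level compositional model
#'
#' Direct simulation at the participant-day level for parameter recovery:
#' participant covariates and realistic ilr variability come from the
#' cohort generator's defaults, the coping self-efficacy covariate from its
#' own two-level model (no measurement noise), and the outcome from exactly
#' the model equation that [fit_hypothesis_model()] estimates - fixed
#' covariate effects, fixed effects on the within-person-centered ilr
#' coordinates of `ordering`, a random intercept (optional slope) and a
#' Gaussian residual. Because the generating ilr deviations are centered at
#' the observed person means, refitting recovers the generating values
#' without centering-induced attenuation.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param ordering Rotation whose coordinates carry the generating ilr
#'   effects.
#' @param params Generating truth, see [h4_stress_params()].
#' @param cse_params Two-level model for the coping self-efficacy
#'   covariate: `gamma` (`intercept`, `sex`, `age`, `bmi`), `tau0`,
#'   `sigma`.
#' @param sigma_between,sigma_within ilr covariances (reference rotation);
#'   defaults from [generator_config()].
#' @param seed Seed.
#' @return Analysis-ready day table (minutes, covariates, `stress_daily`,
#'   `cse_daily`).
#' @export
simulate_model_data <- function(n_participants = 198L, n_days = 12L,
                                ordering = "H4",
                                params = h4_stress_params(),
                                cse_params = list(
                                  gamma = c(intercept = 3.36, sex = 0.14,
                                            age = 0.01, bmi = -0.01),
                                  tau0 = 0.67, sigma = 0.56),
                                sigma_between = NULL, sigma_within = NULL,
                                seed = 1L) {
  cfg <- generator_config(n_participants = n_participants, n_days = n_days,
                          seed = seed)
  if (is.null(sigma_between)) sigma_between <- cfg$sigma_between
  if (is.null(sigma_within)) sigma_within <- cfg$sigma_within
  participants <- generate_participants(cfg)
  set.seed(seed + 1L)
  Sb <- .mvn_sqrt(sigma_between)
  Sw <- .mvn_sqrt(sigma_within)
  n_tot <- n_participants * n_days
  pid <- rep(participants$pid, each = n_days)
  mu <- matrix(stats::rnorm(n_participants * 3L), n_participants, 3L) %*% t(Sb)
  mu <- sweep(mu, 2L, cfg$mean_ilr, "+")
  z <- mu[rep(seq_len(n_participants), each = n_days), , drop = FALSE] +
    matrix(stats::rnorm(n_tot * 3L), n_tot, 3L) %*% t(Sw)
  comp <- ilr_inverse(z, "H1", total = 1440)

  male <- as.numeric(participants$sex == "male")[rep(seq_len(n_participants),
                                                     each = n_days)]
  age <- rep(participants$age, each = n_days)
  bmi <- rep(participants$bmi, each = n_days)

  gc_ <- cse_params$gamma
  u0c <- rep(stats::rnorm(n_participants, 0, cse_params$tau0), each = n_days)
  cse <- gc_[["intercept"]] + gc_[["sex"]] * male + gc_[["age"]] * age +
    gc_[["bmi"]] * bmi + u0c + stats::rnorm(n_tot, 0, cse_params$sigma)

  zo <- ilr_transform(comp, ordering)
  dev <- apply(unclass(zo)[, 1:3, drop = FALSE], 2,
               function(v) v - stats::ave(v, pid))
  g <- params$gamma
  u <- .mvn_sqrt(matrix(c(params$tau0^2,
                          params$rho01 * params$tau0 * params$tau1,
                          params$rho01 * params$tau0 * params$tau1,
                          params$tau1^2), 2, 2)) %*%
    matrix(stats::rnorm(2L * n_participants), 2L)
  u0 <- rep(u[1L, ], each = n_days)
  slope_term <- if (params$slope_coord == "none") 0 else
    rep(u[2L, ], each = n_days) * dev[, params$slope_coord]
  y <- g[["intercept"]] + g[["sex"]] * male + g[["age"]] * age +
    g[["bmi"]] * bmi + g[["cse"]] * (cse - mean(cse)) +
    dev %*% g[c("ilr1", "ilr2", "ilr3")] + u0 + slope_term +
    stats::rnorm(n_tot, 0, params$sigma)

  data.frame(pid = pid, day_index = rep(seq_len(n_days), n_participants),
             sleep_min = comp[, "sleep"], sb_min = comp[, "sb"],
             lpa_min = comp[, "lpa"], mvpa_min = comp[, "mvpa"],
             sex = participants$sex[rep(seq_len(n_participants),
                                        each = n_days)],
             age = age, bmi = bmi,
             cse_daily = cse, stress_daily = as.numeric(y),
             stringsAsFactors = FALSE)
}

#' Parameter-recovery simulation for the hypothesis models
#'
#' Repeatedly simulates cohorts from a known generating truth with
#' [simulate_model_data()], refits the corresponding hypothesis model with
#' [fit_hypothesis_model()], and summarises the estimates against the
#' generating values with Monte-Carlo standard errors.
#'
#' @inheritParams simulate_model_data
#' @param n_rep Number of replicates.
#' @param seed Master seed; one sub-seed per replicate is derived from it.
#' @return Object of class `recovery_summary`: `estimates` (one row per
#'   replicate) and `summary` (per parameter: generating value, mean
#'   estimate, Monte-Carlo SE of the mean, and `z = (mean - generating) /
#'   mc_se`).
#' @export
recover_parameters <- function(n_rep = 100L, n_participants = 198L,
                               n_days = 12L, ordering = "H4",
                               params = h4_stress_params(), seed = 1L) {
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_rep)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_model_data(n_participants = n_participants,
                             n_days = n_days, ordering = ordering,
                             params = params, seed = rep_seeds[r])
    f <- fit_hypothesis_model(d, outcome = "stress", ordering = ordering,
                              random_slope = if (params$slope_coord == "none")
                                "none" else params$slope_coord)
    co <- f$coefficients
    est <- stats::setNames(co$estimate, co$term)
    rows[[r]] <- data.frame(
      rep = r,
      intercept = est[["(Intercept)"]], sex = est[["sexmale"]],
      age = est[["age"]], bmi = est[["bmi"]], cse = est[["cse_cov"]],
      ilr1 = est[["ilr1_c"]], ilr2 = est[["ilr2_c"]], ilr3 = est[["ilr3_c"]],
      tau0 = f$random$sd_intercept, sigma = f$random$sigma)
  }
  est <- do.call(rbind, rows)
  gen <- c(params$gamma[c("intercept", "sex", "age", "bmi", "cse",
                          "ilr1", "ilr2", "ilr3")],
           tau0 = params$tau0, sigma = params$sigma)
  pars <- names(gen)
  summ <- data.frame(
    parameter = pars,
    generating = as.numeric(gen),
    mean_estimate = vapply(pars, function(p) mean(est[[p]]), numeric(1)),
    mc_se = vapply(pars, function(p) stats::sd(est[[p]]) / sqrt(n_rep),
                   numeric(1)),
    row.names = NULL)
  summ$z <- (summ$mean_estimate - summ$generating) / summ$mc_se
  out <- list(estimates = est, summary = summ, n_rep = n_rep,
              n_participants = n_participants, n_days = n_days,
              ordering = ordering)
  class(out) <- "recovery_summary"
  out
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replicates of %d participants x %d days (rotation %s)\n",
              x$n_rep, x$n_participants, x$n_days, x$ordering))
  s <- x$summary
  s[, -1] <- lapply(s[, -1], function(v) round(v, 4))
  print(s, row.names = FALSE)
  invisible(x)
}
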