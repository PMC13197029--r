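# Parent parameters of the truncated normals used for participant covariates.
# Chosen so the *realized* (truncated) draws reproduce the target descriptive
# mean/SD within the observed range: age mean 35.87, SD 10.76 on [20, 65];
# BMI mean 23.99, SD 3.28 on [17.9, 35.3].
.age_parent <- c(mu = 25.7025, sigma = 18.1045, lo = 20, hi = 65)
.bmi_parent <- c(mu = 23.4534, sigma = 3.7723, lo = 17.9, hi = 35.3)
.p_female <- 0.548

# Covariate means used when the generator needs a deterministic reference
# point (the coping self-efficacy anchor in the stress equation).
.cov_means <- c(age = 35.87, bmi = 23.99, male = 1 - .p_female)

#' Configuration for the synthetic ambulatory-assessment cohort
#'
#' Bundles every parameter of the generator. The defaults emulate the study
#' conditions of a 15-working-day ambulatory assessment of ~198 university
#' employees: the geometric-mean day (8.1 h sleep, 10.8 h SB, 3.8 h LPA,
#' 1.2 h MVPA), person-level spread of each behavior, daily outcome models on
#' the 1-5 Likert scale, prompt compliance (~4.4 surveys/day), and the
#' imperfections the screening stage must handle (short-wear days, days
#' without detected walking, below-detection MVPA zeros).
#'
#' Compositions are generated on the ilr scale (logistic-normal): each
#' participant draws a person-mean coordinate vector from
#' `MVN(mean_ilr, sigma_between)` and each day adds `MVN(0, sigma_within)`
#' noise, so the between/within variance partition is exact by construction
#' and the population geometric-mean day equals `ilr_inverse(mean_ilr)`.
#' All coordinate-scale parameters refer to the reference rotation `H1`.
#'
#' @param n_participants,n_days Cohort size and scheduled days per person.
#' @param geometric_mean_day Target geometric-mean day, minutes (canonical
#'   part names). Defines `mean_ilr` when that is `NULL`.
#' @param mean_ilr Population mean ilr coordinates (H1 rotation); computed
#'   from `geometric_mean_day` by default.
#' @param between_cv Person-level coefficient of variation of each behavior;
#'   the between-person ilr covariance defaults to the projection
#'   `t(V) diag(cv^2) V` of independent log-part variances onto the pivot
#'   basis, which reproduces the person-aggregated hour SDs of the emulated
#'   study.
#' @param sigma_between,sigma_within 3x3 ilr covariance matrices (H1
#'   rotation) of person means and of daily deviations.
#' @param outcome_params Per-outcome generating models (`stress`, `cse`):
#'   `gamma` (named fixed effects: `intercept`, `sex` (male vs female),
#'   `age`, `bmi`, for stress `cse`, and `ilr1..ilr3` applied to
#'   within-person deviations), `tau0`/`tau1` random intercept/slope SDs,
#'   `rho01` their correlation, `slope_coord`, and residual SD `sigma`.
#' @param rho_between_outcomes Correlation of the two outcomes' random
#'   intercepts; calibrated so the unconditional between-person stress
#'   variance matches the emulated study despite the strong daily coupling
#'   of stress to coping self-efficacy.
#' @param prompt_rate Mean of the Poisson prompt count, capped at 6/day.
#' @param compliance Probability that a day has any ratings at all.
#' @param prompt_noise_sd SD of prompt-level measurement noise around the
#'   daily latent outcome, before rounding to the 1-5 grid.
#' @param zero_rate Probability that a day's MVPA is recorded as 0 (detection
#'   failure; the minutes are absorbed into SB).
#' @param shortwear_rate Probability of a day with < 20 h wear.
#' @param nowalk_rate Probability of a day without any detected walking.
#' @param sleep_quality_missing,exercised_missing Missingness rates of the
#'   morning sleep-quality item and the evening exercise item.
#' @param seed Master seed. One stream per participant and stage is derived
#'   from it, so enlarging the cohort does not perturb earlier participants.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 198L,
                             n_days = 15L,
                             geometric_mean_day = c(sleep = 486, sb = 648,
                                                    lpa = 228, mvpa = 72),
                             mean_ilr = NULL,
                             between_cv = c(sleep = 0.151, sb = 0.113,
                                            lpa = 0.272, mvpa = 0.333),
                             sigma_between = NULL,
                             sigma_within = diag(c(0.23, 0.34, 0.32)^2),
                             outcome_params = default_outcome_params(),
                             rho_between_outcomes = 0.20,
                             prompt_rate = 4.9,
                             compliance = 0.93,
                             prompt_noise_sd = 0.3,
                             zero_rate = 0.0013,
                             shortwear_rate = 0.15,
                             nowalk_rate = 0.01,
                             sleep_quality_missing = 0.10,
                             exercised_missing = 0.30,
                             seed = 1L) {
  if (length(n_participants) != 1L || is.na(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive count", call. = FALSE)
  }
  if (n_days < 1) stop("n_days must be a positive count", call. = FALSE)
  if (is.null(mean_ilr)) {
    mean_ilr <- as.numeric(ilr_transform(geometric_mean_day, "H1"))
  }
  if (is.null(sigma_between)) {
    V <- pivot_basis()
    cv <- between_cv[ilr_orderings$H1]
    sigma_between <- t(V) %*% diag(cv^2) %*% V
  }
  for (S in list(sigma_between, sigma_within)) {
    if (!isSymmetric(unname(S), tol = 1e-8) || min(eigen(S, symmetric = TRUE,
                                                         only.values = TRUE)$values) < -1e-8) {
      stop("ilr covariance matrices must be symmetric positive semi-definite",
           call. = FALSE)
    }
  }
  probs <- c(compliance = compliance, zero_rate = zero_rate,
             shortwear_rate = shortwear_rate, nowalk_rate = nowalk_rate,
             sleep_quality_missing = sleep_quality_missing,
             exercised_missing = exercised_missing)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (abs(rho_between_outcomes) > 1) {
    stop("rho_between_outcomes must lie in [-1, 1]", call. = FALSE)
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_days = as.integer(n_days),
              geometric_mean_day = geometric_mean_day,
              mean_ilr = mean_ilr,
              sigma_between = unname(sigma_between),
              sigma_within = unname(sigma_within),
              outcome_params = outcome_params,
              rho_between_outcomes = rho_between_outcomes,
              prompt_rate = prompt_rate, compliance = compliance,
              prompt_noise_sd = prompt_noise_sd, zero_rate = zero_rate,
              shortwear_rate = shortwear_rate, nowalk_rate = nowalk_rate,
              sleep_quality_missing = sleep_quality_missing,
              exercised_missing = exercised_missing,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Default generating models for the daily outcomes
#'
#' Fixed effects, random-effect SDs and residual SDs of the two daily
#' outcomes under the reference rotation `H1`, set to the estimates of the
#' emulated study's reference stress and coping self-efficacy models
#' (sex coded female = 0; ilr effects apply to within-person deviations).
#'
#' @return Named list with elements `stress` and `cse`.
#' @export
default_outcome_params <- function() {
  list(
    stress = list(
      gamma = c(intercept = 2.29, sex = -0.10, age = -0.01, bmi = 0.02,
                cse = -0.57, ilr1 = 0.05, ilr2 = -0.01, ilr3 = 0.06),
      tau0 = 0.61, tau1 = 0.22, rho01 = -0.23, slope_coord = "ilr3",
      sigma = 0.54),
    cse = list(
      gamma = c(intercept = 3.36, sex = 0.14, age = 0.01, bmi = -0.01,
                ilr1 = 0.01, ilr2 = 0.08, ilr3 = 0.08),
      tau0 = 0.67, tau1 = 0, rho01 = 0, slope_coord = "none",
      sigma = 0.56)
  )
}

# One RNG stream per participant and generation stage (attributes,
# compositions, outcome latents, prompts), derived from the master seed.
# Streams are drawn sequentially, so the first k participants are identical
# for any cohort size >= k.
.participant_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(sample.int(2147483646L, 4L * n), ncol = 4L, byrow = TRUE)
}

.rtrunc_norm <- function(n, mu, sigma, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mu, sigma)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Symmetric square root for a PSD matrix (tolerates zero variance rows).
.mvn_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = nrow(S)) %*% t(e$vectors)
}

#' Generate the participant table
#'
#' Draws `n_participants` participants with age and BMI from truncated
#' normals that reproduce the emulated study's descriptive mean/SD/range and
#' sex from a Bernoulli(0.548 female). Deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return Data frame with columns `pid`, `age`, `sex` (factor,
#'   female/male), `bmi`.
#' @export
generate_participants <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_participants
  seeds <- .participant_seeds(cfg$seed, n)
  age <- bmi <- numeric(n)
  sex <- character(n)
  for (j in seq_len(n)) {
    set.seed(seeds[j, 1L])
    age[j] <- .rtrunc_norm(1, .age_parent["mu"], .age_parent["sigma"],
                           .age_parent["lo"], .age_parent["hi"])
    sex[j] <- if (stats::runif(1) < .p_female) "female" else "male"
    bmi[j] <- .rtrunc_norm(1, .bmi_parent["mu"], .bmi_parent["sigma"],
                           .bmi_parent["lo"], .bmi_parent["hi"])
  }
  data.frame(pid = sprintf("P%04d", seq_len(n)),
             age = age,
             sex = factor(sex, levels = c("female", "male")),
             bmi = bmi,
             stringsAsFactors = FALSE)
}

#' Generate the participant-day table
#'
#' For each participant draws a person-mean ilr vector and daily ilr
#' deviations, maps them back to a closed 1440-minute composition, and adds
#' the wear metadata and survey covariates the screening stage consumes:
#' wear hours (~23.8, with a `shortwear_rate` fraction below 20 h), walking
#' bout counts (0 on a small injected fraction of days), below-detection
#' MVPA zeros (minutes absorbed into SB), morning sleep quality (0-100) and
#' the evening exercise flag. Daily latent outcome means are computed from
#' `cfg$outcome_params` and attached for the prompt stage.
#'
#' @param participants Participant table from [generate_participants()].
#' @param cfg The same [generator_config()].
#' @return Data frame, one row per participant-day. Columns `latent_stress`
#'   and `latent_cse` are generator internals consumed by
#'   [generate_momentary_ratings()] and are not written by
#'   [write_cohort_csv()].
#' @export
generate_day_compositions <- function(participants, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.data.frame(participants) || nrow(participants) == 0L) {
    stop("participants table must be non-empty", call. = FALSE)
  }
  n <- nrow(participants)
  nd <- cfg$n_days
  seeds <- .participant_seeds(cfg$seed, max(n, cfg$n_participants))
  Sb <- .mvn_sqrt(cfg$sigma_between)
  Sw <- .mvn_sqrt(cfg$sigma_within)
  ps <- cfg$outcome_params$stress
  pc <- cfg$outcome_params$cse
  Sigma_u <- .random_effects_cov(ps, pc, cfg$rho_between_outcomes)
  Au <- .mvn_sqrt(Sigma_u)
  cse_ref <- .expected_cse(pc)
  coord_idx <- c(ilr1 = 1L, ilr2 = 2L, ilr3 = 3L, none = 0L)

  out <- vector("list", n)
  for (j in seq_len(n)) {
    set.seed(seeds[j, 2L])
    mu_j <- cfg$mean_ilr + as.numeric(Sb %*% stats::rnorm(3))
    dev <- matrix(stats::rnorm(nd * 3L), nd, 3L) %*% t(Sw)
    z <- sweep(dev, 2L, mu_j, "+")
    comp <- ilr_inverse(z, "H1", total = 1440)
    mu_comp <- ilr_inverse(mu_j, "H1", total = 1440)

    wear <- pmin(24, stats::rnorm(nd, 23.79, 0.35))
    short <- stats::runif(nd) < cfg$shortwear_rate
    wear[short] <- stats::runif(sum(short), 14, 19.9)
    walking <- 1L + stats::rpois(nd, 7)
    walking[stats::runif(nd) < cfg$nowalk_rate] <- 0L

    sq <- 70 + 0.06 * (comp[, "sleep"] - mu_comp["sleep"]) +
      stats::rnorm(nd, 0, 12)
    sq <- round(pmin(100, pmax(0, sq)))
    sq[stats::runif(nd) < cfg$sleep_quality_missing] <- NA
    p_ex <- stats::plogis(-1.1 + 0.02 * (comp[, "mvpa"] - mu_comp["mvpa"]))
    ex <- ifelse(stats::runif(nd) < p_ex, "yes", "no")
    ex[stats::runif(nd) < cfg$exercised_missing] <- NA

    # detection: MVPA under 1 minute, or an injected sensor miss, is
    # recorded as 0 and its minutes land in SB
    mvpa_zero <- comp[, "mvpa"] < 1 | stats::runif(nd) < cfg$zero_rate
    sb_min <- comp[, "sb"] + ifelse(mvpa_zero, comp[, "mvpa"], 0)
    mvpa_min <- ifelse(mvpa_zero, 0, comp[, "mvpa"])

    set.seed(seeds[j, 3L])
    u <- as.numeric(Au %*% stats::rnorm(4))  # u0 stress, u1 stress, u0 cse, u1 cse
    slope_c <- coord_idx[[pc$slope_coord]]
    slope_s <- coord_idx[[ps$slope_coord]]
    male <- as.numeric(participants$sex[j] == "male")
    xb_c <- pc$gamma[["intercept"]] + pc$gamma[["sex"]] * male +
      pc$gamma[["age"]] * participants$age[j] +
      pc$gamma[["bmi"]] * participants$bmi[j]
    cse_lat <- xb_c + dev %*% pc$gamma[c("ilr1", "ilr2", "ilr3")] + u[3L] +
      (if (slope_c > 0L) u[4L] * dev[, slope_c] else 0) +
      stats::rnorm(nd, 0, pc$sigma)
    xb_s <- ps$gamma[["intercept"]] + ps$gamma[["sex"]] * male +
      ps$gamma[["age"]] * participants$age[j] +
      ps$gamma[["bmi"]] * participants$bmi[j]
    stress_lat <- xb_s + ps$gamma[["cse"]] * (cse_lat - cse_ref) +
      dev %*% ps$gamma[c("ilr1", "ilr2", "ilr3")] + u[1L] +
      (if (slope_s > 0L) u[2L] * dev[, slope_s] else 0) +
      stats::rnorm(nd, 0, ps$sigma)

    out[[j]] <- data.frame(
      pid = participants$pid[j], day_index = seq_len(nd),
      wear_hours = wear, walking_bouts = walking,
      sleep_min = comp[, "sleep"], sb_min = sb_min,
      lpa_min = comp[, "lpa"], mvpa_min = mvpa_min,
      mvpa_zero = mvpa_zero,
      sleep_quality = sq, exercised = ex,
      latent_stress = as.numeric(stress_lat),
      latent_cse = as.numeric(cse_lat),
      stringsAsFactors = FALSE)
  }
  days <- do.call(rbind, out)
  rownames(days) <- NULL
  days
}

# Joint covariance of (u0 stress, u1 stress, u0 cse, u1 cse).
.random_effects_cov <- function(ps, pc, rho_bo) {
  S <- matrix(0, 4, 4)
  S[1, 1] <- ps$tau0^2; S[2, 2] <- ps$tau1^2
  S[1, 2] <- S[2, 1] <- ps$rho01 * ps$tau0 * ps$tau1
  S[3, 3] <- pc$tau0^2; S[4, 4] <- pc$tau1^2
  S[3, 4] <- S[4, 3] <- pc$rho01 * pc$tau0 * pc$tau1
  S[1, 3] <- S[3, 1] <- rho_bo * ps$tau0 * pc$tau0
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("random-effect covariance implied by outcome_params is not PSD",
         call. = FALSE)
  }
  S
}

# Deterministic anchor for the cse covariate in the stress equation:
# expected daily cse at the covariate means.
.expected_cse <- function(pc) {
  pc$gamma[["intercept"]] + pc$gamma[["sex"]] * .cov_means[["male"]] +
    pc$gamma[["age"]] * .cov_means[["age"]] +
    pc$gamma[["bmi"]] * .cov_means[["bmi"]]
}

#' Generate the momentary prompt table
#'
#' Per day draws a prompt count (Poisson mean `prompt_rate`, capped at 6);
#' with probability `1 - compliance` the day has no ratings at all. Each
#' answered prompt rates both momentary items by adding measurement noise to
#' the day's latent outcome mean, rounding to the Likert grid and clamping
#' to 1-5.
#'
#' @param days Day table from [generate_day_compositions()] (must carry the
#'   latent outcome columns).
#' @param cfg The same [generator_config()].
#' @return Data frame with columns `pid`, `day_index`, `timestamp`,
#'   `stress`, `cse`, `trigger`.
#' @export
generate_momentary_ratings <- function(days, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!all(c("latent_stress", "latent_cse") %in% names(days))) {
    stop("day table lacks latent outcome means; run generate_day_compositions first",
         call. = FALSE)
  }
  pids <- unique(days$pid)
  seeds <- .participant_seeds(cfg$seed, max(length(pids), cfg$n_participants))
  base_date <- as.Date("2022-10-03")
  out <- vector("list", length(pids))
  for (j in seq_along(pids)) {
    set.seed(seeds[j, 4L])
    dj <- days[days$pid == pids[j], , drop = FALSE]
    rows <- vector("list", nrow(dj))
    for (i in seq_len(nrow(dj))) {
      np <- min(stats::rpois(1L, cfg$prompt_rate), 6L)
      if (stats::runif(1) > cfg$compliance) np <- 0L
      if (np == 0L) next
      secs <- sort(round(stats::runif(np, 8 * 3600 + 40 * 60,
                                      21 * 3600 + 40 * 60)))
      stamp <- format(as.POSIXct(base_date + (dj$day_index[i] - 1L),
                                 tz = "UTC") + secs,
                      "%Y-%m-%d %H:%M:%S", tz = "UTC")
      rate <- function(latent) {
        pmin(5, pmax(1, round(latent + stats::rnorm(np, 0, cfg$prompt_noise_sd))))
      }
      rows[[i]] <- data.frame(
        pid = pids[j], day_index = dj$day_index[i], timestamp = stamp,
        stress = rate(dj$latent_stress[i]), cse = rate(dj$latent_cse[i]),
        trigger = sample(c("passive", "sb_interruption"), np, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    out[[j]] <- do.call(rbind, rows)
  }
  prompts <- do.call(rbind, out)
  rownames(prompts) <- NULL
  prompts
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [generate_participants()],
#' [generate_day_compositions()] and [generate_momentary_ratings()].
#'
#' @param cfg A [generator_config()].
#' @return List with `participants`, `days`, `prompts` and the `config`.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  participants <- generate_participants(cfg)
  days <- generate_day_compositions(participants, cfg)
  prompts <- generate_momentary_ratings(days, cfg)
  list(participants = participants, days = days, prompts = prompts,
       config = cfg)
}

#' Write / read a cohort as the three CSV tables
#'
#' `write_cohort_csv()` writes `participants.csv`, `days.csv` (generator
#' internals dropped) and `prompts.csv`; `read_cohort_csv()` reads them
#' back.
#'
#' @param cohort List as returned by [simulate_cohort()].
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort_csv()` the directory, invisibly;
#'   `read_cohort_csv()` a list with the three tables.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  days <- cohort$days
  days <- days[, setdiff(names(days), c("latent_stress", "latent_cse")),
               drop = FALSE]
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(days, file.path(dir, "days.csv"), row.names = FALSE)
  utils::write.csv(cohort$prompts, file.path(dir, "prompts.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  read1 <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  participants <- read1("participants.csv")
  participants$sex <- factor(participants$sex, levels = c("female", "male"))
  list(participants = participants, days = read1("days.csv"),
       prompts = read1("prompts.csv"))
}
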