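#' Merge participant covariates into the day table
#'
#' @param days Screened day table.
#' @param participants Participant table (`pid`, `age`, `sex`, `bmi`).
#' @return Day table with the covariate columns attached.
#' @export
prepare_analysis_days <- function(days, participants) {
  need <- c("pid", "age", "sex", "bmi")
  miss <- setdiff(need, names(participants))
  if (length(miss)) {
    stop("participant table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  merge(days, participants[, need], by = "pid", sort = FALSE)
}

.outcome_col <- function(outcome) {
  switch(outcome, stress = "stress_daily", cse = "cse_daily",
         stop("outcome must be 'stress' or 'cse'", call. = FALSE))
}

#' Intercept-only two-level model and intraclass correlation
#'
#' Fits the unconditional model \eqn{y_{ij} = \gamma_{00} + u_{0j} + r_{ij}}
#' by REML and reports the intraclass correlation
#' \eqn{\rho_I = \tau_0^2 / (\tau_0^2 + \sigma^2)}: the between-person share
#' of the outcome variance. The complementary within-person share is
#' `100 * (1 - rho)` percent (see [within_person_share()]).
#'
#' @param days Day table with the daily outcome columns.
#' @param outcome `"stress"` or `"cse"`.
#' @return Object of class `uncond_fit`: `tau0`, `sigma`, `icc`,
#'   `within_share` (percent), `loglik`, `n_obs`, `n_participants`, and the
#'   underlying `lme4` fit.
#' @export
fit_unconditional <- function(days, outcome = c("stress", "cse")) {
  outcome <- match.arg(outcome)
  ycol <- .outcome_col(outcome)
  d <- days[!is.na(days[[ycol]]), c("pid", ycol)]
  names(d) <- c("pid", "y")
  if (length(unique(d$pid)) < 2L) {
    stop("unconditional model needs at least 2 participants", call. = FALSE)
  }
  fit <- lme4::lmer(y ~ 1 + (1 | pid), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau0 <- vc$sdcor[vc$grp == "pid"][1L]
  sigma <- vc$sdcor[vc$grp == "Residual"][1L]
  icc <- tau0^2 / (tau0^2 + sigma^2)
  out <- list(outcome = outcome, tau0 = tau0, sigma = sigma, icc = icc,
              within_share = within_person_share(icc),
              loglik = as.numeric(stats::logLik(fit)),
              n_obs = nrow(d), n_participants = length(unique(d$pid)),
              fit = fit)
  class(out) <- "uncond_fit"
  out
}

#' Within-person variance share implied by an intraclass correlation
#'
#' @param icc Intraclass correlation \eqn{\rho_I} in `[0, 1]`.
#' @return Percentage of outcome variance attributable to within-person
#'   fluctuation: `100 * (1 - icc)`.
#' @examples
#' within_person_share(0.483)  # 51.7
#' @export
within_person_share <- function(icc) {
  stopifnot(all(icc >= 0 & icc <= 1))
  100 * (1 - icc)
}

# Build the model frame: zero replacement, ilr under the rotation,
# listwise deletion, within-person centering over the rows entering the fit.
.model_frame <- function(days, outcome, ordering, extra = character(),
                         cse_centering = "grand",
                         zero_method = "multiplicative") {
  ycol <- .outcome_col(outcome)
  need <- c("pid", ycol, "sex", "age", "bmi",
            "sleep_min", "sb_min", "lpa_min", "mvpa_min")
  if (outcome == "stress") need <- c(need, "cse_daily")
  need <- c(need, extra)
  miss <- setdiff(need, names(days))
  if (length(miss)) {
    stop("day table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  comp <- days[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")]
  names(comp) <- behavior_parts
  comp <- replace_zeros(comp, method = zero_method)
  z <- ilr_transform(comp, ordering)
  d <- cbind(days[need], as.data.frame(unclass(z)[, 1:3, drop = FALSE]))
  d$y <- d[[ycol]]
  if (outcome == "stress") {
    d$cse_cov <- switch(cse_centering,
                        grand = d$cse_daily - mean(d$cse_daily, na.rm = TRUE),
                        none = d$cse_daily,
                        stop("cse_centering must be 'grand' or 'none'",
                             call. = FALSE))
  }
  keep_cols <- c("y", "sex", "age", "bmi",
                 if (outcome == "stress") "cse_cov", extra)
  d <- d[stats::complete.cases(d[, keep_cols]), , drop = FALSE]
  cw <- center_within_person(d, cols = c("ilr1", "ilr2", "ilr3"))
  cw$data
}

#' Fit a hypothesis-specific two-level compositional model
#'
#' Fits, by REML, the daily outcome on the within-person-centered ilr
#' coordinates of the chosen rotation plus the person-level covariates sex
#' (female = reference), age and BMI; stress models additionally adjust for
#' the day's coping self-efficacy. The random part is a participant
#' intercept, optionally plus one ilr slope with an unstructured 2x2
#' covariance. `random_slope = "auto"` delegates the choice to
#' [select_random_slope()].
#'
#' Inference for fixed effects uses the residual degree-of-freedom
#' convention `df = n_obs - n_fixed`; standardized coefficients are
#' `B * SD(x) / SD(y)` over the retained participant-days.
#'
#' @param days Screened day table with covariates attached
#'   (see [prepare_analysis_days()]).
#' @param outcome `"stress"` or `"cse"`.
#' @param ordering Rotation name, see [ilr_orderings].
#' @param random_slope `"none"`, one of `"ilr1"`..`"ilr3"`, or `"auto"`.
#' @param extra Names of additional day-level fixed predictors (e.g.
#'   `"sleep_quality"`, `"exercised"`); days missing them are dropped
#'   listwise for this model only.
#' @param cse_centering How the coping self-efficacy covariate enters stress
#'   models: `"grand"` (grand-mean centered, default) or `"none"` (raw).
#' @param zero_method Zero-replacement method, see [replace_zeros()].
#' @param REML Use restricted maximum likelihood (default `TRUE`).
#' @return Object of class `hypothesis_fit`: `coefficients` (estimate, SE,
#'   95% CI, df, t, p, standardized beta per fixed effect), `random`
#'   (intercept/slope SDs, their correlation, residual SD), `loglik`,
#'   `converged` plus any optimizer messages, the model frame, and the
#'   underlying `lme4` fit.
#' @export
fit_hypothesis_model <- function(days, outcome = c("stress", "cse"),
                                 ordering = "H1",
                                 random_slope = c("none", "ilr1", "ilr2",
                                                  "ilr3", "auto"),
                                 extra = character(),
                                 cse_centering = "grand",
                                 zero_method = "multiplicative",
                                 REML = TRUE) {
  outcome <- match.arg(outcome)
  random_slope <- match.arg(random_slope)
  if (random_slope == "auto") {
    sel <- select_random_slope(days, outcome = outcome, ordering = ordering,
                               extra = extra, cse_centering = cse_centering,
                               zero_method = zero_method)
    random_slope <- sel$slope
  }
  d <- .model_frame(days, outcome, ordering, extra = extra,
                    cse_centering = cse_centering, zero_method = zero_method)
  fixed <- c("sex", "age", "bmi", if (outcome == "stress") "cse_cov",
             extra, "ilr1_c", "ilr2_c", "ilr3_c")
  ranpart <- if (random_slope == "none") "(1 | pid)" else
    sprintf("(1 + %s_c | pid)", random_slope)
  form <- stats::as.formula(paste("y ~", paste(fixed, collapse = " + "),
                                  "+", ranpart))
  fit <- lme4::lmer(form, data = d, REML = REML)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(d)
  df <- n_obs - length(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  X <- stats::model.matrix(fit)
  sdy <- stats::sd(d$y)
  std <- vapply(seq_along(beta), function(k) {
    if (names(beta)[k] == "(Intercept)") return(NA_real_)
    beta[k] * stats::sd(X[, names(beta)[k]]) / sdy
  }, numeric(1))
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta),
                      se = as.numeric(se), ci_low = beta - crit * se,
                      ci_high = beta + crit * se, df = df, t = tval,
                      p = pval, std_beta = std, row.names = NULL)

  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp == "pid" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)][1L]
  sd_slope <- if (random_slope == "none") NA_real_ else
    vc$sdcor[vc$grp == "pid" & vc$var1 == paste0(random_slope, "_c") &
               is.na(vc$var2)][1L]
  corr <- if (random_slope == "none") NA_real_ else
    vc$sdcor[vc$grp == "pid" & !is.na(vc$var2)][1L]
  sigma <- vc$sdcor[vc$grp == "Residual"][1L]

  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  out <- list(outcome = outcome, ordering = ordering,
              random_slope = random_slope, extra = extra,
              formula = form,
              coefficients = coefs,
              random = list(sd_intercept = sd_int, sd_slope = sd_slope,
                            slope_coord = random_slope, corr = corr,
                            sigma = sigma),
              loglik = as.numeric(stats::logLik(fit)),
              REML = REML, converged = is.null(msgs),
              messages = msgs,
              n_obs = n_obs, n_participants = length(unique(d$pid)),
              data = d, fit = fit)
  class(out) <- "hypothesis_fit"
  out
}

#' Select at most one random ilr slope by restricted likelihood-ratio test
#'
#' Each candidate slope is tested one at a time against the intercept-only
#' model via the REML likelihood ratio, using the boundary-corrected
#' \eqn{0.5\,\chi^2_1 + 0.5\,\chi^2_2} mixture null. The candidate with the
#' smallest p-value is retained if it is below `alpha`; ties break by ilr
#' index.
#'
#' @inheritParams fit_hypothesis_model
#' @param candidates Candidate slope coordinates (default all three).
#' @param alpha Retention level (default 0.05).
#' @return List: `slope` (chosen coordinate or `"none"`) and `tests`
#'   (candidate, log-likelihoods, LR statistic, mixture p-value).
#' @export
select_random_slope <- function(days, outcome = c("stress", "cse"),
                                ordering = "H1",
                                candidates = c("ilr1", "ilr2", "ilr3"),
                                alpha = 0.05, extra = character(),
                                cse_centering = "grand",
                                zero_method = "multiplicative") {
  outcome <- match.arg(outcome)
  if (!length(candidates)) {
    return(list(slope = "none",
                tests = data.frame(candidate = character(0), ll_base = numeric(0),
                                   ll_slope = numeric(0), lr = numeric(0),
                                   p = numeric(0))))
  }
  base <- fit_hypothesis_model(days, outcome = outcome, ordering = ordering,
                               random_slope = "none", extra = extra,
                               cse_centering = cse_centering,
                               zero_method = zero_method)
  rows <- lapply(candidates, function(cand) {
    f <- suppressMessages(
      fit_hypothesis_model(days, outcome = outcome, ordering = ordering,
                           random_slope = cand, extra = extra,
                           cse_centering = cse_centering,
                           zero_method = zero_method))
    lr <- max(0, 2 * (f$loglik - base$loglik))
    p <- 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(lr, 2, lower.tail = FALSE)
    data.frame(candidate = cand, ll_base = base$loglik, ll_slope = f$loglik,
               lr = lr, p = p)
  })
  tests <- do.call(rbind, rows)
  slope <- "none"
  if (any(tests$p < alpha)) {
    slope <- tests$candidate[which.min(tests$p)]
  }
  list(slope = slope, tests = tests)
}

#' Standardized coefficients of a fitted hypothesis model
#'
#' Convention: \eqn{\beta_{std} = B \cdot SD(x) / SD(y)}, with SDs taken
#' over all retained participant-days.
#'
#' @param fit A `hypothesis_fit`.
#' @return Data frame with `term` and `std_beta`.
#' @export
standardize_coefficients <- function(fit) {
  stopifnot(inherits(fit, "hypothesis_fit"))
  fit$coefficients[, c("term", "std_beta")]
}

#' Model diagnostics: collinearity, residual normality, homoscedasticity
#'
#' Computes variance-inflation factors of the fixed predictors (infinite
#' under perfect collinearity), a Shapiro-Wilk statistic and QQ data for the
#' level-1 residuals, and a Spearman test of |residual| against fitted
#' values. Flags only; nothing is refitted.
#'
#' @param fit A `hypothesis_fit`.
#' @param alpha Flagging level (default 0.05).
#' @return Object of class `mlm_diagnostics`: `vif`, `collinearity_flag`,
#'   `shapiro` (statistic, p), `normality_flag`, `heteroscedasticity`
#'   (rho, p), `heteroscedasticity_flag`, `qq` (theoretical and sample
#'   quantiles).
#' @export
model_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "hypothesis_fit"))
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(attr(stats::terms(fit$formula), "term.labels")[
      !grepl("\\|", attr(stats::terms(fit$formula), "term.labels"))],
      collapse = " + "))), data = fit$data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- rep(Inf, ncol(X))
  names(vif) <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  if (all(sds > 0)) {
    R <- stats::cor(X)
    Ri <- tryCatch(solve(R), error = function(e) NULL)
    if (!is.null(Ri) && all(diag(Ri) > 0) && kappa(R) < 1e12) vif <- diag(Ri)
  }
  res <- stats::residuals(fit$fit)
  rs <- as.numeric(scale(res))
  if (length(rs) > 5000) {
    rs <- rs[round(seq(1, length(rs), length.out = 5000))]
  }
  sh <- stats::shapiro.test(rs)
  het <- suppressWarnings(stats::cor.test(abs(res), stats::fitted(fit$fit),
                                          method = "spearman"))
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(rs))),
                   sample = sort(rs))
  out <- list(vif = vif,
              collinearity_flag = any(!is.finite(vif)) || any(vif > 10),
              shapiro = c(statistic = unname(sh$statistic), p = sh$p.value),
              normality_flag = sh$p.value < alpha,
              heteroscedasticity = c(rho = unname(het$estimate),
                                     p = het$p.value),
              heteroscedasticity_flag = het$p.value < alpha,
              qq = qq)
  class(out) <- "mlm_diagnostics"
  out
}

#' @export
print.uncond_fit <- function(x, ...) {
  cat(sprintf("Unconditional two-level model for %s (%d days, %d participants)\n",
              x$outcome, x$n_obs, x$n_participants))
  cat(sprintf("  tau0 = %.3f, sigma = %.3f\n", x$tau0, x$sigma))
  cat(sprintf("  ICC (rho_I) = %.3f; within-person share = %.1f%%\n",
              x$icc, x$within_share))
  invisible(x)
}

#' @export
print.hypothesis_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-level compositional model: %s ~ rotation %s (%d days, %d participants)\n",
              x$outcome, x$ordering, x$n_obs, x$n_participants))
  cat(sprintf("Random slope: %s%s\n", x$random_slope,
              if (!x$converged) "  [optimizer messages -- inspect $messages]" else ""))
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], function(v) round(v, digits))
  print(co, row.names = FALSE)
  cat(sprintf("Random effects: SD(intercept) = %.3f%s, residual SD = %.3f\n",
              x$random$sd_intercept,
              if (!is.na(x$random$sd_slope))
                sprintf(", SD(slope %s) = %.3f, corr = %.2f",
                        x$random$slope_coord, x$random$sd_slope,
                        x$random$corr) else "",
              x$random$sigma))
  invisible(x)
}

#' @export
print.mlm_diagnostics <- function(x, ...) {
  cat("Fixed-predictor VIFs:\n")
  print(round(x$vif, 2))
  cat(sprintf("Collinearity flag: %s\n", x$collinearity_flag))
  cat(sprintf("Shapiro-Wilk on level-1 residuals: W = %.3f, p = %.3g (flag: %s)\n",
              x$shapiro["statistic"], x$shapiro["p"], x$normality_flag))
  cat(sprintf("|residual| vs fitted Spearman rho = %.3f, p = %.3g (flag: %s)\n",
              x$heteroscedasticity["rho"], x$heteroscedasticity["p"],
              x$heteroscedasticity_flag))
  invisible(x)
}
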