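#' Move minutes from one behavior to another
#'
#' The elementary isotemporal substitution: `minutes` leave `from`,
#' `minutes` enter `to`, the other parts and the 1440-minute total are
#' untouched.
#'
#' @param base Named composition in minutes (parts `sleep`, `sb`, `lpa`,
#'   `mvpa`).
#' @param from,to Donor and recipient behaviors (distinct).
#' @param minutes Non-negative minutes to move; must be strictly less than
#'   `base[from]` so the reallocated day keeps all parts positive.
#' @return The reallocated composition.
#' @examples
#' reallocate(c(sleep = 490, sb = 649, lpa = 227, mvpa = 74),
#'            from = "sb", to = "sleep", minutes = 60)
#' @export
reallocate <- function(base, from, to, minutes) {
  base <- close_composition(base, total = sum(.as_part_matrix(base)))
  from <- match.arg(from, behavior_parts)
  to <- match.arg(to, behavior_parts)
  if (from == to) stop("'from' and 'to' must differ", call. = FALSE)
  if (minutes < 0) stop("'minutes' must be non-negative", call. = FALSE)
  if (minutes >= base[[from]]) {
    stop(sprintf("cannot move %.0f minutes out of %s (only %.1f available)",
                 minutes, from, base[[from]]), call. = FALSE)
  }
  base[[from]] <- base[[from]] - minutes
  base[[to]] <- base[[to]] + minutes
  base
}

#' Predicted outcome change for a time reallocation
#'
#' The expected change in the daily outcome when `minutes` move from one
#' behavior to another, starting from the base composition:
#' \eqn{\Delta = \sum_k \gamma_k (z_k(\mathrm{new}) - z_k(\mathrm{base}))}
#' over the three composition fixed effects of the fitted model. Because
#' the predictors are within-person centered and the covariates are held
#' fixed, everything except the ilr difference cancels.
#'
#' @param fit A `hypothesis_fit`.
#' @param base Named base composition in minutes.
#' @param from,to,minutes As in [reallocate()].
#' @return The predicted change, in outcome (Likert) units.
#' @export
predict_delta <- function(fit, base, from, to, minutes) {
  stopifnot(inherits(fit, "hypothesis_fit"))
  gamma <- .ilr_gamma(fit$coefficients)
  .delta_from_gamma(gamma, fit$ordering, base, from, to, minutes)
}

.ilr_gamma <- function(coefs) {
  g <- coefs$estimate[match(c("ilr1_c", "ilr2_c", "ilr3_c"), coefs$term)]
  if (anyNA(g)) stop("fit lacks the three ilr fixed effects", call. = FALSE)
  g
}

.delta_from_gamma <- function(gamma, ordering, base, from, to, minutes) {
  if (minutes == 0) return(0)
  znew <- ilr_transform(reallocate(base, from, to, minutes), ordering)
  zbase <- ilr_transform(base, ordering)
  sum(gamma * (as.numeric(znew) - as.numeric(zbase)))
}

#' Default reallocation pairs: replacing sedentary behavior
#'
#' @return Data frame of donor/recipient pairs: SB time replaced by LPA,
#'   MVPA and sleep.
#' @export
default_reallocation_pairs <- function() {
  data.frame(from = c("sb", "sb", "sb"), to = c("lpa", "mvpa", "sleep"),
             stringsAsFactors = FALSE)
}

# Mean day of the data behind a fit, closed to 1440 (the default base).
.mean_day <- function(data) {
  m <- colMeans(data[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])
  names(m) <- behavior_parts
  close_composition(m)
}

#' Point estimates for a reallocation grid
#'
#' @param fit A `hypothesis_fit`.
#' @param base Base composition; defaults to the arithmetic mean day of the
#'   data behind the fit, closed to 1440 minutes.
#' @param pairs Data frame of `from`/`to` pairs
#'   (default [default_reallocation_pairs()]).
#' @param minutes Reallocation grid in minutes (default 0, 20, 40, 60).
#' @return Data frame: `outcome`, `from`, `to`, `minutes`, `delta`.
#' @export
reallocation_grid <- function(fit, base = NULL,
                              pairs = default_reallocation_pairs(),
                              minutes = c(0, 20, 40, 60)) {
  stopifnot(inherits(fit, "hypothesis_fit"))
  if (is.null(base)) base <- .mean_day(fit$data)
  grid <- merge(pairs, data.frame(minutes = minutes))
  grid$outcome <- fit$outcome
  grid$delta <- mapply(function(f, t, m) predict_delta(fit, base, f, t, m),
                       grid$from, grid$to, grid$minutes)
  grid[order(grid$from, grid$to, grid$minutes),
       c("outcome", "from", "to", "minutes", "delta")]
}

# Lean refit used inside the bootstrap: same model frame machinery,
# derivative checks off, returns only what the delta needs.
.fit_ilr_gamma <- function(days, outcome, ordering, random_slope,
                           extra, cse_centering, zero_method) {
  d <- .model_frame(days, outcome, ordering, extra = extra,
                    cse_centering = cse_centering, zero_method = zero_method)
  fixed <- c("sex", "age", "bmi", if (outcome == "stress") "cse_cov",
             extra, "ilr1_c", "ilr2_c", "ilr3_c")
  ranpart <- if (random_slope == "none") "(1 | pid)" else
    sprintf("(1 + %s_c | pid)", random_slope)
  form <- stats::as.formula(paste("y ~", paste(fixed, collapse = " + "),
                                  "+", ranpart))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  fe[c("ilr1_c", "ilr2_c", "ilr3_c")]
}

#' Cluster-bootstrap confidence intervals for reallocation estimates
#'
#' Resamples participants (level-2 units) with replacement, keeping each
#' participant's days intact, refits the model on every resample with the
#' random structure fixed to the one chosen on the full data, and recomputes
#' the predicted change for every grid point. Confidence bounds are the
#' 2.5/97.5 percentiles of the bootstrap distribution. Deterministic given
#' `seed`.
#'
#' @inheritParams fit_hypothesis_model
#' @param base Base composition; defaults to the arithmetic mean day of the
#'   fitted data.
#' @param pairs,minutes Reallocation grid, as in [reallocation_grid()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @param max_fail Abort when more than this fraction of replicates fails
#'   to fit (default 0.2).
#' @return Data frame of class `reallocation_ci`: `outcome`, `from`, `to`,
#'   `minutes`, `delta`, `ci_low`, `ci_high`; attributes `n_boot` and
#'   `n_failed`.
#' @export
bootstrap_delta_ci <- function(days, outcome = c("stress", "cse"),
                               ordering = "H1", random_slope = "none",
                               base = NULL,
                               pairs = default_reallocation_pairs(),
                               minutes = c(0, 20, 40, 60),
                               n_boot = 1000L, seed = 1L, max_fail = 0.2,
                               extra = character(), cse_centering = "grand",
                               zero_method = "multiplicative") {
  outcome <- match.arg(outcome)
  fit <- fit_hypothesis_model(days, outcome = outcome, ordering = ordering,
                              random_slope = random_slope, extra = extra,
                              cse_centering = cse_centering,
                              zero_method = zero_method)
  if (is.null(base)) base <- .mean_day(fit$data)
  grid <- reallocation_grid(fit, base = base, pairs = pairs,
                            minutes = minutes)

  pids <- unique(days$pid)
  np <- length(pids)
  set.seed(seed)
  draws <- matrix(sample.int(np, np * n_boot, replace = TRUE), nrow = n_boot)
  rows_by_pid <- split(seq_len(nrow(days)), days$pid)

  boot <- matrix(NA_real_, n_boot, nrow(grid))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- pids[draws[b, ]]
    idx <- unlist(rows_by_pid[take], use.names = FALSE)
    d <- days[idx, , drop = FALSE]
    # duplicated participants become distinct clusters
    d$pid <- rep(paste0(take, "#", seq_len(np)),
                 lengths(rows_by_pid[take]))
    gamma <- tryCatch(
      suppressMessages(suppressWarnings(
        .fit_ilr_gamma(d, outcome, ordering, random_slope, extra,
                       cse_centering, zero_method))),
      error = function(e) NULL)
    if (is.null(gamma) || anyNA(gamma)) {
      n_failed <- n_failed + 1L
      next
    }
    boot[b, ] <- mapply(function(f, t, m)
      .delta_from_gamma(gamma, ordering, base, f, t, m),
      grid$from, grid$to, grid$minutes)
  }
  if (n_failed > max_fail * n_boot) {
    stop(sprintf("bootstrap aborted: %d of %d replicates failed to converge",
                 n_failed, n_boot), call. = FALSE)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  grid$ci_low <- ci[1L, ]
  grid$ci_high <- ci[2L, ]
  attr(grid, "n_boot") <- n_boot
  attr(grid, "n_failed") <- n_failed
  class(grid) <- c("reallocation_ci", class(grid))
  grid
}

#' Plot reallocation estimates with bootstrap intervals
#'
#' Point-and-interval display of the predicted outcome change per
#' reallocation pair and increment.
#'
#' @param grid Output of [bootstrap_delta_ci()] (or
#'   [reallocation_grid()], in which case no intervals are drawn).
#' @return A ggplot object.
#' @export
plot_reallocation <- function(grid) {
  lab <- toupper(paste(grid$from, "→", grid$to))
  df <- cbind(as.data.frame(grid), pair = lab)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = minutes, y = delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(outcome ~ pair) +
    ggplot2::labs(x = "Minutes reallocated",
                  y = "Predicted outcome change (Likert units)") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(df))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = ci_low, ymax = ci_high), width = 2)
  }
  p
}
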