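#' Convert a composition percentage of the day to hours
#'
#' @param pct Percentage of the 24-hour day (0-100).
#' @param digits Rounding for display (default 1, as such tables print).
#' @return Hours per day.
#' @examples
#' pct_to_hours(45.2)  # 10.8
#' @export
pct_to_hours <- function(pct, digits = 1) {
  round(pct / 100 * 24, digits)
}

#' Percentage helper for count ratios
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Rounding for display (default 1).
#' @return `100 * num / den`, rounded.
#' @examples
#' proportion_pct(122, 2187)  # 5.6
#' @export
proportion_pct <- function(num, den, digits = 1) {
  round(100 * num / den, digits)
}

#' Cohort descriptives: covariates, behaviors, outcomes, geometric-mean day
#'
#' Participant-aggregated summaries in the layout such studies print:
#' covariate and behavior means/SDs/ranges (behaviors first averaged within
#' participants, in hours/day), daily outcome summaries, and the
#' geometric-mean day with its percentage split.
#'
#' @param days Screened day table with covariates and daily outcomes.
#' @return List: `table` (variable, mean, sd, min, max),
#'   `geometric_mean_day` (minutes) and `geometric_mean_pct`.
#' @export
behavior_descriptives <- function(days) {
  per_person <- function(col) {
    tapply(days[[col]], days$pid, mean, na.rm = TRUE)
  }
  hrs <- list(sleep = per_person("sleep_min") / 60,
              sb = per_person("sb_min") / 60,
              lpa = per_person("lpa_min") / 60,
              mvpa = per_person("mvpa_min") / 60)
  row <- function(name, v) {
    v <- v[!is.na(v)]
    data.frame(variable = name, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }
  first_per_pid <- days[!duplicated(days$pid), ]
  tab <- rbind(
    row("age_y", first_per_pid$age),
    row("bmi", first_per_pid$bmi),
    row("valid_days", as.numeric(table(days$pid))),
    row("sleep_h", hrs$sleep), row("sb_h", hrs$sb),
    row("lpa_h", hrs$lpa), row("mvpa_h", hrs$mvpa),
    row("stress_daily", per_person("stress_daily")),
    row("cse_daily", per_person("cse_daily")))
  comp <- days[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")]
  names(comp) <- behavior_parts
  comp <- replace_zeros(comp)
  gm <- geometric_mean_composition(comp)
  list(table = tab, geometric_mean_day = gm,
       geometric_mean_pct = 100 * gm / 1440)
}
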