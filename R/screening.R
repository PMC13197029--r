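#' Flag valid wear days
#'
#' A participant-day is valid when the accelerometer was worn at least 20
#' hours, at least one period of walking was detected, and the day comprises
#' more than zero minutes of sleep.
#'
#' @param days Day table with columns `wear_hours`, `walking_bouts`,
#'   `sleep_min`.
#' @return `days` with a logical `valid` column.
#' @export
flag_valid_days <- function(days) {
  need <- c("wear_hours", "walking_bouts", "sleep_min")
  miss <- setdiff(need, names(days))
  if (length(miss)) {
    stop("day table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  days$valid <- days$wear_hours >= 20 & days$walking_bouts >= 1 &
    days$sleep_min > 0
  days
}

#' Drop participants with fewer than `min_days` valid days
#'
#' @param days Day table carrying a `valid` flag (see [flag_valid_days()]).
#' @param min_days Minimum number of valid wear days (default 3).
#' @return List: `days` (rows of retained participants only) and
#'   `excluded_pids`.
#' @export
filter_participants <- function(days, min_days = 3L) {
  if (!"valid" %in% names(days)) {
    stop("run flag_valid_days() first", call. = FALSE)
  }
  if (nrow(days) == 0L) {
    return(list(days = days, excluded_pids = character(0)))
  }
  nvalid <- tapply(days$valid, days$pid, sum)
  excluded <- names(nvalid)[nvalid < min_days]
  list(days = days[!days$pid %in% excluded, , drop = FALSE],
       excluded_pids = excluded)
}

#' Aggregate momentary ratings to participant-day means
#'
#' Attaches the arithmetic mean of each day's non-missing stress and coping
#' self-efficacy ratings (`stress_daily`, `cse_daily`) plus the rating count
#' `n_ratings`. Days without any rating of either outcome are dropped, and
#' participants left with no remaining days are dropped with them.
#'
#' @param prompts Prompt table with columns `pid`, `day_index`, `stress`,
#'   `cse` (ratings on the 1-5 grid).
#' @param days Day table.
#' @return List: `days` (aggregated, rating-free days removed),
#'   `n_rating_free` (days dropped), `dropped_pids` (participants whose
#'   days were all rating-free).
#' @export
aggregate_daily_ratings <- function(prompts, days) {
  ratings <- c(prompts$stress, prompts$cse)
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) && (any(ratings < 1) || any(ratings > 5))) {
    stop("ratings must lie on the 1-5 scale", call. = FALSE)
  }
  key <- function(d) paste(d$pid, d$day_index, sep = "\r")
  mean_by <- function(x, k) {
    ok <- !is.na(x)
    if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
    tapply(x[ok], k[ok], mean)
  }
  pk <- key(prompts)
  sm <- mean_by(prompts$stress, pk)
  cm <- mean_by(prompts$cse, pk)
  nr <- table(pk)
  dk <- key(days)
  days$n_ratings <- as.integer(nr[dk])
  days$n_ratings[is.na(days$n_ratings)] <- 0L
  days$stress_daily <- as.numeric(sm[dk])
  days$cse_daily <- as.numeric(cm[dk])
  rating_free <- is.na(days$stress_daily) & is.na(days$cse_daily)
  kept <- days[!rating_free, , drop = FALSE]
  dropped_pids <- setdiff(unique(days$pid), unique(kept$pid))
  list(days = kept, n_rating_free = sum(rating_free),
       dropped_pids = dropped_pids)
}

#' Apply the full inclusion screen to a cohort
#'
#' Runs the study's inclusion filters in order: flag valid wear days
#' (>= 20 h wear, walking detected, non-zero sleep), drop participants with
#' fewer than `min_days` valid days, drop the remaining invalid days,
#' aggregate momentary ratings and drop rating-free days (and participants
#' left empty). Every input day lands in exactly one bucket of the report,
#' so the counts reconcile exactly.
#'
#' @param days,prompts Cohort tables (see [simulate_cohort()]).
#' @param min_days Minimum valid days per participant (default 3).
#' @return List: `days` (the analysis set), `report` (named counts:
#'   `n_days_input`, `n_days_excluded_participants`, `n_days_wear_invalid`,
#'   `n_days_rating_free`, `n_days_retained`, participant-level counts and
#'   the exclusion id lists).
#' @export
screen_cohort <- function(days, prompts, min_days = 3L) {
  days <- flag_valid_days(days)
  n_input <- nrow(days)
  pids_input <- unique(days$pid)

  fp <- filter_participants(days, min_days = min_days)
  n_excluded_participant_days <- n_input - nrow(fp$days)

  wear_invalid <- !fp$days$valid
  n_wear_invalid <- sum(wear_invalid)
  valid_days <- fp$days[!wear_invalid, , drop = FALSE]

  agg <- aggregate_daily_ratings(prompts, valid_days)

  report <- list(
    n_days_input = n_input,
    n_days_excluded_participants = n_excluded_participant_days,
    n_days_wear_invalid = n_wear_invalid,
    n_days_rating_free = agg$n_rating_free,
    n_days_retained = nrow(agg$days),
    n_participants_input = length(pids_input),
    n_participants_excluded_wear = length(fp$excluded_pids),
    n_participants_excluded_ratings = length(agg$dropped_pids),
    n_participants_retained = length(unique(agg$days$pid)),
    excluded_pids_wear = fp$excluded_pids,
    excluded_pids_ratings = agg$dropped_pids)
  list(days = agg$days, report = report)
}
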