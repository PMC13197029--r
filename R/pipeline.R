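#' Default configuration for the full analysis pipeline
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @return Named list understood by [run_pipeline()]: generator overrides
#'   (`generator`), screening threshold (`min_valid_days`),
#'   zero-replacement method, the hypothesis rotations and outcomes to fit,
#'   random-slope policy, exploratory covariate toggles
#'   (`add_sleep_quality` for the sleep-vs-SB models, `add_exercised` for
#'   the activity models), reallocation settings (`realloc`), and the
#'   output directory.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       input_dir = NULL,
       generator = list(),
       min_valid_days = 3L,
       zero_method = "multiplicative",
       orderings = c("H1", "H2", "H3", "H4"),
       outcomes = c("stress", "cse"),
       random_slope = "auto",
       cse_centering = "grand",
       add_sleep_quality = FALSE,
       add_exercised = FALSE,
       realloc = list(enabled = TRUE, ordering = "H1", base = NULL,
                      minutes = c(0, 20, 40, 60), n_boot = 1000L),
       write_plot = FALSE,
       out_dir = "stresscomp-output")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys fall back to [default_run_config()] (nested lists are
#' merged key-wise).
#'
#' @param path YAML file.
#' @param seed Seed used when the file does not set one.
#' @return Configuration list.
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(seed), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(f))
}

.stage_msg <- function(stage, t0) {
  message(sprintf("[stresscomp] %-12s %6.1f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

# Hypothesis id -> outcome/rotation map: models 1-4 predict stress under
# rotations H1-H4, models 5-8 predict coping self-efficacy under the same
# four rotations.
.hypothesis_plan <- function() {
  data.frame(model = paste0("H", 1:8),
             outcome = rep(c("stress", "cse"), each = 4L),
             ordering = rep(c("H1", "H2", "H3", "H4"), 2L),
             stringsAsFactors = FALSE)
}

.model_csv <- function(fit) {
  co <- fit$coefficients
  co$type <- "fixed"
  ran <- data.frame(
    term = c("sd_intercept",
             if (!is.na(fit$random$sd_slope))
               paste0("sd_slope_", fit$random$slope_coord),
             if (!is.na(fit$random$corr)) "intercept_slope_corr",
             "sd_residual"),
    estimate = c(fit$random$sd_intercept,
                 if (!is.na(fit$random$sd_slope)) fit$random$sd_slope,
                 if (!is.na(fit$random$corr)) fit$random$corr,
                 fit$random$sigma),
    stringsAsFactors = FALSE)
  ran$variance <- ifelse(grepl("^sd_", ran$term), ran$estimate^2, NA_real_)
  ran$type <- "random"
  cols <- c("type", "term", "estimate", "se", "ci_low", "ci_high", "df",
            "t", "p", "std_beta", "variance")
  for (cl in setdiff(cols, names(co))) co[[cl]] <- NA_real_
  for (cl in setdiff(cols, names(ran))) ran[[cl]] <- NA_real_
  rbind(co[cols], ran[cols])
}

#' Run the full compositional stress analysis pipeline
#'
#' Orchestrates generate (or load) -> screen -> descriptives -> ICCs ->
#' hypothesis models -> reallocation -> report. Writes, under
#' `config$out_dir`: `screening.json`, `descriptives.csv`,
#' `geometric_mean_day.json`, `icc.json`, `model_H1.csv` .. `model_H8.csv`,
#' `reallocation.csv` (plus `reallocation.png` when `write_plot`), and a
#' machine-readable `manifest.json` (config, config hash, seed, versions).
#' Per-stage timings and slope decisions go to `stderr`. Identical config
#' and seed give byte-identical CSV outputs.
#'
#' @param config Configuration list, see [default_run_config()] /
#'   [read_run_config()].
#' @return Invisibly, a list with the screened data, reports, fitted
#'   models and reallocation table.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]

  if (!is.null(config$input_dir)) {
    cohort <- read_cohort_csv(config$input_dir)
  } else {
    gcfg <- do.call(generator_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$generator))
    cohort <- simulate_cohort(gcfg)
  }
  .stage_msg("simulate", t0)

  scr <- screen_cohort(cohort$days, cohort$prompts,
                       min_days = config$min_valid_days)
  jsonlite::write_json(scr$report, file.path(out_dir, "screening.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  days <- prepare_analysis_days(scr$days, cohort$participants)
  .stage_msg("screen", t0)

  desc <- behavior_descriptives(days)
  utils::write.csv(desc$table, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(minutes = as.list(desc$geometric_mean_day),
         percent = as.list(desc$geometric_mean_pct)),
    file.path(out_dir, "geometric_mean_day.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  icc <- lapply(stats::setNames(nm = config$outcomes),
                function(oc) fit_unconditional(days, oc))
  jsonlite::write_json(
    lapply(icc, function(u) list(icc = u$icc,
                                 within_share_pct = u$within_share,
                                 tau0 = u$tau0, sigma = u$sigma,
                                 n_days = u$n_obs,
                                 n_participants = u$n_participants)),
    file.path(out_dir, "icc.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .stage_msg("icc", t0)

  plan <- .hypothesis_plan()
  plan <- plan[plan$outcome %in% config$outcomes, ]
  fits <- list()
  for (i in seq_len(nrow(plan))) {
    extra <- character()
    if (isTRUE(config$add_sleep_quality) && plan$ordering[i] == "H4") {
      extra <- c(extra, "sleep_quality")
    }
    if (isTRUE(config$add_exercised) && plan$ordering[i] != "H4") {
      extra <- c(extra, "exercised")
    }
    f <- fit_hypothesis_model(days, outcome = plan$outcome[i],
                              ordering = plan$ordering[i],
                              random_slope = config$random_slope,
                              extra = extra,
                              cse_centering = config$cse_centering,
                              zero_method = config$zero_method)
    message(sprintf("[stresscomp] model %s (%s, %s): random slope = %s%s",
                    plan$model[i], plan$outcome[i], plan$ordering[i],
                    f$random_slope,
                    if (f$converged) "" else " [optimizer messages]"))
    utils::write.csv(.model_csv(f),
                     file.path(out_dir, paste0("model_", plan$model[i], ".csv")),
                     row.names = FALSE)
    fits[[plan$model[i]]] <- f
  }
  .stage_msg("models", t0)

  realloc_tab <- NULL
  if (isTRUE(config$realloc$enabled)) {
    set.seed(config$seed)
    boot_seeds <- sample.int(2147483646L, length(config$outcomes))
    tabs <- list()
    for (k in seq_along(config$outcomes)) {
      oc <- config$outcomes[k]
      ref_model <- plan$model[plan$outcome == oc &
                                plan$ordering == config$realloc$ordering]
      slope <- fits[[ref_model]]$random_slope
      tabs[[oc]] <- bootstrap_delta_ci(
        days, outcome = oc, ordering = config$realloc$ordering,
        random_slope = slope,
        base = config$realloc$base,
        minutes = config$realloc$minutes,
        n_boot = config$realloc$n_boot, seed = boot_seeds[k],
        cse_centering = config$cse_centering,
        zero_method = config$zero_method)
    }
    realloc_tab <- do.call(rbind, lapply(tabs, as.data.frame))
    rownames(realloc_tab) <- NULL
    utils::write.csv(realloc_tab, file.path(out_dir, "reallocation.csv"),
                     row.names = FALSE)
    if (isTRUE(config$write_plot)) {
      p <- plot_reallocation(realloc_tab)
      ggplot2::ggsave(file.path(out_dir, "reallocation.png"), p,
                      width = 8, height = 5, dpi = 150)
    }
    .stage_msg("reallocate", t0)
  }

  manifest <- list(
    package = "stresscomp",
    package_version = as.character(utils::packageVersion("stresscomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  .stage_msg("done", t0)
  invisible(list(days = days, screening = scr$report, descriptives = desc,
                 icc = icc, fits = fits, reallocation = realloc_tab,
                 out_dir = out_dir))
}
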