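#!/usr/bin/env Rscript
# Thin command-line wrapper over the stresscomp package.
# Usage: Rscript scripts/pipeline.R <subcommand> [options]
# Subcommands: simulate | screen | fit | reallocate | report | all

suppressPackageStartupMessages({
  library(optparse)
  library(stresscomp)
})

args <- commandArgs(trailingOnly = TRUE)
sub <- if (length(args)) args[1] else "all"
rest <- args[-1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration file"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default %default]"),
  make_option("--out", type = "character", default = "stresscomp-output",
              help = "output directory [default %default]"),
  make_option("--set", type = "character", default = NULL, action = "store",
              help = "override a top-level config key, key=value (repeatable via commas)"),
  make_option("--show-config", action = "store_true", default = FALSE,
              dest = "show_config", help = "print the resolved config and exit")
))
opt <- parse_args(parser, args = rest)

config <- if (!is.null(opt$config)) {
  read_run_config(opt$config, seed = opt$seed)
} else {
  default_run_config(seed = opt$seed)
}
config$out_dir <- opt$out
if (!is.null(opt$set)) {
  for (kv in strsplit(opt$set, ",", fixed = TRUE)[[1]]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("--set expects key=value")
    val <- utils::type.convert(parts[2], as.is = TRUE)
    config[[parts[1]]] <- val
  }
}
if (isTRUE(opt$show_config)) {
  cat(yaml::as.yaml(config))
  quit(status = 0)
}

run_sub <- function(sub, config) {
  switch(
    sub,
    simulate = {
      gcfg <- do.call(generator_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$generator))
      write_cohort_csv(simulate_cohort(gcfg), config$out_dir)
      message("cohort CSVs written to ", config$out_dir)
    },
    screen = ,
    fit = ,
    reallocate = ,
    report = ,
    all = {
      if (sub %in% c("screen")) config$realloc$enabled <- FALSE
      if (sub == "reallocate") config$write_plot <- TRUE
      invisible(run_pipeline(config))
    },
    stop("unknown subcommand '", sub,
         "'; use simulate|screen|fit|reallocate|report|all")
  )
}
run_sub(sub, config)
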