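#!/usr/bin/env Rscript
# Thin command-line wrapper over mtphylo::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R --config FILE

suppressPackageStartupMessages({
  library(optparse)
  library(mtphylo)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", help = "YAML run configuration")
)))
if (is.null(opts$config)) stop("--config is required")

run <- run_pipeline(read_run_config(opts$config))
summary(run)
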