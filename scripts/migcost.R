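#!/usr/bin/env Rscript
# Command-line driver for the migcost pipeline:
#   Rscript scripts/migcost.R --mode all --seed 1 --out-dir results/run1

suppressPackageStartupMessages({
  library(optparse)
  library(migcost)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration path [default: packaged baseline]"),
  make_option("--mode", type = "character", default = "all",
              help = "simulate | summarise | cost | tornado | psa | all"),
  make_option("--seed", type = "integer", default = 1L,
              help = "RNG seed for the survey simulation and the PSA"),
  make_option("--n-draws", type = "integer", default = NULL, dest = "n_draws",
              help = "Monte Carlo draw count [default: configured value]"),
  make_option("--out-dir", type = "character", default = "migcost-output",
              dest = "out_dir", help = "output directory"),
  make_option("--delta", type = "double", default = NULL,
              help = "tornado variation range [default: configured value]"),
  make_option("--dump-draws", action = "store_true", default = FALSE,
              dest = "dump_draws", help = "also write per-draw PSA costs as CSV")
)))

status <- tryCatch({
  run_pipeline(config_path = opts$config, mode = opts$mode, seed = opts$seed,
               n_draws = opts$n_draws, out_dir = opts$out_dir,
               delta = opts$delta, dump_draws = opts$dump_draws)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
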