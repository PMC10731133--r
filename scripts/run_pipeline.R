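#!/usr/bin/env Rscript
# Thin command-line front end over osteomech::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [--preset reference|wellposed]
#                                       [--seed 1] [--out run_out]

suppressMessages({
  library(optparse)
  library(osteomech)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--preset", type = "character", default = "reference"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "run_out")
)))

cfg <- cohort_config(preset = opts$preset, seed = opts$seed)
run <- run_pipeline(cfg, output_dir = opts$out, verbose = TRUE)
writeLines(write_report(run))
cat(sprintf("\nartifacts written to %s (config %s)\n", opts$out,
            run$manifest$config_hash))
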