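#!/usr/bin/env Rscript
# Thin command-line entry point over the package: generates both synthetic
# studies and runs every analysis stage, writing all CSV/JSON outputs under
# --out. Deterministic for a fixed --seed.

suppressPackageStartupMessages({
  library(optparse)
  library(rejuvmet)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "pipeline_output")
)))

run_rejuvenation_pipeline(opts$out, seed = opts$seed)
message("pipeline outputs written to ", opts$out)
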