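#!/usr/bin/env Rscript
# Thin command-line wrapper: Rscript scripts/sgtn.R <subcommand> [options]
suppressPackageStartupMessages(library(sgtn))
quit(status = run_command(commandArgs(trailingOnly = TRUE)), save = "no")
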