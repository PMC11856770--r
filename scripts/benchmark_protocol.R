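#!/usr/bin/env Rscript
# Optional integration script: runs the full benchmark protocol (five
# repeats, 100 epochs) on the Indian Pines / Salinas / Pavia University
# cubes for users who have downloaded the MAT containers. Not executed by
# the test suite; expect hours of CPU time.
#
# Usage:
#   Rscript scripts/benchmark_protocol.R <dataset> <cube.mat> <gt.mat> [outdir]
# where <dataset> is one of ip | sa | pu.

suppressPackageStartupMessages(library(sgtn))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 3) {
  stop("usage: Rscript scripts/benchmark_protocol.R <ip|sa|pu> <cube> <gt> [outdir]")
}
dataset <- match.arg(args[1], c("ip", "sa", "pu"))
outdir <- if (length(args) >= 4) args[4] else file.path("benchmark_out", dataset)
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

conf <- switch(dataset,
  ip = list(s = 13L, fracs = c(0.10, 0.10), drop = "ip"),
  sa = list(s = 15L, fracs = c(0.01, 0.01), drop = "sa"),
  pu = list(s = 15L, fracs = c(0.01, 0.01), drop = NULL))

loaded <- load_cube(args[2], args[3], name = dataset)
cube <- loaded$cube
if (!is.null(conf$drop) && cube$band_count > 210)
  cube <- remove_bands(cube, default_band_drops(conf$drop))
cube <- normalize_cube(cube)

cfg <- sgtn_config(bands = cube$band_count, n_classes = loaded$gt$class_count,
                   s = conf$s, seed = 1L)
tspec <- train_spec(learning_rate = 0.001, batch_size = 64L, epochs = 100L,
                    seed = 1L)
summary <- repeat_experiment(cube, loaded$gt, cfg, tspec,
                             train_frac = conf$fracs[1],
                             val_frac = conf$fracs[2], n_repeats = 5L)

write.csv(summary$runs, file.path(outdir, "runs.csv"), row.names = FALSE)
write.csv(summary$metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
write.csv(summary$per_class, file.path(outdir, "per_class.csv"),
          row.names = FALSE)
print(summary$metrics)
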