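#!/usr/bin/env Rscript
# Thin command-line wrapper over the itraqr package.
#
#   Rscript scripts/itraqr.R <subcommand> [--config FILE] [--seed N]
#                            [--out DIR] [--jpf FILE,FILE,...]
#
# Subcommands: simulate, quantify, aggregate, classify, enrich, cluster,
# run-all. All subcommands are stages of run_pipeline(); each one runs
# the pipeline up to (and including) its stage using the same config.

suppressPackageStartupMessages({
  library(itraqr)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
  cat("usage: itraqr.R <simulate|quantify|aggregate|classify|enrich|",
      "cluster|run-all> [--config FILE] [--seed N] [--out DIR]",
      "[--jpf FILES]\n")
  quit(status = 0)
}
subcommand <- args[1]
parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "itraqr_out"),
  make_option("--jpf", type = "character", default = NULL,
              help = "comma-separated per-experiment .jpf files")
))
opt <- parse_args(parser, args = args[-1])

overrides <- list(out_dir = opt$out)
if (!is.null(opt$seed)) overrides$seed <- opt$seed
cfg <- if (!is.null(opt$config)) {
  do.call(read_run_config, c(list(opt$config), overrides))
} else if (!is.null(opt$jpf)) {
  run_config(sim = NULL, jpf_paths = trimws(strsplit(opt$jpf, ",")[[1]]),
             out_dir = opt$out, seed = opt$seed,
             null_mean = 1.02, null_sd = 0.10)
} else {
  run_config(sim = sim_config(seed = if (is.null(opt$seed)) 1L else
    opt$seed), out_dir = opt$out)
}

known <- c("simulate", "quantify", "aggregate", "classify", "enrich",
           "cluster", "run-all")
if (!subcommand %in% known)
  stop("unknown subcommand: ", subcommand)

# every stage's outputs are written by run_pipeline; single-stage
# subcommands simply report the relevant part of the manifest
manifest <- run_pipeline(cfg)
if (subcommand == "run-all") {
  print(manifest)
} else {
  stage <- c(simulate = "simulate", quantify = "quantify",
             aggregate = "aggregate", classify = "classify",
             enrich = "enrich", cluster = "cluster")[[subcommand]]
  st <- manifest$stages
  print(st[st$stage %in% c(stage, "filter", "catalogue")[
    if (stage == "aggregate") 1:3 else 1], ], row.names = FALSE)
  cat("outputs in", manifest$out_dir, "\n")
}
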