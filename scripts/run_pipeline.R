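#!/usr/bin/env Rscript

# Thin command-line wrapper over skewnet::run_pipeline(). Either run the
# bundled synthetic study world or point the four --csv-* flags at your own
# record CSVs.
#
#   Rscript scripts/run_pipeline.R --outdir runs/demo --seed 1
#   Rscript scripts/run_pipeline.R --outdir runs/field \
#     --registry registry.csv --copresence copresence.csv \
#     --interactions interactions.csv --reproduction reproduction.csv

suppressPackageStartupMessages({
  library(optparse)
  library(skewnet)
})

parser <- OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "skewnet-run"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-perm", type = "integer", default = 10000L, dest = "n_perm"),
  make_option("--n-boot", type = "integer", default = 100L, dest = "n_boot"),
  make_option("--min-traps", type = "double", default = 5, dest = "min_traps"),
  make_option("--n-groups", type = "integer", default = 25L, dest = "n_groups",
              help = "synthetic world size (ignored when CSVs are given)"),
  make_option("--coupling", type = "double", default = 1),
  make_option("--registry", type = "character", default = NULL),
  make_option("--copresence", type = "character", default = NULL),
  make_option("--interactions", type = "character", default = NULL),
  make_option("--reproduction", type = "character", default = NULL)))
opt <- parse_args(parser)

csvs <- opt[c("registry", "copresence", "interactions", "reproduction")]
data <- if (all(!vapply(csvs, is.null, logical(1)))) {
  csvs
} else {
  message("no input CSVs given: generating a synthetic study world")
  generate_colony_data(
    synthetic_config(n_groups = opt$n_groups, coupling = opt$coupling),
    seed = opt$seed)
}

res <- run_pipeline(data, outdir = opt$outdir, seed = opt$seed,
                    n_perm = opt$n_perm, n_boot = opt$n_boot,
                    min_traps = opt$min_traps)
message("run complete: ", normalizePath(res$outdir))
print(res$ladder)
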