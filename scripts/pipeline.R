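#!/usr/bin/env Rscript

# Thin shell entry point over the package functions.
#
#   Rscript scripts/pipeline.R simulate --out <dir> [--seed N] [--n-tips N]
#       [--grid-res R] [--drift R] [--mode sympatric|allopatric|peripatric|mixed]
#   Rscript scripts/pipeline.R run --tree <nwk> --ranges <dir|geojson>
#       [--traits <csv>] --out <dir> [--seed N] [--threshold X]
#       [--grid-res R] [--prob-cutoff X] [--n-perm N] [--mantel-mode M]
#   Rscript scripts/pipeline.R run --config <flat key=value file>
#   Rscript scripts/pipeline.R config-init            # print default config

suppressMessages(library(sympatree))

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args) >= 1) args[1] else "help"
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
num <- function(x) if (is.null(x)) NULL else as.numeric(x)

if (cmd == "simulate") {
  grid_res <- num(opt("--grid-res", "1"))
  cfg <- sim_config(
    n_tips = as.integer(opt("--n-tips", "123")),
    speciation_mode = opt("--mode", "mixed"),
    drift_rate = num(opt("--drift", "2")),
    grid = grid_spec(-180, 180, -60, 60, resolution = grid_res),
    seed = as.integer(opt("--seed", "1"))
  )
  out <- opt("--out", "sympatree-scenario")
  make_scenario(cfg, dir = out)
  cat("scenario written to", out, "\n")
} else if (cmd == "run") {
  cfg_path <- opt("--config")
  cfg <- if (!is.null(cfg_path)) {
    read_run_config(cfg_path)
  } else {
    run_config(
      tree = opt("--tree"), ranges = opt("--ranges"), traits = opt("--traits"),
      out = opt("--out", "sympatree-run"),
      overlap_threshold = num(opt("--threshold", "0.05")),
      grid = grid_spec(resolution = num(opt("--grid-res", "0.5"))),
      prob_cutoff = num(opt("--prob-cutoff", "0.5")),
      n_perm = as.integer(opt("--n-perm", "1000")),
      mantel_mode = opt("--mantel-mode", "plain"),
      seed = as.integer(opt("--seed", "1"))
    )
  }
  res <- run_pipeline(cfg)
  cat("pipeline outputs in", cfg$out, "\n")
} else if (cmd == "config-init") {
  cat(paste0(c("tree=tree.nwk", "ranges=grids", "traits=traits.csv",
               "out=sympatree-run", "overlap_threshold=0.05",
               "grid_lon_min=-180", "grid_lon_max=180", "grid_lat_min=-90",
               "grid_lat_max=90", "grid_resolution=0.5", "prob_cutoff=0.5",
               "n_perm=1000", "mantel_mode=plain", "seed=1"), collapse = "\n"),
      "\n")
} else {
  cat("usage: Rscript scripts/pipeline.R simulate|run|config-init [flags]\n")
  if (cmd != "help") quit(status = 1)
}
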