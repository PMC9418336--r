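#!/usr/bin/env Rscript
# Thin command-line wrapper over the smallfield package.
#
#   Rscript scripts/smallfield.R run      --seed 7 --out artifacts/
#   Rscript scripts/smallfield.R validate --matrix matrix.csv --mode proportions \
#                                         --merge active,fallow,rest
#
# `run` executes the seeded synthetic end-to-end demo and writes the QA and
# validation reports; `validate` ingests an error matrix CSV (counts with a
# `weights` column, or proportions) and prints the design-based report.

suppressPackageStartupMessages({
  library(optparse)
  library(smallfield)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "validate")) {
  stop("usage: smallfield.R <run|validate> [options]")
}
cmd <- args[1]

if (cmd == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1L),
    make_option("--size", type = "integer", default = 128L),
    make_option("--trees", type = "integer", default = 100L),
    make_option("--out", type = "character", default = "smallfield_run")
  )), args = args[-1])
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  cfg <- run_config(seed = opts$seed,
                    scene = list(nrow = opts$size, ncol = opts$size),
                    learner = list(n_trees = opts$trees))
  res <- run_end_to_end(cfg, log_path = file.path(opts$out, "run.jsonl"))
  write_ascii_grid(field_grid(res$map$values + 0, res$map$pixel_size),
                   file.path(opts$out, "classification.asc"))
  write_ascii_grid(res$noise$before, file.path(opts$out, "tsnoise_before.asc"))
  write_ascii_grid(res$noise$after, file.path(opts$out, "tsnoise_after.asc"))
  utils::write.csv(tidy(res$validation),
                   file.path(opts$out, "accuracy_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$grid_summary, file.path(opts$out, "grid_summary.csv"),
                   row.names = FALSE)
  print(glance(res$validation))
  print(tidy(res$validation))
} else {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--matrix", type = "character"),
    make_option("--mode", type = "character", default = "proportions"),
    make_option("--weights", type = "character", default = NULL,
                help = "comma-separated stratum weights (counts mode)"),
    make_option("--merge", type = "character", default = NULL,
                help = "comma-separated group index per class, e.g. 1,2,3,3,3,3,3")
  )), args = args[-1])
  m <- as.matrix(utils::read.csv(opts$matrix, row.names = 1,
                                 check.names = FALSE))
  est <- if (opts$mode == "proportions") {
    error_matrix_from_proportions(m)
  } else {
    W <- as.numeric(strsplit(opts$weights, ",")[[1]])
    error_matrix_from_counts(m, W)
  }
  if (!is.null(opts$merge)) {
    est <- merge_classes(est, as.integer(strsplit(opts$merge, ",")[[1]]))
  }
  print(est)
  print(area_report(est))
}
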