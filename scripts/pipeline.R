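#!/usr/bin/env Rscript
# Thin command-line wrapper over thrscore::run_thr_pipeline().
#   Rscript scripts/pipeline.R --seed 7 --out results/run7 [--n 174]
#     [--cutoff consensus|<number>] [--replicates 1000] [--nri-b 200]

suppressPackageStartupMessages({
  library(optparse)
  library(thrscore)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L,
              help = "seed for every random draw [default %default]"),
  make_option("--out", type = "character", default = "results/pipeline",
              help = "output directory [default %default]"),
  make_option("--n", type = "integer", default = 174L,
              help = "synthetic cohort size [default %default]"),
  make_option("--cutoff", type = "character", default = "consensus",
              help = "'consensus' or a fixed numeric cutoff [default %default]"),
  make_option("--replicates", type = "integer", default = 1000L,
              help = "consensus subsample replicates [default %default]"),
  make_option("--nri-b", type = "integer", default = 200L, dest = "nri_b",
              help = "bootstrap replicates for NRI/IDI [default %default]"),
  make_option("--clinical", type = "character", default = NULL,
              help = "optional clinical CSV (with --lesions, skips simulation)"),
  make_option("--lesions", type = "character", default = NULL,
              help = "optional lesion CSV"))))

cutoff <- if (identical(opts$cutoff, "consensus")) "consensus" else
  as.numeric(opts$cutoff)
cohort <- NULL
if (!is.null(opts$clinical) || !is.null(opts$lesions)) {
  if (is.null(opts$clinical) || is.null(opts$lesions)) {
    stop("--clinical and --lesions must be given together", call. = FALSE)
  }
  cohort <- read_cohort(opts$clinical, opts$lesions, provenance = "cli")
}

status <- tryCatch({
  run_thr_pipeline(opts$out, sim_config(n_patients = opts$n, seed = opts$seed),
                   cohort = cohort, cutoff = cutoff,
                   replicates = opts$replicates, nri_B = opts$nri_b)
  0L
}, error = function(e) {
  message("pipeline error: ", conditionMessage(e))
  1L
})
quit(status = status)
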