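#!/usr/bin/env Rscript
# Analyzes the comet runs written by 01_simulate.R: spot detection, LAP
# linking, process-inclusion filtering, angle-threshold classification and
# per-axon summaries.  Prints the recovered plus-end-out fraction per
# condition next to the generative value.

suppressMessages(library(neuritemt))
root <- "results/runs"
runs <- list.files(root, pattern = "^comets_", full.names = TRUE)
if (!length(runs)) stop("no comet runs found; run analysis/01_simulate.R first")

for (dir in runs) {
  res <- run_analyze(dir, center = "estimate")
  cfg <- load_config(file.path(dir, "config.yaml"))
  agg <- res$aggregate
  cat(sprintf("%-22s true f_out %.2f | pooled %.3f | per-axon mean %.3f +/- %.3f (n = %d axons, %d comets)\n",
              basename(dir), cfg$simulate$f_plus_end_out, agg$pooled_f_out,
              agg$mean_f_out, agg$sd_f_out, agg$n_axons, agg$n_comets))
}
cat("per-run calls.csv / summaries.csv / condition_aggregate.csv written.\n")
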