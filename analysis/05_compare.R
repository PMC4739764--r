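#!/usr/bin/env Rscript
# Statistical comparisons between conditions: Mann-Whitney U on per-axon
# plus-end-out fractions for every pair of comet conditions, and Fisher's
# exact test on the tip-accumulation phenotype counts of the
# tip_accumulated vs scattered runs.  Assembles report bundles under
# results/reports/.

suppressMessages(library(neuritemt))
root <- "results/runs"
out_root <- "results/reports"

comet_runs <- list.files(root, pattern = "^comets_", full.names = TRUE)
if (length(comet_runs) >= 2) {
  for (i in seq_len(length(comet_runs) - 1)) for (j in (i + 1):length(comet_runs)) {
    a <- comet_runs[i]; b <- comet_runs[j]
    out <- file.path(out_root, paste(basename(a), "vs", basename(b), sep = "_"))
    res <- run_compare(a, b, out)
    for (nm in names(res$stats))
      cat(sprintf("%-45s p = %.4g (%s)\n", nm, res$stats[[nm]]$p_value,
                  res$stats[[nm]]$method))
  }
}

ta <- file.path(root, "tip_tip_accumulated")
sc <- file.path(root, "tip_scattered")
if (dir.exists(ta) && dir.exists(sc)) {
  res <- run_compare(ta, sc, file.path(out_root, "tip_accumulated_vs_scattered"))
  for (nm in names(res$stats))
    cat(sprintf("%-45s p = %.4g (%s)\n", nm, res$stats[[nm]]$p_value,
                res$stats[[nm]]$method))
}
cat("reports written under", out_root, "\n")
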