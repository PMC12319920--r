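#!/usr/bin/env Rscript
# Stage 3: diffusion-time dependence of MD and MK in the S1FL-like region.
#
# Pools the ROI means into MD(Delta) and MK(Delta) curves per condition and
# laterality, fits the 1D / 2D-3D structural-disorder forms and (for MK)
# the two-compartment exchange model, and compares them by AICc. Output:
# results/timedep_comparison.tsv in the shape of the usual model-comparison
# tables (parameters +/- SE, AICc, winner per curve).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

roi_path <- file.path(RESULTS_DIR, "roi_table.tsv")
if (!file.exists(roi_path))
  stop("run analysis/02_estimate.R first (missing ", roi_path, ")")
roi <- read.table(roi_path, sep = "\t", header = TRUE)

tabs <- list()
for (lat in c("contra", "ipsi")) {
  curves <- list()
  for (metric in c("MD", "MK")) for (cond in c("rest", "stimulus")) {
    ss <- roi[roi$roi == "s1fl" & roi$laterality == lat &
                roi$metric == metric & roi$condition == cond, ]
    ds <- sort(unique(ss$delta_big))
    mn <- vapply(ds, function(d) mean(ss$mean[ss$delta_big == d]), numeric(1))
    se <- vapply(ds, function(d) {
      x <- ss$mean[ss$delta_big == d]; sd(x) / sqrt(length(x))
    }, numeric(1))
    curves[[length(curves) + 1L]] <-
      timedep_curve(ds, mn, se, metric = metric, condition = cond,
                    laterality = lat)
  }
  cmp <- compare_models(curves)
  cat(sprintf("\n== S1FL %slateral ==\n", lat))
  print(cmp)
  kf <- cmp$table[cmp$table$model == "karger_mk", ]
  cat("Exchange-model fits:\n")
  for (r in seq_len(nrow(kf)))
    cat(sprintf("  %s: %s\n", kf$condition[r], kf$params[r]))
  tabs[[lat]] <- cmp$table
}
out <- do.call(rbind, tabs)
write.table(out, file.path(RESULTS_DIR, "timedep_comparison.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nComparison table ->",
    file.path(RESULTS_DIR, "timedep_comparison.tsv"), "\n")
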