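#!/usr/bin/env Rscript
# Stage 4: ROI-level rest-vs-stimulus statistics.
#
# Diffusion arm: per-ROI percent changes per diffusion time, the signed
# maximum-amplitude change, mixed-effects condition tests (condition +
# diffusion time fixed; run + subject random) and BH-FDR within each
# metric. BOLD arm: 0.01 Hz high-pass, epoch normalization to the 14 s
# pre-stimulus baseline, condition-averaged amplitudes, condition test and
# FDR across ROIs. Outputs: results/change_report.tsv, results/bold.tsv.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

roi_path <- file.path(RESULTS_DIR, "roi_table.tsv")
if (!file.exists(roi_path))
  stop("run analysis/02_estimate.R first (missing ", roi_path, ")")
roi <- read.table(roi_path, sep = "\t", header = TRUE)
study <- build_study()

reports <- list()
for (lat in c("contra", "ipsi")) {
  cat(sprintf("\n== %slateral ROIs ==\n", lat))
  rep_ch <- change_report(roi[roi$laterality == lat, ])
  print(rep_ch)
  s <- rep_ch$summary; s$laterality <- lat
  reports[[lat]] <- s
}
changes <- do.call(rbind, reports)
write.table(changes, file.path(RESULTS_DIR, "change_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("\n== BOLD condition averages ==\n")
bold_rows <- list()
box <- as.numeric(study$bold_schedule$condition == "stimulus")
for (rid in study$runs$run_id) {
  rr <- study$runs[study$runs$run_id == rid, ]
  series <- study_bold_series(study, rid)
  for (nm in names(study$roi_names)) {
    vox <- study$labels == study$roi_names[[nm]]
    ts <- highpass_dct(colMeans(series[vox, , drop = FALSE]),
                       study$bold_design$tr, protect = box)
    avg <- bold_condition_average(ts, study$bold_design)
    bold_rows[[length(bold_rows) + 1L]] <- data.frame(
      roi = nm, run = rid, subject = rr$rat, laterality = rr$laterality,
      condition = c("rest", "stimulus"),
      mean = c(avg$rest_mean, avg$stim_mean))
  }
}
bold_rows <- do.call(rbind, bold_rows)
bold_out <- list()
for (lat in c("contra", "ipsi")) {
  sub <- bold_rows[bold_rows$laterality == lat, ]
  res <- do.call(rbind, lapply(unique(sub$roi), function(nm) {
    ss <- sub[sub$roi == nm, ]
    r <- mean(ss$mean[ss$condition == "rest"])
    s <- mean(ss$mean[ss$condition == "stimulus"])
    p <- tryCatch(condition_mixed_test(ss)$p, error = function(e) NA_real_)
    data.frame(roi = nm, laterality = lat,
               change_pct = percent_change(r, s), p = p)
  }))
  res$q <- fdr_adjust(res$p)
  for (r in seq_len(nrow(res)))
    cat(sprintf("  %-5s %-6s %+7.3f%%  q = %.3g\n", res$roi[r], lat,
                res$change_pct[r], res$q[r]))
  bold_out[[lat]] <- res
}
write.table(do.call(rbind, bold_out), file.path(RESULTS_DIR, "bold.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nReports -> results/change_report.tsv, results/bold.tsv\n")
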