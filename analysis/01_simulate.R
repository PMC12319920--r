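#!/usr/bin/env Rscript
# Stage 1: assemble the synthetic study and record its design bookkeeping.
#
# The study mirrors the acquisition protocol: 10 rats, 5 functional runs
# each (two rats with 4), forepaw alternating between runs and starting
# side alternating between rats; per run five diffusion acquisitions
# (Delta = 9.5/15/20/25/30 ms, 84 volumes in 3 epochs of 28 s rest / 28 s
# stimulus at TR = 2 s) and one BOLD series (336 volumes, 6 epochs,
# TR = 1 s). Volumes are generated lazily; this stage writes the manifest
# and the text-format fixtures (gradient tables, schedules, labels).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

study <- build_study()
print(study)

sched <- study$dwi_schedule
cat(sprintf("Diffusion schedule: %d volumes (%d rest / %d stimulus)\n",
            nrow(sched), sum(sched$condition == "rest"),
            sum(sched$condition == "stimulus")))
cat(sprintf("BOLD schedule: %d volumes (%d per condition)\n",
            nrow(study$bold_schedule),
            sum(study$bold_schedule$condition == "rest")))
cat(sprintf("Run manifest: %d runs (%d contralateral, %d ipsilateral)\n",
            nrow(study$runs), sum(study$runs$laterality == "contra"),
            sum(study$runs$laterality == "ipsi")))

out <- file.path(RESULTS_DIR, "study")
write_study(study, out, materialize = FALSE)
cat("Fixtures and manifest written under", out, "\n")
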