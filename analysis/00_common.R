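# Shared setup for the analysis scripts: one master seed, one study
# configuration, results/ directory. Every script rebuilds the (lazy) study
# object deterministically from these, so the scripts can be run
# independently or in sequence.

suppressPackageStartupMessages(library(dfkurtosis))

MASTER_SEED <- 20260928L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_config <- default_study_config()
build_study <- function() make_study(study_config, seed = MASTER_SEED)
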