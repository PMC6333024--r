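# Shared settings for the analysis drivers. Run the scripts in order from
# the repository root: Rscript analysis/01_simulate.R, then 02..05.
suppressMessages(library(gsbreedr))

MASTER_SEED <- 2026L
N_MARKERS <- 4000L          # panel width; the full study scale (21,211) runs
                            # the same way, this keeps a laptop run in minutes
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

msg <- function(...) cat(sprintf(...), "\n")
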