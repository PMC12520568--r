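## Shared configuration for the numbered analysis drivers.
## Intermediates (large per-site tables) live under scratch/; the small
## summary tables each driver reports go under results/.

library(duomod)
library(data.table)

SCENARIO <- simulation_scenario(seed = 42L)
PROTOCOL_M <- "CD"    # 5mC assay
PROTOCOL_H <- "ACE"   # 5hmC assay

SCRATCH <- "scratch/pipeline"
RESULTS <- "results"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

stage_path <- function(...) file.path(SCRATCH, paste0(...))
result_path <- function(...) file.path(RESULTS, paste0(...))
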