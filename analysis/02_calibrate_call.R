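#!/usr/bin/env Rscript

## Stage 2: spike-in calibration and binomial site calling.
##
## Pools each assay's libraries over the spike-in contigs to estimate its
## false-positive and conversion rate, then calls modified cytosines per
## condition (replicate-pooled counts) with the one-sided binomial test,
## BH correction at q <= 0.05 and coverage >= 5.

source("analysis/00_config.R")

assays <- c(m = PROTOCOL_M, h = PROTOCOL_H)
calib_rows <- list()
for (a in names(assays)) {
  reps <- rbindlist(lapply(
    Sys.glob(stage_path(sprintf("pileup_%s_*_rep*.tsv", a))), read_pileup))
  pooled <- reps[, .(count_C = sum(count_C), count_T = sum(count_T)),
                 by = .(contig, pos0, strand, context)]
  cal <- calibrate(pooled, assays[[a]])
  calib_rows[[a]] <- data.table(
    assay = a, protocol = assays[[a]],
    false_positive_rate = cal$false_positive_rate,
    conversion_rate = cal$conversion_rate,
    retention_rate = cal$retention_rate)
  for (cond in c("WT", "AD")) {
    cp <- rbindlist(lapply(
      Sys.glob(stage_path(sprintf("pileup_%s_%s_rep*.tsv", a, cond))),
      read_pileup))
    cp <- cp[, .(count_C = sum(count_C), count_T = sum(count_T)),
             by = .(contig, pos0, strand, context)]
    calls <- call_sites(cp, cal)
    fwrite(calls, stage_path(sprintf("calls_%s_%s.tsv", a, cond)),
           sep = "\t", na = "NA")
    message(sprintf("%s/%s: %d sites tested, %.1f%% called",
                    assays[[a]], cond, nrow(calls), 100 * mean(calls$called)))
  }
}
calibration <- rbindlist(calib_rows)
fwrite(calibration, result_path("calibration.tsv"), sep = "\t")
message(sprintf(
  "calibration: CD-seq 5hmC conversion %.1f%%, retention %.1f%%; ACE-seq false positives %.2f%%",
  100 * calibration[assay == "m", conversion_rate],
  100 * calibration[assay == "m", retention_rate],
  100 * calibration[assay == "h", false_positive_rate]))
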