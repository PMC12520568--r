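#!/usr/bin/env Rscript

## Stage 1: generate the synthetic two-condition study.
##
## Builds a 1 Mb genome with 200 genes and CpG-rich promoters, a WT-like
## and an AD-like methylome (gene-body 5hmC reduced 0.6x, eight planted
## hyper-methylated regions), both fully modified spike-ins at 0.5% mass,
## and assay-converted pileups: CD-seq for 5mC and ACE-seq for 5hmC, two
## replicates per condition at 30x.

source("analysis/00_config.R")

sim <- generate_scenario(SCENARIO)
write_genome_fasta(sim$genome, stage_path("genome.fa"))
write_genes_bed(sim$genes, stage_path("genes.bed"))
fwrite(sim$truth, stage_path("planted_truth.tsv"), sep = "\t")
for (cond in c("WT", "AD"))
  fwrite(sim$methylome[[cond]], stage_path("methylome_", cond, ".tsv"),
         sep = "\t", na = "NA")

depths <- c(chr1 = SCENARIO$depth, spikein_depths(SCENARIO))
assays <- c(m = PROTOCOL_M, h = PROTOCOL_H)
k <- 0L
for (a in names(assays)) for (cond in c("WT", "AD"))
  for (r in seq_len(SCENARIO$n_rep)) {
    k <- k + 1L
    p <- simulate_pileups(sim$methylome[[cond]], assays[[a]], depth = depths,
                          seed = SCENARIO$seed + 17L * k)
    write_pileup(p, stage_path(sprintf("pileup_%s_%s_rep%d.tsv", a, cond, r)))
  }

wt <- sim$methylome$WT
message(sprintf(
  "simulated %d cytosine sites (%d CpG); WT gene-body 5hmC mean %.3f vs AD %.3f; %d planted regions",
  nrow(wt), sum(wt$context == "CpG", na.rm = TRUE),
  wt[feature == "gene_body" & context == "CpG", mean(h)],
  sim$methylome$AD[feature == "gene_body" & context == "CpG", mean(h)],
  nrow(sim$truth)))
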