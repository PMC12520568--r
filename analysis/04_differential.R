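#!/usr/bin/env Rscript

## Stage 4: differential sites, regions, and gene classes.
##
## Site-level two-group tests per assay (significant: p < 0.05 and
## |difference| >= 0.1), greedy segmentation into DMR/DhMR under the
## region criteria (>= 10 member CpGs, |mean difference| >= 0.1, inter-CpG
## gaps < 300 bp, MWU p < 0.001), hyper/hypo classification, DMC/DhMC
## intersection and region-to-gene mapping.

source("analysis/00_config.R")

genes <- read_genes_bed(stage_path("genes.bed"))
reps <- function(a, cond)
  lapply(Sys.glob(stage_path(sprintf("pileup_%s_%s_rep*.tsv", a, cond))),
         read_pileup)

diffs <- list(); regions <- list()
for (a in c("m", "h")) {
  diffs[[a]] <- test_dmc(reps(a, "WT"), reps(a, "AD"))
  regions[[a]] <- call_regions(diffs[[a]])
  stopifnot(all(validate_regions(regions[[a]])))
  fwrite(regions[[a]], result_path("regions_", a, ".tsv"), sep = "\t")
  counts <- attr(classify_direction(regions[[a]]), "counts")
  message(sprintf("%s-assay: %d significant sites; %d regions (%d hyper / %d hypo)",
                  a, sum(diffs[[a]]$significant), nrow(regions[[a]]),
                  counts[["hyper"]], counts[["hypo"]]))
}

classes <- intersect_classes(diffs$m, diffs$h)
direction_counts <- rbindlist(lapply(c("m", "h"), function(a) {
  counts <- attr(classify_direction(regions[[a]]), "counts")
  data.table(assay = a, hyper = counts[["hyper"]], hypo = counts[["hypo"]],
             dmc = if (a == "m") classes$counts[["dmc"]] else
               classes$counts[["dhmc"]],
             dual_sites = classes$counts[["both"]])
}))
fwrite(direction_counts, result_path("differential_counts.tsv"), sep = "\t")

gene_classes <- map_to_genes(regions$m, regions$h, genes)
fwrite(gene_classes, result_path("gene_classes.tsv"), sep = "\t")
message(sprintf("DMC/DhMC overlap: %d dual sites of %d DMC and %d DhMC; %d DMG, %d DhMG (%d dual)",
                classes$counts[["both"]], classes$counts[["dmc"]],
                classes$counts[["dhmc"]], sum(gene_classes$dmg),
                sum(gene_classes$dhmg), sum(gene_classes$dmhmg)))
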