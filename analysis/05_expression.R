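#!/usr/bin/env Rscript

## Stage 5: expression association.
##
## Simulates negative-binomial expression counts coupled to the per-gene
## modification levels (positive in 5hmC, negative in 5mC), runs the
## two-group differential-expression surrogate (DEG: p < 0.05 and
## |log2 FC| > 0.58), summarises per-gene modification-expression
## correlation signs, and reports the DMG/DhMG/DEG overlap.

source("analysis/00_config.R")

genes <- read_genes_bed(stage_path("genes.bed"))
methylome <- lapply(c(WT = "WT", AD = "AD"), function(cond)
  fread(stage_path("methylome_", cond, ".tsv"), na.strings = "NA"))
gene_mod <- lapply(methylome, gene_true_modification, genes = genes)

expr <- simulate_expression(gene_mod, SCENARIO, seed = SCENARIO$seed + 9000L)
fwrite(as.data.table(expr$counts, keep.rownames = "gene_id"),
       stage_path("expression_counts.tsv"), sep = "\t")

de <- differential_expression(expr$counts, expr$condition)
fwrite(de, result_path("expression_de.tsv"), sep = "\t")

n_cpg <- list(m_prom = gene_mod$WT$n_cpg_prom, h_prom = gene_mod$WT$n_cpg_prom,
              m_body = gene_mod$WT$n_cpg_body, h_body = gene_mod$WT$n_cpg_body)
cor_summary <- correlation_sign_summary(expr$mod, expr$counts, n_cpg = n_cpg)
fwrite(cor_summary, result_path("correlation_summary.tsv"), sep = "\t")
message(paste(sprintf("%s: %.0f%% positive / %.0f%% negative",
                      cor_summary$covariate, 100 * cor_summary$prop_positive,
                      100 * cor_summary$prop_negative), collapse = "; "))

gene_classes <- fread(result_path("gene_classes.tsv"))
overlap <- overlap_report(gene_classes[dmg == TRUE, gene_id],
                          gene_classes[dhmg == TRUE, gene_id],
                          de[deg == TRUE, gene_id])
fwrite(data.table(cell = names(overlap), n = as.integer(overlap)),
       result_path("overlap_dmg_dhmg_deg.tsv"), sep = "\t")
message(sprintf("%d DEG; DhMG-DEG overlap %d (+%d also DMG) of %d genes in any class",
                sum(de$deg), overlap[["dhmg_deg"]], overlap[["all_three"]],
                overlap[["union"]]))
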