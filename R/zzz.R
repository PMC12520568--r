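#' duomod: subtraction-free dual profiling of 5mC and 5hmC
#'
#' See the methods vignette (`vignettes/duomod-methods.Rmd` in the source
#' tree) for the model, the synthetic study design and the numerical
#' choices.
#'
#' @import data.table
#' @importFrom stats pbinom pnorm pt rbeta rbinom rnbinom rnorm rpois runif
#' @importFrom stats p.adjust setNames var sd cor wilcox.test
#' @importFrom methods is
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "contig", "pos0", "strand", "context", "count_C",
  "count_T", "coverage", "p_value", "q_value", "called", "feature", "m", "h",
  "gene_id", "start", "end", "tss", "score", "level", "level_m", "level_h",
  "level_5mC", "level_5hmC", "coverage_m", "coverage_h", "called_m",
  "called_h", "n1", "n2", "count_C_1", "count_C_2", "count_T_1", "count_T_2",
  "mu_g1", "mu_g2", "diff", "p_pool", "se", "z", "significant", "run",
  "mean_diff", "direction", "log2_fc", "deg", "dmg", "dhmg", "dmhmg",
  "condition", "effect", "n_sites", "assay", "sign", "mean_level", "n_cpg"
))
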