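## Differential expression surrogate, per-gene modification-expression
## correlation, and DMG/DhMG/DEG overlap reporting.

#' Library-size-normalised log2 counts per million
#'
#' @param counts Genes x samples count matrix.
#' @return log2(CPM + 1) matrix.
#' @export
log2_cpm <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample with zero library size")
  log2(t(t(counts) / libs) * 1e6 + 1)
}

#' Differential expression between two groups
#'
#' Per-gene Welch t-test on log2(CPM + 1) with the log2 fold-change taken
#' as the difference of group means on that scale (a simple surrogate for
#' shrinkage-based count models, swappable behind this interface).  A gene
#' is differentially expressed when `p < alpha` and `|log2_fc| > lfc_min`
#' (conjunctive).  All-zero genes are excluded and counted.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor/character of length `ncol(counts)` with two levels;
#'   the second level is the condition (fold-changes are condition minus
#'   reference).
#' @param alpha P-value threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.58,
#'   i.e. a 1.5-fold change).
#' @return `data.table` with `gene_id`, group means, `log2_fc`, `p_value`,
#'   `deg`; attribute `n_excluded_zero` counts dropped all-zero genes.
#' @export
differential_expression <- function(counts, groups, alpha = 0.05,
                                    lfc_min = 0.58) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(counts))
  if (min(table(groups)) < 2L)
    stop("need at least 2 replicates per group")
  keep <- rowSums(counts) > 0
  n_zero <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  l <- log2_cpm(counts)
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(l[, i1, drop = FALSE])
  m2 <- rowMeans(l[, i2, drop = FALSE])
  v1 <- apply(l[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(l[, i2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 == 0, 0, (m2 - m1) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  out <- data.table::data.table(
    gene_id = if (!is.null(rownames(counts))) rownames(counts) else
      as.character(seq_len(nrow(counts))),
    mean_g1 = m1, mean_g2 = m2, log2_fc = m2 - m1, p_value = p)
  out[, deg := p_value < alpha & abs(log2_fc) > lfc_min]
  data.table::setattr(out, "n_excluded_zero", n_zero)
  out[]
}

#' Per-gene correlation between modification level and expression
#'
#' Pearson correlation across samples, per gene, between a modification
#' covariate (e.g. gene-body 5hmC) and log2(CPM + 1) expression.  Genes
#' with too few informative CpGs or zero variance in either variable are
#' reported as `NA` and excluded from the sign summary.
#'
#' @param mod Genes x samples matrix of modification levels.
#' @param expr Genes x samples expression count or log-expression matrix
#'   (counts are log2-CPM transformed when all entries are non-negative
#'   integers).
#' @param n_cpg Optional per-gene informative-CpG counts.
#' @param min_cpg Minimum informative CpGs per gene (default 5).
#' @return `data.table` with `gene_id`, `correlation`; attribute
#'   `sign_summary` gives the proportion of positive and negative genes.
#' @export
correlate_modification_expression <- function(mod, expr, n_cpg = NULL,
                                              min_cpg = 5L) {
  stopifnot(identical(dim(mod), dim(expr)))
  if (all(expr >= 0) && all(expr == round(expr))) expr <- log2_cpm(expr)
  r <- vapply(seq_len(nrow(mod)), function(i) {
    x <- mod[i, ]; y <- expr[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (!is.null(n_cpg)) r[n_cpg < min_cpg] <- NA_real_
  out <- data.table::data.table(
    gene_id = if (!is.null(rownames(mod))) rownames(mod) else
      as.character(seq_len(nrow(mod))),
    correlation = r)
  ok <- !is.na(r)
  data.table::setattr(out, "sign_summary", c(
    prop_positive = if (any(ok)) mean(r[ok] > 0) else NA_real_,
    prop_negative = if (any(ok)) mean(r[ok] < 0) else NA_real_,
    n_informative = sum(ok)))
  out[]
}

#' Sign summary of modification-expression correlations per assay/feature
#'
#' Runs [correlate_modification_expression()] for each covariate matrix in
#' `mod_list` and tabulates the proportion of positively and negatively
#' correlated genes.
#'
#' @param mod_list Named list of genes x samples modification matrices
#'   (e.g. `m_prom`, `m_body`, `h_prom`, `h_body`).
#' @param expr Genes x samples expression matrix.
#' @param n_cpg Optional named list of per-gene CpG counts per covariate.
#' @param min_cpg Minimum informative CpGs.
#' @return `data.table` with `covariate`, `prop_positive`, `prop_negative`,
#'   `n_informative`.
#' @export
correlation_sign_summary <- function(mod_list, expr, n_cpg = NULL,
                                     min_cpg = 5L) {
  data.table::rbindlist(lapply(names(mod_list), function(nm) {
    res <- correlate_modification_expression(
      mod_list[[nm]], expr,
      n_cpg = if (!is.null(n_cpg)) n_cpg[[nm]] else NULL,
      min_cpg = min_cpg)
    s <- attr(res, "sign_summary")
    data.table::data.table(covariate = nm,
                           prop_positive = s[["prop_positive"]],
                           prop_negative = s[["prop_negative"]],
                           n_informative = s[["n_informative"]])
  }))
}

#' Three-way overlap of DMG, DhMG and DEG sets
#'
#' Exact set arithmetic over a shared gene universe: all seven disjoint
#' intersection cells plus the union size.
#'
#' @param dmg,dhmg,deg Character vectors of gene ids.
#' @return Named integer vector of the seven disjoint cells and `union`.
#' @export
overlap_report <- function(dmg, dhmg, deg) {
  dmg <- unique(dmg); dhmg <- unique(dhmg); deg <- unique(deg)
  u <- union(union(dmg, dhmg), deg)
  inA <- u %in% dmg; inB <- u %in% dhmg; inC <- u %in% deg
  c(dmg_only = sum(inA & !inB & !inC),
    dhmg_only = sum(!inA & inB & !inC),
    deg_only = sum(!inA & !inB & inC),
    dmg_dhmg = sum(inA & inB & !inC),
    dmg_deg = sum(inA & !inB & inC),
    dhmg_deg = sum(!inA & inB & inC),
    all_three = sum(inA & inB & inC),
    union = length(u))
}
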