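## Subtraction-free pairing of 5mC and 5hmC calls, genomic-feature
## annotation and feature-level summaries.

.genome_chars <- function(genome, contig) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!(contig %in% names(genome))) return(NULL)
    return(strsplit(as.character(genome[[contig]]), "")[[1]])
  }
  genome[[contig]]
}

#' Join 5mC and 5hmC site calls into a paired, subtraction-free table
#'
#' Inner join on `(contig, pos0, strand)`.  Because the two levels come
#' from different libraries there is no constraint forcing
#' `level_5mC + level_5hmC <= 1` at finite coverage; each level is an
#' independent estimate in \[0,1\].  Sites present in only one input are
#' returned in side tables with their counts reported.
#'
#' @param calls_m,calls_h [call_sites()] outputs for the 5mC assay (CD/CT)
#'   and the 5hmC assay (ACE/TAB).
#' @return List of class `paired_sites` with `paired`, `only_m`, `only_h`.
#' @export
pair_sites <- function(calls_m, calls_h) {
  cm <- sort(unique(calls_m$contig))
  ch <- sort(unique(calls_h$contig))
  if (!identical(cm, ch))
    stop("contig name mismatch between inputs: only in 5mC calls {",
         paste(setdiff(cm, ch), collapse = ","), "}; only in 5hmC calls {",
         paste(setdiff(ch, cm), collapse = ","), "}")
  m <- data.table::as.data.table(calls_m)
  h <- data.table::as.data.table(calls_h)
  key <- c("contig", "pos0", "strand")
  paired <- merge(
    m[, .(contig, pos0, strand, context,
          level_5mC = raw_level, coverage_m = coverage, called_m = called)],
    h[, .(contig, pos0, strand,
          level_5hmC = raw_level, coverage_h = coverage, called_h = called)],
    by = key)
  data.table::setorderv(paired, key)
  only_m <- m[!h, on = key]
  only_h <- h[!m, on = key]
  message(sprintf("paired %d sites (%d only in 5mC input, %d only in 5hmC input)",
                  nrow(paired), nrow(only_m), nrow(only_h)))
  structure(list(paired = paired, only_m = only_m, only_h = only_h),
            class = "paired_sites")
}

#' @export
print.paired_sites <- function(x, ...) {
  cat(sprintf("<paired_sites> %d paired, %d 5mC-only, %d 5hmC-only\n",
              nrow(x$paired), nrow(x$only_m), nrow(x$only_h)))
  invisible(x)
}

#' Subtraction estimator of 5mC (for the comparison report only)
#'
#' The legacy estimate obtained by subtracting a 5hmC assay level from a
#' bisulfite level that counts both marks.  Explicitly allowed to be
#' negative: at finite depth the two noisy estimates need not be ordered,
#' which is the artifact the paired direct assays avoid.
#'
#' @param bs_level BS-seq level (counts 5mC + 5hmC).
#' @param h_level 5hmC assay level.
#' @return Signed value `bs_level - h_level`.
#' @export
subtraction_estimate <- function(bs_level, h_level) {
  stopifnot(all(bs_level >= 0 & bs_level <= 1),
            all(h_level >= 0 & h_level <= 1))
  bs_level - h_level
}

#' Annotate trinucleotide context from a genome
#'
#' Strand-aware: a site is CpG if the next base 3' on its own strand is G,
#' CHG if the base after that is G, else CHH; positions too close to the
#' contig end for the needed bases are labeled `NA`.
#'
#' @param sites Table with `contig`, `pos0` (0-based), `strand`.
#' @param genome Named list of character base vectors or a
#'   `Biostrings::DNAStringSet`.
#' @return Character vector of contexts aligned with `sites` rows.
#' @export
annotate_context <- function(sites, genome) {
  out <- rep(NA_character_, nrow(sites))
  for (ct in unique(sites$contig)) {
    chars <- .genome_chars(genome, ct)
    if (is.null(chars)) stop("contig '", ct, "' not present in genome")
    rows <- which(sites$contig == ct)
    i <- sites$pos0[rows] + 1L                 # 1-based
    if (any(i < 1L | i > length(chars)))
      stop("positions outside contig '", ct, "' bounds")
    plus <- sites$strand[rows] == "+"
    at <- function(j) ifelse(j >= 1L & j <= length(chars), chars[pmax(j, 1L)], NA)
    n1 <- ifelse(plus, at(i + 1L), at(i - 1L))
    n2 <- ifelse(plus, at(i + 2L), at(i - 2L))
    want <- ifelse(plus, "G", "C")             # G downstream == C on minus
    out[rows] <- ifelse(!is.na(n1) & n1 == want, "CpG",
      ifelse(is.na(n1), NA,
        ifelse(!is.na(n2) & n2 == want, "CHG",
          ifelse(is.na(n2), NA, "CHH"))))
  }
  out
}

.gene_granges <- function(genes, feature = c("promoter", "gene_body")) {
  feature <- match.arg(feature)
  if (feature == "promoter") {
    start0 <- pmax(genes$tss - 1000L, 0L)
    end0 <- genes$tss + 1001L                  # [tss-1kb, tss+1kb], half-open
  } else {
    start0 <- genes$start
    end0 <- genes$end
  }
  GenomicRanges::GRanges(genes$contig,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         gene_id = genes$gene_id)
}

#' Assign each site to promoter, gene body or intergenic space
#'
#' Promoters are TSS +/- 1 kb (strand-aware via the TSS position); a site
#' falling in both a promoter and a gene body is labeled `promoter`.
#'
#' @param sites Table with `contig`, `pos0`.
#' @param genes Gene model table (`gene_id`, `contig`, `start`, `end`,
#'   `strand`, `tss`; 0-based half-open).
#' @return Character vector in `{"promoter","gene_body","intergenic"}`.
#' @export
assign_features <- function(sites, genes) {
  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  feat <- rep("intergenic", nrow(sites))
  hitsB <- GenomicRanges::findOverlaps(gr, .gene_granges(genes, "gene_body"))
  feat[unique(S4Vectors::queryHits(hitsB))] <- "gene_body"
  hitsP <- GenomicRanges::findOverlaps(gr, .gene_granges(genes, "promoter"))
  feat[unique(S4Vectors::queryHits(hitsP))] <- "promoter"
  feat
}

#' Mean modification levels per genomic feature
#'
#' Mean raw level per assay over all CpG sites of each feature class
#' (promoter, gene body, intergenic), the per-feature summary used to
#' compare conditions.
#'
#' @param paired A `paired_sites` object or a site table carrying
#'   `level_5mC` and/or `level_5hmC` columns.
#' @param genes Gene model table.
#' @param contexts Contexts to include (default CpG only).
#' @return `data.table` with `feature`, `assay`, `mean_level`, `n_sites`
#'   (features with no sites reported as `NA` with a warning).
#' @export
summarize_by_feature <- function(paired, genes, contexts = "CpG") {
  dt <- if (inherits(paired, "paired_sites")) paired$paired else
    data.table::as.data.table(paired)
  dt <- dt[!is.na(context) & context %in% contexts]
  dt[, feature := assign_features(dt, genes)]
  assays <- intersect(c("level_5mC", "level_5hmC"), names(dt))
  long <- data.table::rbindlist(lapply(assays, function(a)
    dt[, .(assay = sub("level_", "", a), level = get(a)), by = feature]))
  out <- long[, .(mean_level = mean(level), n_sites = .N),
              by = .(feature, assay)]
  grid <- data.table::CJ(feature = c("promoter", "gene_body", "intergenic"),
                         assay = unique(out$assay))
  out <- out[grid, on = c("feature", "assay")]
  if (anyNA(out$mean_level)) {
    warning("empty feature class: ",
            paste(unique(out$feature[is.na(out$mean_level)]), collapse = ", "))
    out[is.na(n_sites), n_sites := 0L]
  }
  out[]
}

#' Per-gene mean modification levels over promoter and gene-body CpGs
#'
#' @param sites Site table with `contig`, `pos0` and level columns
#'   `level_m` and/or `level_h` (already restricted to the context of
#'   interest).
#' @param genes Gene model table.
#' @return `data.table` keyed by `gene_id` with `m_prom`, `h_prom`,
#'   `m_body`, `h_body` (those with a matching level column) and CpG
#'   counts `n_cpg_prom`, `n_cpg_body`.
#' @export
gene_level_means <- function(sites, genes) {
  dt <- data.table::as.data.table(sites)
  gr <- GenomicRanges::GRanges(dt$contig,
                               IRanges::IRanges(dt$pos0 + 1L, width = 1L))
  one <- function(feature, suffix) {
    hits <- GenomicRanges::findOverlaps(gr, .gene_granges(genes, feature))
    sub <- dt[S4Vectors::queryHits(hits)]
    sub[, gene_id := genes$gene_id[S4Vectors::subjectHits(hits)]]
    cols <- intersect(c("level_m", "level_h"), names(sub))
    agg <- sub[, c(lapply(.SD, mean), .(n = .N)), by = gene_id, .SDcols = cols]
    nm <- names(agg)
    nm[nm == "level_m"] <- paste0("m_", suffix)
    nm[nm == "level_h"] <- paste0("h_", suffix)
    nm[nm == "n"] <- paste0("n_cpg_", suffix)
    data.table::setnames(agg, nm)
    agg
  }
  prom <- one("promoter", "prom")
  body <- one("gene_body", "body")
  out <- merge(genes[, .(gene_id)], prom, by = "gene_id", all.x = TRUE)
  out <- merge(out, body, by = "gene_id", all.x = TRUE)
  for (cl in grep("^n_cpg", names(out), value = TRUE))
    out[is.na(get(cl)), (cl) := 0L]
  data.table::setorder(out, gene_id)
  out[]
}
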