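## Two-group site tests, greedy region segmentation under the stated
## region criteria, hyper/hypo classification, class intersection and
## gene mapping.

#' Per-site two-group modification test
#'
#' Replicates within each group are pooled into one count per site and the
#' groups are compared with a two-proportion z-test with continuity
#' correction (a deliberately simple surrogate for dispersion-shrinkage
#' count models, swappable behind this interface).  Only sites with pooled
#' coverage at or above `min_coverage` in *both* groups are tested; sites
#' absent or under-covered in either group are excluded and counted.
#' A site is flagged significant when `p < alpha` and the absolute level
#' difference is at least `min_diff` (the two gates are conjunctive).
#'
#' @param pileups_g1,pileups_g2 Lists of replicate pileup tables for the
#'   two groups (group 1 is the reference, e.g. WT; group 2 the condition,
#'   e.g. AD).
#' @param contexts Contexts tested (default CpG, as in the region
#'   analysis).
#' @param min_coverage Per-group pooled coverage floor (default 5).
#' @param alpha Site p-value threshold (default 0.05).
#' @param min_diff Minimum absolute mean modification difference (0.1).
#' @param exclude_contigs Contigs dropped before testing.
#' @return `data.table` with per-site `mu_g1`, `mu_g2`,
#'   `diff = mu_g2 - mu_g1`, `p_value`, `significant`; attribute
#'   `n_excluded` records the filter loss.
#' @export
test_dmc <- function(pileups_g1, pileups_g2, contexts = "CpG",
                     min_coverage = 5L, alpha = 0.05, min_diff = 0.1,
                     exclude_contigs = c(SPIKEIN_MC_CONTIG,
                                         SPIKEIN_HMC_CONTIG)) {
  pool <- function(reps) {
    dt <- data.table::rbindlist(lapply(reps, data.table::as.data.table))
    dt <- dt[!(contig %in% exclude_contigs) &
               !is.na(context) & context %in% contexts]
    dt[, .(count_C = sum(count_C), count_T = sum(count_T)),
       by = .(contig, pos0, strand, context)]
  }
  g1 <- pool(pileups_g1)
  g2 <- pool(pileups_g2)
  key <- c("contig", "pos0", "strand", "context")
  both <- merge(g1, g2, by = key, suffixes = c("_1", "_2"))
  n_before <- nrow(both)
  both[, `:=`(n1 = count_C_1 + count_T_1, n2 = count_C_2 + count_T_2)]
  both <- both[n1 >= min_coverage & n2 >= min_coverage]
  n_excl <- (nrow(g1) + nrow(g2) - 2 * n_before) + (n_before - nrow(both))
  both[, `:=`(mu_g1 = count_C_1 / n1, mu_g2 = count_C_2 / n2)]
  both[, diff := mu_g2 - mu_g1]
  ## two-proportion z with continuity correction, vectorised
  both[, p_pool := (count_C_1 + count_C_2) / (n1 + n2)]
  both[, se := sqrt(pmax(p_pool * (1 - p_pool), 0) * (1 / n1 + 1 / n2))]
  both[, z := pmax(abs(diff) - 0.5 * (1 / n1 + 1 / n2), 0) / se]
  both[, p_value := ifelse(se == 0, 1, 2 * stats::pnorm(z, lower.tail = FALSE))]
  both[, significant := p_value < alpha & abs(diff) >= min_diff]
  data.table::setorder(both, contig, pos0, strand)
  out <- both[, .(contig, pos0, strand, context, n1, n2, mu_g1, mu_g2,
                  diff, p_value, significant)]
  data.table::setattr(out, "n_excluded", n_excl)
  out[]
}

#' Segment differentially modified regions from site differences
#'
#' Greedy seed-and-extend segmentation: candidate CpGs — differentially
#' modified sites, i.e. significant in the per-site test (with at least
#' `site_min_diff` absolute difference) — are grouped per contig and sign,
#' split wherever two consecutive candidates are `max_gap` bp or more
#' apart, and each run is emitted as a region when it satisfies all the
#' region criteria: at least `min_cpg` member CpGs, absolute mean
#' difference at or above `min_diff`, all inter-CpG gaps below `max_gap`,
#' and a Mann-Whitney U test comparing member-site levels between the
#' groups with `p < max_p`.  Sign grouping makes every member share the
#' region's direction, satisfying the trend-consistency requirement by
#' construction.  Reading "at least 10 differentially modified CpGs" as 10
#' *significant* member CpGs (rather than 10 tested CpGs) is deliberate:
#' it is what keeps the null false-region rate near zero.
#'
#' @param site_diffs Output of [test_dmc()], sorted by position (an
#'   unsorted input is an error).
#' @param min_cpg Minimum member CpGs per region (10).
#' @param min_diff Minimum absolute mean difference (0.1).
#' @param max_gap Maximum distance between consecutive member CpGs (300).
#' @param max_p MWU p-value threshold (0.001).
#' Region boundaries are refined by a density-aware trim: an outermost
#' member whose distance to its neighbour is far larger than the region's
#' typical member spacing (`trim_mult` times the median gap, floored at 20
#' bp and capped at `max_gap`) is shed, so an isolated stray site in a
#' dense CpG island cannot drag a boundary outward.
#'
#' @param site_min_diff Candidate threshold for member sites (default
#'   equal to `min_diff`).
#' @param trim_mult Multiple of the median member gap beyond which
#'   boundary members are trimmed (default 5).
#' @return `data.table` of regions (`contig`, `start`, `end`, `n_cpg`,
#'   `mean_diff`, `mwu_p`, `direction`); attribute `members` holds the
#'   member-site subtable of each region for validation.
#' @export
call_regions <- function(site_diffs, min_cpg = 10L, min_diff = 0.1,
                         max_gap = 300L, max_p = 0.001,
                         site_min_diff = min_diff, trim_mult = 5) {
  dt <- data.table::as.data.table(site_diffs)
  if (!identical(order(dt$contig, dt$pos0), seq_len(nrow(dt))))
    stop("site_diffs must be sorted by contig and position")
  cand <- if ("significant" %in% names(dt))
    dt[significant == TRUE & abs(diff) >= site_min_diff] else
    dt[abs(diff) >= site_min_diff]
  cand[, sign := ifelse(diff > 0, 1L, -1L)]
  regions <- list()
  members <- list()
  for (sg in c(1L, -1L)) {
    sub <- cand[sign == sg]
    if (nrow(sub) == 0L) next
    sub[, run := cumsum(c(1L, (diff(pos0) >= max_gap) |
                            (contig[-1] != contig[-.N]))), by = NULL]
    trim_run <- function(r) {
      repeat {
        n <- nrow(r)
        if (n < 3L) return(r)
        gaps <- base::diff(r$pos0)
        thr <- min(max_gap, max(trim_mult * stats::median(gaps), 20))
        if (gaps[n - 1L] > thr) r <- r[-n]
        else if (gaps[1L] > thr) r <- r[-1L]
        else return(r)
      }
    }
    for (r in split(sub, sub$run)) {
      r <- trim_run(r)
      if (nrow(r) < min_cpg) next
      mean_diff <- mean(r$diff)
      if (abs(mean_diff) < min_diff) next
      mwu <- suppressWarnings(
        stats::wilcox.test(r$mu_g2, r$mu_g1, exact = FALSE))$p.value
      if (!is.finite(mwu) || mwu >= max_p) next
      regions[[length(regions) + 1L]] <- data.table::data.table(
        contig = r$contig[1], start = min(r$pos0), end = max(r$pos0) + 1L,
        n_cpg = nrow(r), mean_diff = mean_diff, mwu_p = mwu,
        direction = if (mean_diff > 0) "hyper" else "hypo")
      members[[length(members) + 1L]] <- r[, .(contig, pos0, strand,
                                               mu_g1, mu_g2, diff)]
    }
  }
  out <- if (length(regions)) data.table::rbindlist(regions) else
    data.table::data.table(contig = character(), start = integer(),
                           end = integer(), n_cpg = integer(),
                           mean_diff = numeric(), mwu_p = numeric(),
                           direction = character())
  ord <- order(out$contig, out$start)
  out <- out[ord]
  data.table::setattr(out, "members", members[ord])
  out[]
}

#' Recheck every emitted region against the region criteria
#'
#' Post-hoc validator: recomputes member-CpG count, mean difference,
#' inter-CpG gaps and the Mann-Whitney U p-value from each region's member
#' sites and reports whether all four criteria hold.
#'
#' @param regions Output of [call_regions()] (with its `members`
#'   attribute).
#' @param min_cpg,min_diff,max_gap,max_p The criteria.
#' @return Logical vector, one entry per region.
#' @export
validate_regions <- function(regions, min_cpg = 10L, min_diff = 0.1,
                             max_gap = 300L, max_p = 0.001) {
  members <- attr(regions, "members")
  vapply(seq_len(nrow(regions)), function(i) {
    r <- members[[i]]
    gaps <- diff(sort(unique(r$pos0)))
    mwu <- suppressWarnings(
      stats::wilcox.test(r$mu_g2, r$mu_g1, exact = FALSE))$p.value
    nrow(r) >= min_cpg &&
      abs(mean(r$diff)) >= min_diff &&
      (length(gaps) == 0L || max(gaps) < max_gap) &&
      is.finite(mwu) && mwu < max_p
  }, logical(1))
}

#' Hyper/hypo direction labels and counts
#'
#' Regions (or sites) with increased modification in the condition group
#' are hyper, decreased are hypo.
#'
#' @param regions Region table with `mean_diff`.
#' @return The input with a `direction` column, plus a `counts` attribute
#'   (named vector over hyper/hypo).
#' @export
classify_direction <- function(regions) {
  dt <- data.table::as.data.table(regions)
  dt[, direction := ifelse(mean_diff > 0, "hyper", "hypo")]
  counts <- c(hyper = sum(dt$direction == "hyper"),
              hypo = sum(dt$direction == "hypo"))
  data.table::setattr(dt, "counts", counts)
  dt[]
}

#' Intersect differential 5mC and 5hmC site classes
#'
#' Exact coordinate intersection of the significant DMC and DhMC sets;
#' sites significant in both assays form the dual class.
#'
#' @param dmc,dhmc [test_dmc()] outputs for the 5mC and 5hmC assays.
#' @return List with `dmc_only`, `dhmc_only`, `both` tables and a `counts`
#'   vector.
#' @export
intersect_classes <- function(dmc, dhmc) {
  key <- c("contig", "pos0", "strand")
  a <- data.table::as.data.table(dmc)[significant == TRUE]
  b <- data.table::as.data.table(dhmc)[significant == TRUE]
  both <- merge(a[, c(key, "diff"), with = FALSE],
                b[, c(key, "diff"), with = FALSE],
                by = key, suffixes = c("_m", "_h"))
  list(dmc_only = a[!b, on = key],
       dhmc_only = b[!a, on = key],
       both = both,
       counts = c(dmc = nrow(a), dhmc = nrow(b), both = nrow(both)))
}

#' Map regions to genes (DMG/DhMG classification)
#'
#' A gene carries a region class when at least one region overlaps its
#' promoter (TSS +/- 1 kb) or gene body; genes carrying both a DMR and a
#' DhMR form the dual class.
#'
#' @param regions_m,regions_h DMR and DhMR tables (`contig`, `start`,
#'   `end`, 0-based half-open).
#' @param genes Gene model table.
#' @return `data.table` with `gene_id`, logical `dmg`, `dhmg`, `dmhmg`.
#' @export
map_to_genes <- function(regions_m, regions_h, genes) {
  hit_genes <- function(regions) {
    if (is.null(regions) || nrow(regions) == 0L) return(character(0))
    gr <- GenomicRanges::GRanges(regions$contig,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
    hits <- c(
      S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(gr, .gene_granges(genes, "promoter"))),
      S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(gr, .gene_granges(genes, "gene_body"))))
    unique(genes$gene_id[hits])
  }
  out <- data.table::data.table(gene_id = genes$gene_id)
  out[, dmg := gene_id %in% hit_genes(regions_m)]
  out[, dhmg := gene_id %in% hit_genes(regions_h)]
  out[, dmhmg := dmg & dhmg]
  out[]
}
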