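## Spike-in calibration and the binomial modification caller.

#' Estimate per-assay conversion and false-positive rates from spike-ins
#'
#' For a 5mC assay (CD/CT) the false-positive source is the fully
#' hydroxymethylated spike-in (every cytosine should read T); for a 5hmC
#' assay (ACE/TAB) it is the fully methylated spike-in.  The false-positive
#' rate is the pooled `count_C / (count_C + count_T)` over all cytosines of
#' that contig, the conversion rate of the should-convert state is its
#' complement, and the retention rate is the pooled C-fraction of the
#' should-read-C spike-in.  Ratios are pooled over positions, not averaged
#' per position.
#'
#' @param pileups Pileup table containing the spike-in contigs.
#' @param protocol Protocol name or [assay_protocol()].
#' @param spikein_mC,spikein_hmC Contig names of the methylated and
#'   hydroxymethylated spike-ins.
#' @return Object of class `calibration_result`: list with `protocol`,
#'   `false_positive_rate`, `conversion_rate` (`1 - false_positive_rate`),
#'   `retention_rate`, and the pooled base counts used.
#' @export
calibrate <- function(pileups, protocol,
                      spikein_mC = SPIKEIN_MC_CONTIG,
                      spikein_hmC = SPIKEIN_HMC_CONTIG) {
  protocol <- assay_protocol(protocol)
  fp_contig <- switch(protocol$name,
    CD = , CT = spikein_hmC,
    ACE = , TAB = spikein_mC,
    BS = stop("BS-seq reads both 5mC and 5hmC as C; ",
              "no spike-in false-positive source is defined"))
  ret_contig <- if (fp_contig == spikein_hmC) spikein_mC else spikein_hmC
  pool <- function(ct) {
    sub <- pileups[which(pileups$contig == ct), ]
    tot <- sum(sub$count_C) + sum(sub$count_T)
    if (nrow(sub) == 0L || tot == 0L)
      stop("spike-in contig '", ct, "' has zero coverage; ",
           "increase sequencing depth or spike-in fraction")
    c(C = sum(sub$count_C), total = tot)
  }
  fp <- pool(fp_contig)
  ret <- pool(ret_contig)
  structure(list(
    protocol = protocol$name,
    false_positive_rate = unname(fp["C"] / fp["total"]),
    conversion_rate = unname(1 - fp["C"] / fp["total"]),
    retention_rate = unname(ret["C"] / ret["total"]),
    counts = list(false_positive = fp, retention = ret)
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %s: false-positive %.4f, conversion %.4f, retention %.4f\n",
    x$protocol, x$false_positive_rate, x$conversion_rate, x$retention_rate))
  invisible(x)
}

#' Raw modification level of pileup rows
#'
#' The assay's per-site point estimate: `count_C / (count_C + count_T)`.
#' Zero-coverage rows are undefined (`NaN`) and are excluded (with a
#' reported count) by [call_sites()].
#'
#' @param count_C,count_T Converted-read base counts.
#' @return Numeric fraction(s).
#' @export
raw_level <- function(count_C, count_T) {
  count_C / (count_C + count_T)
}

#' Calling configuration
#'
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param min_coverage Minimum read coverage for a site to be tested
#'   (default 5); lower-coverage sites are excluded before adjustment, not
#'   called negative.
#' @return List of class `calling_config`.
#' @export
calling_config <- function(alpha = 0.05, min_coverage = 5L) {
  stopifnot(alpha > 0, alpha < 1, min_coverage >= 1)
  structure(list(alpha = alpha, min_coverage = as.integer(min_coverage)),
            class = "calling_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone, permutation-stable); thin
#' wrapper over [stats::p.adjust()] so the adjustment used by the caller is
#' a single swappable point.
#'
#' @param p Numeric p-values in \[0,1\].
#' @return Adjusted q-values.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call modified cytosines with the spike-in-calibrated binomial test
#'
#' Per site with coverage `n` and C-count `k`, the p-value is the one-sided
#' upper tail `P[X >= k]` for `X ~ Binomial(n, p_hat)` where `p_hat` is the
#' assay's spike-in false-positive rate: a modified site inflates the
#' C-count above what incomplete conversion alone produces.  P-values are
#' BH-adjusted jointly over all tested sites and a site is called when
#' `q <= alpha` and coverage `>= min_coverage`.  Sites below the coverage
#' floor (or with zero coverage) are excluded from testing entirely;
#' spike-in contigs are dropped by default.
#'
#' @param pileups Pileup table.
#' @param calibration A `calibration_result` or a bare false-positive rate.
#' @param config A [calling_config()].
#' @param exclude_contigs Contigs dropped before testing (the spike-ins).
#' @return `data.table` with site coordinates, `coverage`, `raw_level`,
#'   `p_value`, `q_value`, `called`; attribute `n_excluded_low_coverage`
#'   records the filter loss.
#' @export
call_sites <- function(pileups, calibration, config = calling_config(),
                       exclude_contigs = c(SPIKEIN_MC_CONTIG,
                                           SPIKEIN_HMC_CONTIG)) {
  p_hat <- if (inherits(calibration, "calibration_result"))
    calibration$false_positive_rate else as.numeric(calibration)
  if (p_hat >= 1)
    stop("calibration false-positive rate is 1: uninformative calibration")
  dt <- data.table::as.data.table(pileups)
  dt <- dt[!(contig %in% exclude_contigs)]
  dt[, coverage := count_C + count_T]
  n_low <- sum(dt$coverage < config$min_coverage)
  dt <- dt[coverage >= config$min_coverage]
  if (p_hat == 0) {
    ## degenerate perfect calibration: floor at 1/(spike-in coverage + 1)
    ## so the test stays proper; fall back to the tested coverage when only
    ## a bare rate was supplied
    tot <- if (inherits(calibration, "calibration_result"))
      unname(calibration$counts$false_positive["total"]) else sum(dt$coverage)
    p_hat <- 1 / (tot + 1)
    message("calibration false-positive rate of 0 floored at ",
            signif(p_hat, 3), " to keep the binomial test proper")
  }
  dt[, raw_level := raw_level(count_C, count_T)]
  dt[, p_value := stats::pbinom(count_C - 1L, coverage, p_hat,
                                lower.tail = FALSE)]
  dt[, q_value := adjust_bh(p_value)]
  dt[, called := q_value <= config$alpha]
  data.table::setorder(dt, contig, pos0, strand)
  out <- dt[, .(contig, pos0, strand, context, coverage, count_C, count_T,
                raw_level, p_value, q_value, called)]
  data.table::setattr(out, "n_excluded_low_coverage", n_low)
  out[]
}
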