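## Shared fixtures and independent oracles used across the suite.

library(data.table)

## A small scenario that keeps per-test runtimes low.
tiny_scenario <- function(seed = 1L, genome_length = 6e4, n_genes = 12L, ...) {
  simulation_scenario(seed = seed, genome_length = genome_length,
                      n_genes = n_genes, n_hyper = 2L, n_hypo_h = 2L, ...)
}

## Depth vector covering the main contig and both spike-ins.
full_depths <- function(scenario) {
  c(chr1 = scenario$depth, spikein_depths(scenario))
}

## Independent Monte-Carlo oracle for the chemistry: walks each sampled
## molecule through the protocol's steps one Bernoulli draw at a time,
## with its own transition tables (no reuse of the closed-form machinery).
mc_read_C_fraction <- function(state, protocol_name, config, n = 1e5) {
  steps <- switch(protocol_name,
    BS  = "BISULFITE",
    TAB = c("BGT", "TET", "BISULFITE"),
    ACE = c("BGT", "DEA"),
    CD  = c("CMD1", "DEA"),
    CT  = c("CMD1", "TET", "BISULFITE"))
  products <- list(
    CMD1 = c("5mC" = "5gmC"),
    BGT = c("5hmC" = "5ghmC"),
    TET = c("5mC" = "5caC", "5hmC" = "5caC"),
    DEA = c(C = "T", "5mC" = "T", "5hmC" = "T", "5fC" = "T", "5caC" = "T",
            "5gmC" = "T", "5ghmC" = "T"),
    BISULFITE = c(C = "T", "5fC" = "T", "5caC" = "T", "5mC" = "T",
                  "5hmC" = "T", "5gmC" = "T", "5ghmC" = "T"))
  keys <- c(CMD1 = "cmd1", BGT = "bgt", TET = "tet", DEA = "dea",
            BISULFITE = "bisulfite")
  cur <- rep(state, n)
  for (st in steps) {
    eff <- config[[keys[[st]]]]
    prod <- products[[st]]
    for (sub in names(prod)) {
      e <- if (sub %in% names(eff)) eff[[sub]] else 0
      hit <- cur == sub & stats::runif(n) < e
      cur[hit] <- prod[[sub]]
    }
  }
  mean(cur != "T")
}

## Hand-applied BH step-up rule (independent of p.adjust).
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## Interval Jaccard index on 0-based half-open spans.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / ((e1 - s1) + (e2 - s2) - inter)
}

## Best Jaccard of each truth interval against any called region.
best_jaccard <- function(truth, regions) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(regions) == 0L) return(0)
    max(vapply(seq_len(nrow(regions)), function(j)
      interval_jaccard(truth$start[i], truth$end[i],
                       regions$start[j], regions$end[j]), numeric(1)))
  }, numeric(1))
}

## WT methylome with all modification stripped from the main contig
## (spike-ins keep their fixed states so calibration still works).
null_methylome <- function(sim) {
  dt <- data.table::copy(sim$methylome$WT)
  dt[contig == "chr1", `:=`(m = 0, h = 0)]
  dt
}

## Replicate pileup lists for a two-group comparison.
replicate_pileups <- function(methylome, protocol, depths, seeds,
                              config = default_chemistry_config()) {
  lapply(seeds, function(s)
    simulate_pileups(methylome, protocol, config, depth = depths, seed = s))
}
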