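make_diffs <- function(pos0, mu1, mu2, significant = TRUE, contig = "chr1") {
  data.table::data.table(
    contig = contig, pos0 = as.integer(pos0), strand = "+", context = "CpG",
    n1 = 60L, n2 = 60L, mu_g1 = mu1, mu_g2 = mu2, diff = mu2 - mu1,
    p_value = ifelse(significant, 1e-6, 0.5), significant = significant)
}

test_that("identical groups produce no excess significant sites", {
  sc <- tiny_scenario(seed = 29, depth = 30)
  sim <- generate_scenario(sc)
  d <- full_depths(sc)
  g1 <- replicate_pileups(sim$methylome$WT, "CD", d, seeds = 1:2)
  g2 <- replicate_pileups(sim$methylome$WT, "CD", d, seeds = 3:4)
  res <- test_dmc(g1, g2)
  expect_lt(mean(res$significant), 0.05)
  expect_lt(mean(abs(res$diff)), 0.05)
})

test_that("significance requires both the p-value and the difference gate", {
  ## enormous counts: tiny p but |diff| = 0.09 -> not significant
  p1 <- list(data.table::data.table(contig = "chr1", pos0 = 0L, strand = "+",
                                    context = "CpG", count_C = 0L,
                                    count_T = 10000L))
  p2 <- list(data.table::data.table(contig = "chr1", pos0 = 0L, strand = "+",
                                    context = "CpG", count_C = 900L,
                                    count_T = 9100L))
  res <- test_dmc(p1, p2)
  expect_lt(res$p_value, 1e-10)
  expect_false(res$significant)
  ## same p, |diff| = 0.11 -> significant
  p3 <- list(data.table::data.table(contig = "chr1", pos0 = 0L, strand = "+",
                                    context = "CpG", count_C = 1100L,
                                    count_T = 8900L))
  expect_true(test_dmc(p1, p3)$significant)
  ## per-group coverage floor: site dropped when one group is thin
  p4 <- list(data.table::data.table(contig = "chr1", pos0 = 0L, strand = "+",
                                    context = "CpG", count_C = 2L,
                                    count_T = 1L))
  expect_equal(nrow(test_dmc(p1, p4)), 0L)
})

test_that("planted differential sites are recovered with adequate power", {
  for (seed in c(31, 32, 33)) {
    sc <- tiny_scenario(seed = seed, depth = 30)
    sim <- generate_scenario(sc)
    d <- full_depths(sc)
    g1 <- replicate_pileups(sim$methylome$WT, "CD", d, seeds = seed + 0:1)
    g2 <- replicate_pileups(sim$methylome$AD, "CD", d, seeds = seed + 2:3)
    res <- test_dmc(g1, g2)
    hyper <- sim$truth[type == "hyper_m"]
    member <- rep(FALSE, nrow(res))
    for (i in seq_len(nrow(hyper)))
      member <- member | (res$pos0 >= hyper$start[i] & res$pos0 < hyper$end[i])
    expect_gte(mean(res$significant[member]), 0.6)
  }
})

test_that("regions split at CpG deserts and respect the gap rule", {
  left <- make_diffs(seq(0, 950, by = 50), 0.2, 0.5)
  right <- make_diffs(seq(1500, 2450, by = 50), 0.2, 0.5)
  regs <- call_regions(rbind(left, right))
  expect_equal(nrow(regs), 2L)
  expect_true(all(regs$direction == "hyper"))
  expect_true(all(validate_regions(regs)))
  ## without the desert: one region
  regs1 <- call_regions(make_diffs(seq(0, 1950, by = 50), 0.2, 0.5))
  expect_equal(nrow(regs1), 1L)
  expect_equal(regs1$n_cpg, 40L)
  ## unsorted input is rejected
  expect_error(call_regions(rbind(right, left)), "sorted")
})

test_that("regions below any criterion are not emitted", {
  ## fewer than 10 member CpGs
  expect_equal(nrow(call_regions(make_diffs(seq(0, 400, by = 50), 0.2, 0.5))), 0L)
  ## mean difference below 0.1 (members not significant at that diff)
  weak <- make_diffs(seq(0, 950, by = 50), 0.45, 0.5, significant = TRUE)
  expect_equal(nrow(call_regions(weak)), 0L)
  ## non-significant members are never candidates
  ns <- make_diffs(seq(0, 950, by = 50), 0.2, 0.5, significant = FALSE)
  expect_equal(nrow(call_regions(ns)), 0L)
})

test_that("direction classification and counts follow the sign of the change", {
  regs <- data.table::data.table(mean_diff = c(0.15, -0.15, 0.3))
  out <- classify_direction(regs)
  expect_equal(out$direction, c("hyper", "hypo", "hyper"))
  expect_equal(attr(out, "counts"), c(hyper = 2L, hypo = 1L))
})

test_that("AD scenario yields mostly hypo-DhMR and validated regions", {
  sc <- tiny_scenario(seed = 37, depth = 30)
  sim <- generate_scenario(sc)
  d <- full_depths(sc)
  g1 <- replicate_pileups(sim$methylome$WT, "ACE", d, seeds = 70:71)
  g2 <- replicate_pileups(sim$methylome$AD, "ACE", d, seeds = 72:73)
  regs <- call_regions(test_dmc(g1, g2))
  expect_gt(nrow(regs), 0L)
  expect_true(all(validate_regions(regs)))
  counts <- attr(classify_direction(regs), "counts")
  expect_gt(counts[["hypo"]], counts[["hyper"]])
})

test_that("class intersection is exact set arithmetic on coordinates", {
  dmc <- make_diffs(c(0, 10, 20), 0.2, 0.5)
  dhmc <- make_diffs(c(20, 30), 0.5, 0.2)
  x <- intersect_classes(dmc, dhmc)
  expect_equal(x$both$pos0, 20L)
  expect_equal(x$dmc_only$pos0, c(0L, 10L))
  expect_equal(x$dhmc_only$pos0, 30L)
  expect_lte(x$counts[["both"]], min(x$counts[["dmc"]], x$counts[["dhmc"]]))
  ## disjoint classes: empty intersection
  x2 <- intersect_classes(make_diffs(0:5 * 10, 0.2, 0.5),
                          make_diffs(100:105 * 10, 0.5, 0.2))
  expect_equal(nrow(x2$both), 0L)
})

test_that("gene mapping agrees with a brute-force interval oracle", {
  set.seed(41)
  sim <- generate_scenario(tiny_scenario(seed = 43))
  genes <- sim$genes
  regions <- data.table::data.table(
    contig = "chr1",
    start = sample.int(59000, 1000))
  regions[, end := start + sample(50:3000, 1000, replace = TRUE)]
  got <- map_to_genes(regions, NULL, genes)
  prom_s <- pmax(genes$tss - 1000L, 0L)
  prom_e <- genes$tss + 1001L
  brute <- vapply(seq_len(nrow(genes)), function(g)
    any(regions$start < prom_e[g] & regions$end > prom_s[g]) ||
      any(regions$start < genes$end[g] & regions$end > genes$start[g]),
    logical(1))
  expect_identical(got$dmg, brute)
  expect_true(all(got$dhmg == FALSE))
  expect_identical(got$dmhmg, got$dmg & got$dhmg)
})
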