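test_that("scenario generation is byte-identical under a fixed seed", {
  sc <- tiny_scenario(seed = 11)
  a <- generate_scenario(sc)
  b <- generate_scenario(sc)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(a$methylome, b$methylome)
  p1 <- simulate_pileups(a$methylome$WT, "CD", depth = full_depths(sc), seed = 5)
  p2 <- simulate_pileups(b$methylome$WT, "CD", depth = full_depths(sc), seed = 5)
  expect_identical(p1, p2)
})

test_that("methylome respects m + h <= 1 and the designed structure", {
  sim <- generate_scenario(tiny_scenario(seed = 2))
  for (cond in c("WT", "AD")) {
    mh <- sim$methylome[[cond]]
    expect_true(all(mh$m >= 0 & mh$h >= 0))
    expect_lte(max(mh$m + mh$h), 1 + 1e-12)
  }
  wt <- sim$methylome$WT
  ## bimodal CpG methylation: promoters low, elsewhere high
  expect_lt(wt[feature == "promoter" & context == "CpG", mean(m)], 0.3)
  expect_gt(wt[feature == "gene_body" & context == "CpG", mean(m)], 0.5)
  ## non-CpG modification near zero (spike-ins excluded: fixed states)
  expect_lt(wt[contig == "chr1" & context %in% c("CHG", "CHH"), mean(m)], 0.02)
  ## gene-body enriched 5hmC
  expect_gt(wt[feature == "gene_body" & context == "CpG", mean(h)],
            wt[feature == "intergenic" & context == "CpG", mean(h)])
})

test_that("AD-like condition carries the gene-body 5hmC loss and the planted gains", {
  sim <- generate_scenario(tiny_scenario(seed = 3))
  wt <- sim$methylome$WT
  ad <- sim$methylome$AD
  expect_lt(ad[feature == "gene_body" & context == "CpG", mean(h)],
            wt[feature == "gene_body" & context == "CpG", mean(h)])
  ## planted hyper-m regions realise at least the configured effect
  hyper <- sim$truth[type == "hyper_m"]
  for (i in seq_len(nrow(hyper))) {
    in_reg <- wt$contig == "chr1" & wt$pos0 >= hyper$start[i] &
      wt$pos0 < hyper$end[i] & !is.na(wt$context) & wt$context == "CpG"
    expect_gte(mean(ad$m[in_reg]) - mean(wt$m[in_reg]),
               hyper$effect[i] - 1e-9)
  }
  ## planted hypo-h regions lose the configured amount
  hypo <- sim$truth[type == "hypo_h"]
  for (i in seq_len(nrow(hypo))) {
    in_reg <- wt$contig == "chr1" & wt$pos0 >= hypo$start[i] &
      wt$pos0 < hypo$end[i] & !is.na(wt$context) & wt$context == "CpG"
    expect_lte(mean(ad$h[in_reg]) - mean(wt$h[in_reg]),
               -hypo$effect[i] + 1e-9)
  }
})

test_that("spike-in contigs behave as fixed fully modified controls", {
  sc <- tiny_scenario(seed = 4)
  sim <- generate_scenario(sc)
  wt <- sim$methylome$WT
  expect_true(all(wt[contig == SPIKEIN_MC_CONTIG, m == 1 & h == 0]))
  expect_true(all(wt[contig == SPIKEIN_HMC_CONTIG, m == 0 & h == 1]))
  ## 480-bp construct is byte-identical to the printed sequence
  expect_identical(paste(sim$genome[[SPIKEIN_HMC_CONTIG]], collapse = ""),
                   spikein_hmC_sequence())
  expect_identical(nchar(spikein_hmC_sequence()), 480L)
  ## ideal CD-seq: 5hmC spike-in fully converted, 5mC spike-in untouched
  p <- simulate_pileups(wt, "CD", ideal_chemistry_config(),
                        depth = full_depths(sc), seed = 9)
  expect_true(all(p[contig == SPIKEIN_HMC_CONTIG, count_C == 0]))
  expect_true(all(p[contig == SPIKEIN_MC_CONTIG, count_T == 0]))
})

test_that("pooled pileup fractions converge to the chemistry expectation", {
  ## many sites sharing one (m, h) state: pooled C-fraction within 3
  ## binomial SE of the closed-form expectation
  set.seed(10)
  cfg <- default_chemistry_config()
  grid <- list(c(0.3, 0.2), c(0, 0.6), c(0.9, 0.05))
  for (mh in grid) {
    meth <- data.table::data.table(
      contig = "chr1", pos0 = 0:3999, strand = "+", context = "CpG",
      m = mh[1], h = mh[2])
    for (proto in c("CD", "ACE", "BS")) {
      p <- simulate_pileups(meth, proto, cfg, depth = 20, seed = 123)
      expected <- expected_raw_level(mh[1], mh[2], proto, cfg)
      tot <- p[, sum(count_C + count_T)]
      got <- p[, sum(count_C)] / tot
      se <- sqrt(expected * (1 - expected) / tot)
      expect_lt(abs(got - expected), 3 * se + 1e-6)
    }
  }
})

test_that("expression counts couple to modification with the configured signs", {
  sc <- tiny_scenario(seed = 5, genome_length = 1.5e5, n_genes = 30L)
  sim <- generate_scenario(sc)
  gm <- lapply(sim$methylome[c("WT", "AD")], gene_true_modification,
               genes = sim$genes)
  ## no coupling: correlation signs split near 50/50
  sc0 <- tiny_scenario(seed = 5, genome_length = 1.5e5, n_genes = 30L,
                       coupling = c(m_prom = 0, m_body = 0,
                                    h_prom = 0, h_body = 0),
                       n_de = 0L)
  ex0 <- simulate_expression(gm, sc0, seed = 21)
  s0 <- attr(correlate_modification_expression(ex0$mod$h_body, ex0$counts),
             "sign_summary")
  expect_gt(s0[["prop_positive"]], 0.25)
  expect_lt(s0[["prop_positive"]], 0.75)
  ## default coupling: majority positive for h, majority negative for m
  ex <- simulate_expression(gm, sc, seed = 21)
  sh <- attr(correlate_modification_expression(ex$mod$h_body, ex$counts),
             "sign_summary")
  sm <- attr(correlate_modification_expression(ex$mod$m_prom, ex$counts),
             "sign_summary")
  expect_gt(sh[["prop_positive"]], 0.5)
  expect_gt(sm[["prop_negative"]], 0.5)
})

test_that("degenerate and invalid scenario inputs are rejected", {
  expect_error(simulation_scenario(n_rep = 0L))
  expect_error(simulation_scenario(genome_length = 100))
  expect_error(simulate_pileups(
    data.table::data.table(contig = "c", pos0 = 0L, strand = "+",
                           context = "CpG", m = 0.5, h = 0.1),
    "XX"), "unknown protocol")
})
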