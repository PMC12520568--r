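make_calls <- function(contig, pos0, level, coverage = 20L, called = TRUE) {
  data.table::data.table(
    contig = contig, pos0 = pos0, strand = "+", context = "CpG",
    coverage = coverage, count_C = as.integer(round(level * coverage)),
    count_T = as.integer(coverage - round(level * coverage)),
    raw_level = level, p_value = 0.001, q_value = 0.01, called = called)
}

test_that("pairing is an inner join with reported side tables", {
  a <- make_calls("chr1", c(0L, 10L, 20L), c(0.8, 0.5, 0.2))
  b <- make_calls("chr1", c(10L, 20L, 30L), c(0.1, 0.3, 0.9))
  suppressMessages(pr <- pair_sites(a, b))
  expect_equal(pr$paired$pos0, c(10L, 20L))
  expect_equal(pr$paired$level_5mC, c(0.5, 0.2))
  expect_equal(pr$paired$level_5hmC, c(0.1, 0.3))
  expect_equal(pr$only_m$pos0, 0L)
  expect_equal(pr$only_h$pos0, 30L)
  ## disjoint inputs: empty paired table, everything in the side tables
  c2 <- make_calls("chr1", c(100L, 110L), c(0.5, 0.5))
  suppressMessages(pr2 <- pair_sites(a, c2))
  expect_equal(nrow(pr2$paired), 0L)
  expect_equal(nrow(pr2$only_m), 3L)
  expect_equal(nrow(pr2$only_h), 2L)
  ## join symmetry on the site set
  suppressMessages(pr_ab <- pair_sites(a, b))
  suppressMessages(pr_ba <- pair_sites(b, a))
  expect_setequal(pr_ab$paired$pos0, pr_ba$paired$pos0)
  ## contig mismatch is an error naming the offenders
  d <- make_calls("chr2", 0L, 0.5)
  expect_error(suppressMessages(pair_sites(a, d)), "chr2")
})

test_that("paired direct estimates converge to the true (m, h) at high depth", {
  sc <- tiny_scenario(seed = 13)
  sim <- generate_scenario(sc)
  ideal <- ideal_chemistry_config()
  wt <- sim$methylome$WT
  pm <- simulate_pileups(wt, "CD", ideal, depth = 500, seed = 1)
  ph <- simulate_pileups(wt, "ACE", ideal, depth = 500, seed = 2)
  cm <- call_sites(pm, 1e-4)
  ch <- call_sites(ph, 1e-4)
  suppressMessages(pr <- pair_sites(cm, ch))
  j <- merge(pr$paired, wt[contig == "chr1"],
             by = c("contig", "pos0", "strand"))
  expect_gt(nrow(j), 1000)
  expect_lt(sqrt(mean((j$level_5mC - j$m)^2)), 0.02)
  expect_lt(sqrt(mean((j$level_5hmC - j$h)^2)), 0.02)
})

test_that("subtraction can go negative where direct estimates cannot", {
  expect_equal(subtraction_estimate(0.5, 0.5), 0)
  expect_equal(subtraction_estimate(0.1, 0.4), -0.3)
  ideal <- ideal_chemistry_config()
  for (seed in 1:3) {
    meth <- data.table::data.table(
      contig = "chr1", pos0 = 0:1999, strand = "+", context = "CpG",
      m = 0.05, h = 0.6)
    bs <- simulate_pileups(meth, "BS", ideal, depth = 10, seed = seed)
    ace <- simulate_pileups(meth, "ACE", ideal, depth = 10, seed = seed + 100)
    cd <- simulate_pileups(meth, "CD", ideal, depth = 10, seed = seed + 200)
    keep <- bs$count_C + bs$count_T > 0 & ace$count_C + ace$count_T > 0
    sub_est <- subtraction_estimate(
      raw_level(bs$count_C, bs$count_T)[keep],
      raw_level(ace$count_C, ace$count_T)[keep])
    expect_gt(mean(sub_est < 0), 0)
    direct <- raw_level(cd$count_C, cd$count_T)
    direct <- direct[!is.nan(direct)]
    expect_true(all(direct >= 0 & direct <= 1))
    ## equal-depth variance penalty of the subtraction estimator
    expect_gt(stats::var(sub_est), stats::var(direct))
  }
})

test_that("context annotation matches a brute-force window annotator", {
  set.seed(17)
  chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  sites <- cytosine_sites(chars, "c")
  got <- annotate_context(sites, list(c = chars))
  brute <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$pos0[i] + 1L
    w <- if (sites$strand[i] == "+") {
      chars[p:min(p + 2, 400)]
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      unname(comp[chars[p:max(p - 2, 1)]])
    }
    if (length(w) >= 2 && w[2] == "G") return("CpG")
    if (length(w) < 2) return(NA_character_)
    if (length(w) >= 3 && w[3] == "G") return("CHG")
    if (length(w) < 3) return(NA_character_)
    "CHH"
  }, character(1))
  expect_identical(got, brute)
  ## agreement with the generator's own annotation
  expect_identical(got, sites$context)
  ## every site gets exactly one of the four labels
  expect_true(all(got %in% c("CpG", "CHG", "CHH", NA)))
  ## CCGG: the central CG is CpG on both strands
  ccgg <- strsplit("CCGG", "")[[1]]
  s2 <- data.table::data.table(contig = "c", pos0 = c(1L, 2L),
                               strand = c("+", "-"))
  expect_identical(annotate_context(s2, list(c = ccgg)), c("CpG", "CpG"))
  expect_error(annotate_context(
    data.table::data.table(contig = "c", pos0 = 10L, strand = "+"),
    list(c = ccgg)), "bounds")
})

test_that("feature summaries agree with a brute-force group-by", {
  sc <- tiny_scenario(seed = 19)
  sim <- generate_scenario(sc)
  wt <- sim$methylome$WT[contig == "chr1" & context == "CpG"]
  tbl <- wt[, .(contig, pos0, strand, context, level_5mC = m, level_5hmC = h)]
  out <- summarize_by_feature(tbl, sim$genes)
  ## brute force: per-site feature via a naive interval scan over genes
  brute_feat <- vapply(tbl$pos0, function(p) {
    in_prom <- any(p >= pmax(sim$genes$tss - 1000L, 0L) &
                     p < sim$genes$tss + 1001L)
    if (in_prom) return("promoter")
    if (any(p >= sim$genes$start & p < sim$genes$end)) return("gene_body")
    "intergenic"
  }, character(1))
  for (f in unique(brute_feat)) {
    expect_equal(out[feature == f & assay == "5mC", mean_level],
                 mean(tbl$level_5mC[brute_feat == f]))
    expect_equal(out[feature == f & assay == "5hmC", mean_level],
                 mean(tbl$level_5hmC[brute_feat == f]))
  }
  ## uniform levels give uniform feature means
  tbl2 <- data.table::copy(tbl)[, `:=`(level_5mC = 0.5, level_5hmC = 0.5)]
  out2 <- summarize_by_feature(tbl2, sim$genes)
  expect_true(all(abs(out2$mean_level - 0.5) < 1e-12))
})

test_that("the AD scenario lowers the gene-body 5hmC feature mean", {
  sc <- tiny_scenario(seed = 23)
  sim <- generate_scenario(sc)
  mk <- function(cond)
    sim$methylome[[cond]][contig == "chr1" & context == "CpG",
                          .(contig, pos0, strand, context, level_5hmC = h)]
  s_wt <- summarize_by_feature(mk("WT"), sim$genes)
  s_ad <- summarize_by_feature(mk("AD"), sim$genes)
  expect_lt(s_ad[feature == "gene_body" & assay == "5hmC", mean_level],
            s_wt[feature == "gene_body" & assay == "5hmC", mean_level])
})
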