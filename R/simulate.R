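## Synthetic genome / methylome / pileup generator.
##
## The generator emulates the study design the caller is meant for: a small
## genome with CpG-rich promoters, bimodal CpG methylation (hypomethylated
## promoters, methylated elsewhere), low non-CpG modification, gene-body
## enriched 5hmC, two conditions (a WT-like baseline and an AD-like
## condition carrying a genome-wide gene-body 5hmC reduction plus sparse
## planted 5mC hyper-regions), the two fully modified spike-in controls at
## 0.5% mass each, and assay-converted per-site pileups.

#' Name of the fully hydroxymethylated spike-in contig
#' @export
SPIKEIN_HMC_CONTIG <- "spikein_hmC"

#' Name of the fully methylated lambda-like spike-in contig
#' @export
SPIKEIN_MC_CONTIG <- "spikein_mC"

#' The 480-bp fully hydroxymethylated spike-in sequence
#'
#' The synthetic 480-bp template amplified with 5hm-dCTP so that every
#' cytosine is 5hmC; used to estimate each assay's handling of 5hmC
#' (false-positive rate for the 5mC assays, retention for the 5hmC assays).
#'
#' @return A single 480-character DNA string.
#' @export
spikein_hmC_sequence <- function() {
  paste0(
    "GAATTCTTGCAGCACTAGTGCATCTATAAGTTATCTCAAATCAAGAAATCAGTCTAATGA",
    "GAATTTCAATAACTTCAGCAATTTAAGCTGCATGCATCAGTGTCATCGTTATTTTTTTTT",
    "TGAGACGTAGTCATGCTCTGTTGCTGAGTCTGCAGTACAGTGACGAGATATCGACTCAGC",
    "ACAACATCTGCATCACATGTTCAAGCGATTCTCATGCTTCAGCTTGCAGAGTAGCTGTCA",
    "CTACAGACACTGAGCAGCATGCGTGACTAATTTTTGTATTTTTAGTAGAGAGTGCATTTC",
    "GTCATGTTGTACAGTCTAGTTTCAAACTCATGACTTCAGTTGATCTAACTGACACGATCT",
    "CAGAATTTACTGTCATTACAGTACTGTCACACAGTGACAGTCATTTTTCTTAATTTTTAA",
    "AAATATTAAAGTTTTATCTCATTCGTGTTGAAGCATATTCGTGATTTAAAAGTTGCAAAG"
  )
}

#' Simulation scenario configuration
#'
#' Bundles every tunable of the synthetic study.  Defaults encode the
#' desk-scale stand-in for the hippocampal design: a 1 Mb genome with 200
#' genes, 30x depth, two replicates per condition, both spike-ins at 0.5%
#' mass, a 0.6x gene-body 5hmC multiplier in the AD-like condition and
#' eight planted 2-kb hyper-methylated regions of effect +0.3.
#'
#' @param seed Integer master seed; every derived draw is a deterministic
#'   function of it.
#' @param genome_length Main contig length in bp.
#' @param n_genes Number of non-overlapping gene models.
#' @param depth Mean per-site read depth on the main contig.
#' @param n_rep Replicates per condition for the modification assays.
#' @param spikein_fraction Mass fraction of each spike-in in the library
#'   (0.005 each, i.e. 0.5%).
#' @param ad_h_mult Multiplier applied to gene-body 5hmC in the AD-like
#'   condition (< 1 models the global gene-body 5hmC loss).
#' @param n_hyper,hyper_width,hyper_effect Number, width (bp) and added
#'   5mC level of planted hyper-methylated regions in the AD-like
#'   condition.
#' @param n_hypo_h,hypo_h_width,hypo_h_effect Number, width (bp) and lost
#'   5hmC level of planted strongly hydroxymethylated regions whose 5hmC
#'   drops in the AD-like condition (focal losses on top of the global
#'   multiplier).
#' @param cpg_island_rate Per-position CpG planting rate inside promoters.
#' @param coupling Named coefficients linking log expression to per-gene
#'   modification levels (`m_prom`, `m_body`, `h_prom`, `h_body`).
#' @param expr_reps Expression samples per condition (default 6; per-gene
#'   across-sample correlations are not estimable at the modification
#'   assays' two replicates).
#' @param base_mean,nb_size Negative-binomial mean and size for expression
#'   counts.
#' @param sample_jitter_sd SD of per-sample jitter on per-gene modification
#'   levels (biological variability seen by the expression model).
#' @param n_de,de_lfc Number of genes with a planted expression log2
#'   fold-change of +/- `de_lfc` independent of modification coupling.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed = 1L,
                                genome_length = 1e6,
                                n_genes = 200L,
                                depth = 30,
                                n_rep = 2L,
                                spikein_fraction = 0.005,
                                ad_h_mult = 0.6,
                                n_hyper = 8L,
                                hyper_width = 2000L,
                                hyper_effect = 0.3,
                                n_hypo_h = 8L,
                                hypo_h_width = 2000L,
                                hypo_h_effect = 0.2,
                                cpg_island_rate = 0.08,
                                coupling = c(m_prom = -3, m_body = -3,
                                             h_prom = 3, h_body = 3),
                                expr_reps = 6L,
                                base_mean = 200,
                                nb_size = 50,
                                sample_jitter_sd = 0.05,
                                n_de = 20L,
                                de_lfc = 1) {
  stopifnot(n_rep >= 1L, depth > 0, genome_length >= 1e4, n_genes >= 1L,
            spikein_fraction >= 0, spikein_fraction < 0.5,
            ad_h_mult >= 0, hyper_effect >= 0, hyper_effect <= 1)
  structure(as.list(environment()), class = "simulation_scenario")
}

.rand_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Enumerate cytosine sites and trinucleotide contexts of a contig
#'
#' Both strands: a plus-strand site is a `C` in the reference, a
#' minus-strand site is a `G` (a `C` on the reverse complement).  Context
#' is CpG if the strand-aware next base is G, CHG if the base after that is
#' G, else CHH; sites too close to the contig end to decide are `NA`.
#'
#' @param seq_chars Character vector of single bases (one contig).
#' @param contig Contig name to stamp on the rows.
#' @return `data.table` with `contig`, `pos0` (0-based), `strand`,
#'   `context`.
#' @export
cytosine_sites <- function(seq_chars, contig = "chr1") {
  n <- length(seq_chars)
  ip <- which(seq_chars == "C")
  im <- which(seq_chars == "G")
  ctx_plus <- function(i) {
    n1 <- ifelse(i + 1 <= n, seq_chars[i + 1], NA)
    n2 <- ifelse(i + 2 <= n, seq_chars[i + 2], NA)
    ifelse(!is.na(n1) & n1 == "G", "CpG",
      ifelse(is.na(n1), NA,
        ifelse(!is.na(n2) & n2 == "G", "CHG",
          ifelse(is.na(n2), NA, "CHH"))))
  }
  ctx_minus <- function(i) {
    n1 <- ifelse(i - 1 >= 1, seq_chars[pmax(i - 1, 1)], NA)
    n2 <- ifelse(i - 2 >= 1, seq_chars[pmax(i - 2, 1)], NA)
    ifelse(!is.na(n1) & n1 == "C", "CpG",
      ifelse(is.na(n1), NA,
        ifelse(!is.na(n2) & n2 == "C", "CHG",
          ifelse(is.na(n2), NA, "CHH"))))
  }
  dt <- data.table::rbindlist(list(
    data.table::data.table(contig = contig, pos0 = ip - 1L, strand = "+",
                           context = if (length(ip)) ctx_plus(ip) else character()),
    data.table::data.table(contig = contig, pos0 = im - 1L, strand = "-",
                           context = if (length(im)) ctx_minus(im) else character())
  ))
  data.table::setorder(dt, pos0, strand)
  dt[]
}

## rejection-free beta draw helper
.rbeta_n <- function(n, shape1, shape2) {
  if (n == 0) return(numeric(0))
  stats::rbeta(n, shape1, shape2)
}

#' Generate the full synthetic scenario
#'
#' Builds the genome (main contig plus the two spike-in contigs), the gene
#' models, and the per-condition methylome.  CpG methylation is bimodal
#' (low near promoters, high elsewhere), 5hmC is small and concentrated in
#' gene bodies, and CHG/CHH levels are near zero.  The AD-like condition
#' multiplies gene-body 5hmC by `ad_h_mult` and plants `n_hyper`
#' hyper-methylated regions inside gene bodies.  Identical seeds give
#' byte-identical output.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `scenario`, `genome` (named list of character base
#'   vectors), `genes` (`data.table`), `methylome` (list `WT`/`AD` of
#'   site tables with `m`, `h`), and `truth` (planted hyper-region table).
#' @export
generate_scenario <- function(scenario = simulation_scenario()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  L <- as.integer(scenario$genome_length)
  G <- as.integer(scenario$n_genes)

  ## --- gene models on a regular grid of slots --------------------------
  slot <- L %/% G
  if (slot < 3000L) stop("genome too short for ", G, " genes")
  gene_len <- as.integer(round(stats::runif(G, 0.35, 0.7) * slot))
  offset <- vapply(seq_len(G), function(i)
    sample.int(slot - gene_len[i] - 200L, 1L) + 100L, integer(1))
  start <- (seq_len(G) - 1L) * slot + offset
  end <- start + gene_len
  strand <- sample(c("+", "-"), G, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1L)
  genes <- data.table::data.table(
    gene_id = sprintf("gene%03d", seq_len(G)),
    contig = "chr1", start = start, end = end, strand = strand, tss = tss)

  ## --- genome: random DNA + CpG planting in promoters ------------------
  chars <- .rand_dna(L)
  for (i in seq_len(G)) {
    p0 <- max(1L, tss[i] - 999L)        # 1-based window [tss-1kb, tss+1kb]
    p1 <- min(L - 1L, tss[i] + 1001L)
    cand <- seq.int(p0, p1 - 1L, by = 2L)
    sel <- cand[stats::runif(length(cand)) < scenario$cpg_island_rate * 2]
    chars[sel] <- "C"
    chars[sel + 1L] <- "G"
  }
  spike_m <- .rand_dna(5000L)
  spike_h <- strsplit(spikein_hmC_sequence(), "")[[1]]
  genome <- list(chr1 = chars)
  genome[[SPIKEIN_MC_CONTIG]] <- spike_m
  genome[[SPIKEIN_HMC_CONTIG]] <- spike_h

  ## --- site table and feature flags ------------------------------------
  sites <- cytosine_sites(chars, "chr1")
  if (sum(sites$context == "CpG", na.rm = TRUE) == 0L)
    stop("degenerate genome: no CpG sites")
  feat <- assign_features(sites, genes)
  sites[, feature := feat]

  ## --- WT methylome ----------------------------------------------------
  n <- nrow(sites)
  is_cpg <- !is.na(sites$context) & sites$context == "CpG"
  in_prom <- sites$feature == "promoter"
  in_body <- sites$feature == "gene_body"
  m <- numeric(n)
  m[is_cpg & in_prom] <- .rbeta_n(sum(is_cpg & in_prom), 1, 10)
  m[is_cpg & !in_prom] <- .rbeta_n(sum(is_cpg & !in_prom), 6, 1.5)
  m[!is_cpg] <- .rbeta_n(sum(!is_cpg), 1, 200)
  h <- numeric(n)
  h[is_cpg & in_body] <- .rbeta_n(sum(is_cpg & in_body), 2, 18)
  h[is_cpg & !in_body] <- .rbeta_n(sum(is_cpg & !in_body), 1, 30)
  h[!is_cpg] <- .rbeta_n(sum(!is_cpg), 1, 400)
  m <- pmin(m, 1 - h)                    # enforce m + h <= 1, keep h as drawn

  wt <- data.table::copy(sites)[, `:=`(m = m, h = h)]

  ## --- planted differential regions ------------------------------------
  ## hyper-m: lowly methylated regulatory stretches that gain methylation
  ## in the AD-like condition; hypo-h: strongly hydroxymethylated
  ## stretches that lose a fixed amount of 5hmC (focal losses on top of
  ## the global gene-body multiplier).  Base states are redrawn so the
  ## configured effect is realised exactly (no m + h <= 1 clipping).
  pick <- sample(genes$gene_id,
                 min(scenario$n_hyper + scenario$n_hypo_h, nrow(genes)))
  place <- function(ids, width, type, effect) {
    tr <- genes[gene_id %in% ids]
    tr <- tr[, {
      w <- min(width, end - start)
      s <- if (end - start - w > 0) start + sample.int(end - start - w, 1L) else start
      .(start = s, end = s + w)
    }, by = .(gene_id, contig)]
    tr[, `:=`(type = type, effect = effect)]
    tr
  }
  truth <- data.table::rbindlist(list(
    place(pick[seq_len(scenario$n_hyper)], scenario$hyper_width,
          "hyper_m", scenario$hyper_effect),
    place(pick[scenario$n_hyper + seq_len(min(scenario$n_hypo_h,
                                              length(pick) - scenario$n_hyper))],
          scenario$hypo_h_width, "hypo_h", scenario$hypo_h_effect)))
  region_rows <- function(i)
    wt[, .I[pos0 >= truth$start[i] & pos0 < truth$end[i] &
              !is.na(context) & context == "CpG"]]
  for (i in which(truth$type == "hyper_m")) {
    rows <- region_rows(i)
    wt[rows, m := pmax(pmin(.rbeta_n(length(rows), 2, 8),
                            1 - h - scenario$hyper_effect), 0)]
  }
  for (i in which(truth$type == "hypo_h")) {
    rows <- region_rows(i)
    wt[rows, h := pmax(.rbeta_n(length(rows), 10, 15),
                       scenario$hypo_h_effect + 0.02)]
    wt[rows, m := pmin(m, 1 - h)]
  }

  ## --- AD methylome: gene-body h loss + the planted effects ------------
  ad <- data.table::copy(wt)
  ad[feature == "gene_body", h := h * scenario$ad_h_mult]
  for (i in which(truth$type == "hyper_m"))
    ad[pos0 >= truth$start[i] & pos0 < truth$end[i] & context == "CpG",
       m := pmin(m + scenario$hyper_effect, 1 - h)]
  for (i in which(truth$type == "hypo_h"))
    ad[pos0 >= truth$start[i] & pos0 < truth$end[i] & context == "CpG",
       h := pmax(wt[region_rows(i), h] - scenario$hypo_h_effect, 0)]

  ## --- spike-in methylomes (fixed uniform states) ----------------------
  sp_m <- cytosine_sites(spike_m, SPIKEIN_MC_CONTIG)[, `:=`(m = 1, h = 0,
                                                            feature = "spikein")]
  sp_h <- cytosine_sites(spike_h, SPIKEIN_HMC_CONTIG)[, `:=`(m = 0, h = 1,
                                                             feature = "spikein")]
  wt <- data.table::rbindlist(list(wt, sp_m, sp_h), use.names = TRUE)
  ad <- data.table::rbindlist(list(ad, data.table::copy(sp_m),
                                   data.table::copy(sp_h)), use.names = TRUE)

  list(scenario = scenario, genome = genome, genes = genes,
       methylome = list(WT = wt, AD = ad), truth = truth)
}

#' Effective spike-in depths implied by the library mass fractions
#'
#' Coverage is proportional to mass over length: a spike-in present at mass
#' fraction `f` on a contig of length `l` in a library dominated by a
#' genome of length `L` sees depth `depth * f L / ((1 - 2 f) l)`.
#'
#' @param scenario A [simulation_scenario()].
#' @return Named depth vector for the two spike-in contigs.
#' @export
spikein_depths <- function(scenario) {
  f <- scenario$spikein_fraction
  L <- scenario$genome_length
  fac <- f * L / (1 - 2 * f)
  c(stats::setNames(scenario$depth * fac / 5000, SPIKEIN_MC_CONTIG),
    stats::setNames(scenario$depth * fac / 480, SPIKEIN_HMC_CONTIG))
}

#' Simulate assay-converted per-site pileups
#'
#' Forward model for the caller: per site, coverage ~ Poisson(depth) and
#' `count_C ~ Binomial(coverage, p)` where `p` is the chemistry-expected
#' C-fraction for the site's `(m, h)` under the protocol, with the
#' symmetric sequencing-error flip applied.
#'
#' @param methylome Site table with `contig`, `pos0`, `strand`, `context`,
#'   `m`, `h` (one condition of [generate_scenario()]'s output).
#' @param protocol Protocol name or [assay_protocol()].
#' @param config Chemistry config.
#' @param depth Mean depth; either one number or a named per-contig vector
#'   (missing contigs fall back to the unnamed/first value).
#' @param seed Integer seed.
#' @return `data.table` with `contig`, `pos0`, `strand`, `context`,
#'   `count_C`, `count_T`.
#' @export
simulate_pileups <- function(methylome, protocol,
                             config = default_chemistry_config(),
                             depth = 30, seed = 1L) {
  protocol <- assay_protocol(protocol)
  stopifnot(depth > 0)
  set.seed(seed)
  p <- expected_raw_level(methylome$m, methylome$h, protocol, config)
  lam <- if (is.null(names(depth))) rep(depth[1], nrow(methylome)) else {
    d <- depth[methylome$contig]
    d[is.na(d)] <- depth[1]
    as.numeric(d)
  }
  cov <- stats::rpois(nrow(methylome), lam)
  cC <- stats::rbinom(nrow(methylome), cov, p)
  out <- methylome[, .(contig, pos0, strand, context)]
  out[, `:=`(count_C = cC, count_T = cov - cC)]
  out[]
}

#' Per-gene true modification summaries
#'
#' Mean 5mC over promoter CpGs, mean 5mC/5hmC over gene-body CpGs and the
#' matching CpG counts, from a condition's methylome truth.  Used both by
#' the expression simulator (coupling covariates) and as the ground truth
#' in recovery tests.
#'
#' @param methylome One condition's site table (with `m`, `h`).
#' @param genes Gene model table.
#' @return `data.table` keyed by `gene_id` with `m_prom`, `m_body`,
#'   `h_prom`, `h_body` and CpG counts `n_cpg_prom`, `n_cpg_body`.
#' @export
gene_true_modification <- function(methylome, genes) {
  cpg <- methylome[!is.na(context) & context == "CpG" & contig %in% genes$contig]
  lev <- gene_level_means(cpg[, .(contig, pos0, strand,
                                  level_m = m, level_h = h)], genes)
  lev
}

#' Simulate expression counts coupled to modification levels
#'
#' Per-gene negative-binomial counts whose log-mean contains configurable
#' terms in the gene's (per-sample jittered) promoter/gene-body 5mC and
#' 5hmC levels, plus an optional planted log2 fold-change for a subset of
#' genes.  Positive `h_*` coupling and negative `m_*` coupling make the
#' modification-expression correlation signs recoverable downstream.
#'
#' @param gene_mod List with elements `WT` and `AD`, each as returned by
#'   [gene_true_modification()].
#' @param scenario A [simulation_scenario()] (coupling, replicate count,
#'   NB parameters, jitter, planted DE are read from it).
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples matrix), `condition`
#'   (factor), `mod` (list of per-covariate genes x samples matrices),
#'   `planted_lfc` (per-gene), and `gene_id`.
#' @export
simulate_expression <- function(gene_mod, scenario, seed = 1L) {
  set.seed(seed)
  gm_wt <- gene_mod$WT
  gm_ad <- gene_mod$AD
  stopifnot(identical(gm_wt$gene_id, gm_ad$gene_id))
  G <- nrow(gm_wt)
  nr <- scenario$expr_reps
  cond <- factor(rep(c("WT", "AD"), each = nr), levels = c("WT", "AD"))
  covars <- c("m_prom", "m_body", "h_prom", "h_body")
  coupling <- scenario$coupling[covars]
  coupling[is.na(coupling)] <- 0

  planted_lfc <- numeric(G)
  if (scenario$n_de > 0) {
    de <- sample.int(G, min(scenario$n_de, G))
    half <- length(de) %/% 2
    planted_lfc[de] <- rep(c(1, -1), length.out = length(de)) * scenario$de_lfc
  }
  gene_effect <- stats::rnorm(G, 0, 0.5)

  mod <- lapply(covars, function(cv) {
    truth <- cbind(matrix(gm_wt[[cv]], G, nr), matrix(gm_ad[[cv]], G, nr))
    jit <- matrix(stats::rnorm(G * 2 * nr, 0, scenario$sample_jitter_sd),
                  G, 2 * nr)
    pmin(pmax(truth + jit, 0), 1)
  })
  names(mod) <- covars

  centers <- vapply(covars, function(cv)
    mean(c(gm_wt[[cv]], gm_ad[[cv]]), na.rm = TRUE), numeric(1))
  logmu <- matrix(log(scenario$base_mean) + gene_effect, G, 2 * nr)
  for (cv in covars)
    logmu <- logmu + coupling[[cv]] * (mod[[cv]] - centers[[cv]])
  logmu <- logmu + outer(planted_lfc * log(2), as.numeric(cond == "AD"))
  counts <- matrix(stats::rnbinom(G * 2 * nr, mu = exp(logmu),
                                  size = scenario$nb_size), G, 2 * nr)
  colnames(counts) <- paste0(cond, "_", rep(seq_len(nr), 2))
  rownames(counts) <- gm_wt$gene_id
  list(counts = counts, condition = cond, mod = mod,
       planted_lfc = planted_lfc, gene_id = gm_wt$gene_id)
}
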