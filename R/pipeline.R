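## File formats and the end-to-end pipeline driver.
##
## Coordinate convention: all tables are 0-based half-open (BED-style);
## pileup TSVs carry the documented header
## (contig, pos0, strand, context, count_C, count_T).

#' Write / read a per-site pileup TSV
#'
#' Tab-separated with header `contig, pos0, strand, context, count_C,
#' count_T`; `pos0` is the 0-based position of the cytosine on its strand.
#'
#' @param pileups Pileup table.
#' @param path Output path.
#' @return `path`, invisibly (writer); `data.table` (reader).
#' @export
write_pileup <- function(pileups, path) {
  data.table::fwrite(pileups, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = c("contig", "strand",
                                                          "context")))
  need <- c("contig", "pos0", "strand", "context", "count_C", "count_T")
  if (!all(need %in% names(dt)))
    stop("pileup file lacks required columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  dt
}

#' Write site levels as bedGraph
#'
#' One line per site: `contig  pos0  pos0+1  level` (0-based half-open).
#'
#' @param sites Table with `contig`, `pos0` and the chosen level column.
#' @param path Output path.
#' @param level_col Name of the level column.
#' @export
write_bedgraph <- function(sites, path, level_col = "raw_level") {
  dt <- data.table::as.data.table(sites)
  bg <- dt[, .(contig, start = pos0, end = pos0 + 1L,
               level = get(level_col))]
  data.table::fwrite(bg, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write / read gene models as BED6-like TSV
#'
#' Columns `contig, start, end, gene_id, score, strand` (0-based
#' half-open); the TSS is the `start` for `+` genes and `end - 1` for `-`
#' genes and is rederived on read.
#'
#' @param genes Gene model table.
#' @param path File path.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.table::as.data.table(genes)[
    , .(contig, start, end, gene_id, score = 0L, strand)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          col.names = c("contig", "start", "end", "gene_id",
                                        "score", "strand"))
  dt[, tss := ifelse(strand == "+", start, end - 1L)]
  dt[, score := NULL]
  dt[]
}

#' Write a genome as FASTA
#'
#' @param genome Named list of character base vectors.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genome, paste, character(1),
                                          collapse = ""))
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> calibrate -> call -> pair -> differential -> association,
#' writing every stage product plus a run manifest to `outdir`.  All
#' randomness derives from the scenario seed, so reruns with an identical
#' scenario produce byte-identical outputs.  Pileups are simulated per
#' replicate; site calling is done per condition on replicate-pooled
#' counts with one spike-in calibration per assay (pooled over its
#' libraries); the site-level differential test uses the replicate-level
#' pileups.
#'
#' @param scenario A [simulation_scenario()].
#' @param outdir Output directory (created if missing).
#' @param protocol_m,protocol_h Protocols for the 5mC and 5hmC assays
#'   (defaults CD and ACE).
#' @param config Chemistry config.
#' @return Invisibly, a list with every stage result and `manifest`.
#' @export
run_pipeline <- function(scenario = simulation_scenario(), outdir,
                         protocol_m = "CD", protocol_h = "ACE",
                         config = default_chemistry_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  row_counts <- list()

  message("[simulate] generating scenario (seed ", scenario$seed, ")")
  sim <- generate_scenario(scenario)
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_genes_bed(sim$genes, file.path(outdir, "genes.bed"))
  depths <- c(stats::setNames(scenario$depth, "chr1"), spikein_depths(scenario))

  assays <- list(m = assay_protocol(protocol_m), h = assay_protocol(protocol_h))
  conds <- c("WT", "AD")
  pileups <- list()
  k <- 0L
  for (a in names(assays)) for (cond in conds)
    for (rep_i in seq_len(scenario$n_rep)) {
      k <- k + 1L
      nm <- sprintf("%s_%s_rep%d", a, cond, rep_i)
      pileups[[nm]] <- simulate_pileups(sim$methylome[[cond]], assays[[a]],
                                        config, depth = depths,
                                        seed = scenario$seed + 17L * k)
      write_pileup(pileups[[nm]], file.path(outdir, paste0("pileup_", nm, ".tsv")))
      row_counts[[paste0("pileup_", nm)]] <- nrow(pileups[[nm]])
    }

  message("[calibrate] estimating spike-in rates")
  calib <- lapply(names(assays), function(a) {
    pooled <- data.table::rbindlist(pileups[grep(paste0("^", a, "_"),
                                                 names(pileups))])
    pooled <- pooled[, .(count_C = sum(count_C), count_T = sum(count_T)),
                     by = .(contig, pos0, strand, context)]
    calibrate(pooled, assays[[a]])
  })
  names(calib) <- names(assays)
  jsonlite::write_json(
    lapply(calib, function(x) x[c("protocol", "false_positive_rate",
                                  "conversion_rate", "retention_rate")]),
    file.path(outdir, "calibration.json"), auto_unbox = TRUE, digits = NA)

  message("[call] binomial site calling per condition")
  pool_cond <- function(a, cond) {
    dt <- data.table::rbindlist(pileups[grep(sprintf("^%s_%s_", a, cond),
                                             names(pileups))])
    dt[, .(count_C = sum(count_C), count_T = sum(count_T)),
       by = .(contig, pos0, strand, context)]
  }
  calls <- list()
  for (a in names(assays)) for (cond in conds) {
    nm <- paste(a, cond, sep = "_")
    calls[[nm]] <- call_sites(pool_cond(a, cond), calib[[a]])
    data.table::fwrite(calls[[nm]],
                       file.path(outdir, paste0("calls_", nm, ".tsv")),
                       sep = "\t")
    write_bedgraph(calls[[nm]],
                   file.path(outdir, paste0("levels_", nm, ".bedGraph")))
    row_counts[[paste0("calls_", nm)]] <- nrow(calls[[nm]])
  }

  message("[pair] joining 5mC and 5hmC calls")
  paired <- lapply(conds, function(cond)
    pair_sites(calls[[paste0("m_", cond)]], calls[[paste0("h_", cond)]]))
  names(paired) <- conds
  feature_summary <- data.table::rbindlist(lapply(conds, function(cond) {
    s <- summarize_by_feature(paired[[cond]], sim$genes)
    s[, condition := cond]
    s
  }))
  data.table::fwrite(feature_summary,
                     file.path(outdir, "feature_summary.tsv"), sep = "\t")
  for (cond in conds) {
    data.table::fwrite(paired[[cond]]$paired,
                       file.path(outdir, paste0("paired_", cond, ".tsv")),
                       sep = "\t")
    row_counts[[paste0("paired_", cond)]] <- nrow(paired[[cond]]$paired)
  }

  message("[diff] site tests and region segmentation")
  reps_of <- function(a, cond)
    pileups[grep(sprintf("^%s_%s_", a, cond), names(pileups))]
  diffs <- lapply(names(assays), function(a)
    test_dmc(reps_of(a, "WT"), reps_of(a, "AD")))
  names(diffs) <- names(assays)
  regions <- lapply(diffs, call_regions)
  for (a in names(assays)) {
    data.table::fwrite(diffs[[a]],
                       file.path(outdir, paste0("site_diffs_", a, ".tsv")),
                       sep = "\t")
    data.table::fwrite(regions[[a]],
                       file.path(outdir, paste0("regions_", a, ".tsv")),
                       sep = "\t")
    row_counts[[paste0("regions_", a)]] <- nrow(regions[[a]])
  }
  classes <- intersect_classes(diffs$m, diffs$h)
  gene_classes <- map_to_genes(regions$m, regions$h, sim$genes)
  data.table::fwrite(gene_classes, file.path(outdir, "gene_classes.tsv"),
                     sep = "\t")

  message("[associate] expression simulation and correlation")
  gene_mod <- lapply(sim$methylome[conds], gene_true_modification,
                     genes = sim$genes)
  expr <- simulate_expression(gene_mod, scenario,
                              seed = scenario$seed + 9000L)
  data.table::fwrite(data.table::as.data.table(expr$counts,
                                               keep.rownames = "gene_id"),
                     file.path(outdir, "expression_counts.tsv"), sep = "\t")
  de <- differential_expression(expr$counts, expr$condition)
  data.table::fwrite(de, file.path(outdir, "expression_de.tsv"), sep = "\t")
  n_cpg <- list(m_prom = gene_mod$WT$n_cpg_prom, h_prom = gene_mod$WT$n_cpg_prom,
                m_body = gene_mod$WT$n_cpg_body, h_body = gene_mod$WT$n_cpg_body)
  cor_summary <- correlation_sign_summary(expr$mod, expr$counts, n_cpg = n_cpg)
  data.table::fwrite(cor_summary,
                     file.path(outdir, "correlation_summary.tsv"), sep = "\t")
  overlap <- overlap_report(gene_classes[dmg == TRUE, gene_id],
                            gene_classes[dhmg == TRUE, gene_id],
                            de[deg == TRUE, gene_id])
  jsonlite::write_json(as.list(overlap), file.path(outdir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    tool = "duomod",
    version = as.character(utils::packageVersion("duomod")),
    seed = scenario$seed,
    scenario = scenario[setdiff(names(scenario), "coupling")],
    coupling = as.list(scenario$coupling),
    protocols = list(m = assays$m$name, h = assays$h$name),
    row_counts = row_counts,
    files = as.list(tools::md5sum(file.path(outdir, sort(files))))
  )
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[done] ", length(files) + 1L, " files in ", outdir)
  invisible(list(sim = sim, pileups = pileups, calibration = calib,
                 calls = calls, paired = paired,
                 feature_summary = feature_summary, diffs = diffs,
                 regions = regions, classes = classes,
                 gene_classes = gene_classes, expression = expr, de = de,
                 correlation = cor_summary, overlap = overlap,
                 manifest = manifest))
}
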