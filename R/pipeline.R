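# End-to-end orchestration of the three-stage depth-based hybrid assembly and
# its downstream catalog, taxonomy and binning stages, on a simulated
# community. Fully deterministic under the configured seed.

#' Demo pipeline configuration
#'
#' The standard panel: 5 genomes of 50-120 kbp (a desk-scale stand-in for
#' 0.5-2 Mbp genomes), geometric abundances with ratio 4 independently
#' permuted across two samples, one 3-kbp repeat shared by two genomes, and
#' 6 single-copy markers per genome. Sequencing effort is derived from the
#' drawn abundances so that the 4th most abundant genome reaches
#' `target_min_depth` combined short-read coverage and `long_target_depth`
#' long-read coverage (how a sequencing experiment would be sized); the
#' rarest genome is expected to stay unassemblable, as in real surveys.
#'
#' @param seed mandatory RNG seed driving every stage.
#' @param ... overrides for any configuration entry.
#' @return named list of class `dm_config`.
#' @export
demo_config <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genomes = 5L,
    genome_length_range = c(50000L, 120000L),
    gc_range = c(0.35, 0.65),
    n_markers = 6L,
    repeat_spec = list(list(length = 3000L, copies = 1L, genomes = c(1L, 2L))),
    abundance_profile = list(type = "geometric", r = 4),
    n_samples = 2L,
    read_length = 150L, insert_mean = 250L, insert_sd = 25,
    sub_rate = 0.001,
    target_min_depth = 20,      # combined depth of the 4th-ranked genome
    long_target_depth = 5,      # same, long reads
    max_pairs = 600000L, max_long_reads = 20000L,
    long_mean_length = 7604L, long_min_length = 50L,
    long_error_rates = c(sub = 0.015, ins = 0.090, del = 0.045),
    long_quality_model = list(mean = 85, sd = 5),
    qc_min_length = 50L, qc_min_quality = 75,
    n_bins = 11L,
    k_assembly = 31L, k_map = 21L, k_anchor = 17L,
    min_kmer_count = "auto",    # adaptive abundance floor (see vignette)
    min_anchor_kmers = 10L, min_support = 2L,
    min_contig_emit = 200L,
    subsample_depth = 60,       # per-phylotype short-read coverage cap
    long_subsample_depth = 30,  # per-phylotype long-read coverage cap
    max_mismatch_frac = 0.05, min_chain_seeds = 5L,
    partition_scheme = "differential",  # per-sample depth vector (see vignette)
    partition_boundaries = "gap",       # natural-breaks depth boundaries
    min_gene_length = 100L, min_contig_length = 500L,
    cluster_identity = 0.95, cluster_coverage = 0.90,
    max_evalue = 1e-5, score_margin = 0.90,
    n_hits_per_gene = 5L, decoy_rate = 0.1,
    bin_min_contig = 2500L, bin_depth_weight = 2,
    min_completeness = 0.60, max_contamination = 0.20,
    reassemble_contamination = 0.05,
    agreement = 0.75,
    read_map_sample = 40000L,   # reads used for mapping-ratio estimates
    run_pogc = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "dm_config"
  cfg
}

.clamp <- function(x, lo, hi) max(lo, min(hi, x))

.auto_min_count <- function(reads, k) {
  med <- kmer_median_count(reads, k)
  as.integer(.clamp(round(med / 8), 2, 10))
}

#' Generate the demo community (inputs of the pipeline)
#'
#' @param config from [demo_config()].
#' @return list with `truth`, `abundances`, `short` (per-sample pair sets),
#'   `long` (per-sample long reads), `seeds` (derived stage seeds) and
#'   `config`.
#' @export
make_demo <- function(config = demo_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 10L)
  truth <- generate_genomes(config$n_genomes, config$genome_length_range,
                            config$gc_range, config$n_markers,
                            config$repeat_spec, seed = seeds[1])
  ab <- sample_abundances(config$n_genomes, config$abundance_profile,
                          n_samples = config$n_samples, seed = seeds[2])
  lens <- nchar(truth$genomes$seq)
  W <- colSums(ab * lens)
  # combined per-genome depth per sequenced unit
  coef_short <- rowSums(sweep(ab, 2, 2 * config$read_length / W, "*"))
  coef_long <- rowSums(sweep(ab, 2, config$long_mean_length / W, "*"))
  r4_short <- sort(coef_short, decreasing = TRUE)[min(4L, config$n_genomes)]
  r4_long <- sort(coef_long, decreasing = TRUE)[min(4L, config$n_genomes)]
  n_pairs <- min(config$max_pairs,
                 as.integer(ceiling(config$target_min_depth / r4_short)))
  n_long <- min(config$max_long_reads,
                as.integer(ceiling(config$long_target_depth / r4_long)))
  short <- list(); long <- list()
  for (s in seq_len(config$n_samples)) {
    lab <- paste0("s", s)
    short[[lab]] <- simulate_short_reads(
      truth, n_pairs, ab[, s], config$read_length, config$insert_mean,
      config$insert_sd, config$sub_rate, seed = seeds[2 + s],
      sample_label = lab)
    long[[lab]] <- simulate_long_reads(
      truth, n_long, ab[, s], config$long_mean_length,
      config$long_min_length, config$long_error_rates,
      config$long_quality_model, seed = seeds[4 + s], sample_label = lab)
  }
  list(truth = truth, abundances = ab, short = short, long = long,
       n_pairs = n_pairs, n_long = n_long, seeds = seeds, config = config)
}

.log_add <- function(log, stage, metric, value) {
  rbind(log, data.frame(stage = stage, metric = metric,
                        value = as.character(value),
                        stringsAsFactors = FALSE))
}

.subsample_ids <- function(ids, frac, seed) {
  if (frac >= 1 || length(ids) < 2L) return(ids)
  set.seed(seed)
  sort(sample(ids, max(1L, ceiling(frac * length(ids)))))
}

#' Run the full depth-based hybrid pipeline
#'
#' Stage 1 assembles all short reads, maps every read back, stratifies
#' contigs and reads into depth phylotypes; stage 2 assembles each phylotype
#' and merges its contigs with its long reads; stage 3 pools phylotypes,
#' removes contained redundancy and polishes with short reads. Downstream:
#' ORFs, non-redundant catalogs (short-only, hybrid, depth-hybrid), a merged
#' reference catalog, simulated hit tables + LCA taxonomy, TNF/depth binning
#' with marker QC and optional bin re-assembly, and comparative reports.
#'
#' @param config from [demo_config()].
#' @param out_dir output directory for artifacts (created); `NULL` writes
#'   nothing.
#' @param community optional pre-built [make_demo()] result (reused as-is).
#' @return list with all stage outputs (see names); also written as
#'   FASTA/TSV artifacts plus an event log under `out_dir` when given.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         community = NULL) {
  t0 <- Sys.time()
  log <- data.frame(stage = character(0), metric = character(0),
                    value = character(0), stringsAsFactors = FALSE)
  demo <- community %||% make_demo(config)
  truth <- demo$truth
  nsamp <- config$n_samples
  labs <- paste0("s", seq_len(nsamp))
  message(sprintf("[depthmeta] community: %d pairs + %d long reads per sample",
                  demo$n_pairs, demo$n_long))
  log <- .log_add(log, "simulate", "n_pairs_per_sample", demo$n_pairs)
  log <- .log_add(log, "simulate", "n_long_per_sample", demo$n_long)

  # --- QC ------------------------------------------------------------------
  long_kept <- list()
  for (s in labs) {
    qc <- qc_filter_long_reads(demo$long[[s]]$reads, config$qc_min_length,
                               config$qc_min_quality)
    long_kept[[s]] <- qc$reads
    log <- .log_add(log, "qc", paste0("long_removed_", s), qc$n_removed)
  }
  all_long <- do.call(rbind, unname(long_kept))

  # --- stage 1: merged short-read assembly, mapping, depth partition -------
  all_r1 <- do.call(rbind, lapply(labs, function(s) demo$short[[s]]$r1))
  all_r2 <- do.call(rbind, lapply(labs, function(s) demo$short[[s]]$r2))
  all_short_seqs <- c(all_r1$seq, all_r2$seq)
  mc0 <- if (identical(config$min_kmer_count, "auto"))
    .auto_min_count(all_short_seqs, config$k_assembly) else
      config$min_kmer_count
  log <- .log_add(log, "stage1", "min_kmer_count", mc0)
  message(sprintf("[depthmeta] stage 1: merged assembly of %d reads (floor %d)",
                  length(all_short_seqs), mc0))
  stage0 <- assemble_short_reads(all_short_seqs, k = config$k_assembly,
                                 min_kmer_count = mc0, id_prefix = "m")
  stage0 <- stage0[nchar(stage0$seq) >= config$min_contig_emit, , drop = FALSE]
  class(stage0) <- c("dm_seqs", "data.frame")
  log <- .log_add(log, "stage1", "short_only_contigs", nrow(stage0))
  message(sprintf("[depthmeta] stage 1: mapping reads back to %d contigs",
                  nrow(stage0)))
  idx0 <- build_kmer_index(stage0, k = config$k_map)
  aln1 <- list(); aln2 <- list(); alnL <- list()
  for (s in labs) {
    aln1[[s]] <- map_short_reads(demo$short[[s]]$r1, idx0,
                                 config$max_mismatch_frac)
    aln2[[s]] <- map_short_reads(demo$short[[s]]$r2, idx0,
                                 config$max_mismatch_frac)
    aln1[[s]]$sample <- s; aln2[[s]]$sample <- s
    alnL[[s]] <- map_long_reads(long_kept[[s]], idx0,
                                config$min_chain_seeds)
    alnL[[s]]$sample <- s
  }
  short_aln0 <- do.call(rbind, unname(c(aln1, aln2)))
  depths0 <- compute_depths(short_aln0, idx0$contig_lengths)
  part <- if (identical(config$partition_scheme, "combined"))
    partition_by_depth(depths0, n_bins = config$n_bins,
                       scheme = config$partition_boundaries) else
      partition_by_depth_joint(depths0, n_bins = config$n_bins,
                               scheme = config$partition_boundaries)
  log <- .log_add(log, "stage1", "n_phylotypes_nonempty",
                  length(unique(part$contigs$bin)))
  pair_bins <- list(); long_bins <- list()
  for (s in labs) {
    pair_bins[[s]] <- assign_reads(demo$short[[s]]$r1$id, part,
                                   aln1[[s]], aln2[[s]])
    long_bins[[s]] <- assign_reads(long_kept[[s]]$id, part, alnL[[s]])
  }
  pair_bin_all <- do.call(rbind, unname(pair_bins))
  long_bin_all <- do.call(rbind, unname(long_bins))
  n_reads_total <- 2L * nrow(pair_bin_all)
  log <- .log_add(log, "stage1", "reads_total", n_reads_total)
  log <- .log_add(log, "stage1", "reads_unmapped_pairs",
                  sum(is.na(pair_bin_all$bin)))

  # helper tables for read retrieval
  r1_seq <- setNames(all_r1$seq, all_r1$id)
  r2_seq <- setNames(all_r2$seq, all_r2$id)
  long_seq <- setNames(all_long$seq, all_long$id)
  contig_depth <- setNames(part$contigs$depth, part$contigs$contig_id)
  contig_bin <- setNames(part$contigs$bin, part$contigs$contig_id)

  # --- stage 2: per-phylotype assembly + hybrid merge ----------------------
  message(sprintf("[depthmeta] stage 2: %d phylotypes",
                  length(unique(part$contigs$bin))))
  hybrid_parts <- list()
  for (b in sort(unique(part$contigs$bin))) {
    pids <- pair_bin_all$read_id[!is.na(pair_bin_all$bin) &
                                   pair_bin_all$bin == b]
    if (length(pids) < 10L) next
    # estimated phylotype coverage from its contigs (length-weighted)
    members <- names(contig_bin)[contig_bin == b]
    wl <- idx0$contig_lengths[members]
    est_depth <- sum(contig_depth[members] * wl) / sum(wl)
    frac <- min(1, config$subsample_depth / max(est_depth, 1e-9))
    sub <- .subsample_ids(pids, frac, seed = config$seed + 1000L + b)
    reads_b <- c(r1_seq[sub], r2_seq[sub])
    mc_b <- if (identical(config$min_kmer_count, "auto"))
      .auto_min_count(reads_b, config$k_assembly) else config$min_kmer_count
    asm <- assemble_short_reads(reads_b, k = config$k_assembly,
                                min_kmer_count = mc_b,
                                id_prefix = sprintf("p%02dc", b),
                                phylotype = b)
    asm <- asm[nchar(asm$seq) >= config$min_contig_emit, , drop = FALSE]
    class(asm) <- c("dm_seqs", "data.frame")
    if (nrow(asm) == 0L) next
    lids <- long_bin_all$read_id[!is.na(long_bin_all$bin) &
                                   long_bin_all$bin == b]
    merged <- asm
    if (length(lids) > 0L) {
      lfrac <- min(1, config$long_subsample_depth * sum(as.numeric(wl)) /
                     max(1, sum(nchar(long_seq[lids]))))
      lsub <- .subsample_ids(lids, lfrac, seed = config$seed + 2000L + b)
      lr <- seq_set(lsub, long_seq[lsub])
      chains <- anchor_contigs(asm, lr, config$k_anchor,
                               config$min_anchor_kmers)
      merged <- hybrid_merge(asm, chains, lr, config$min_support)
      merged$id <- sprintf("p%02d_%s", b, merged$id)
    }
    log <- .log_add(log, "stage2", sprintf("phylotype_%02d_contigs", b),
                    nrow(merged))
    hybrid_parts[[as.character(b)]] <- merged
  }
  .dm_assert(length(hybrid_parts) > 0L, "no phylotype produced contigs")
  pooled <- do.call(rbind, unname(lapply(hybrid_parts, function(x)
    x[, c("id", "seq", "provenance", "phylotype")])))
  class(pooled) <- c("dm_seqs", "data.frame")
  log <- .log_add(log, "stage3", "contigs_pooled", nrow(pooled))

  # --- stage 3: pooled hybrid assembly, de-duplication, polishing ----------
  message(sprintf("[depthmeta] stage 3: %d pooled contigs", nrow(pooled)))
  # contigs of one organism can land in different depth strata (short
  # breakpoint-flanking contigs have noisy depth); a second anchoring/merge
  # pass over the pooled contigs joins them before redundancy removal
  lsub3 <- .subsample_ids(all_long$id,
                          min(1, config$long_subsample_depth *
                                sum(as.numeric(nchar(pooled$seq))) /
                                max(1, sum(nchar(all_long$seq)))),
                          seed = config$seed + 5000L)
  lr3 <- seq_set(lsub3, long_seq[lsub3])
  ch3 <- anchor_contigs(pooled, lr3, config$k_anchor,
                        config$min_anchor_kmers)
  # per-sample depth estimates on the pooled contigs (read subsample; only
  # within-sample ratios matter for the junction depth gate)
  idxP <- build_kmer_index(pooled, k = config$k_map)
  set.seed(config$seed + 6000L)
  subP <- sort(sample.int(nrow(all_r1), min(50000L, nrow(all_r1))))
  alnP <- map_short_reads(all_r1[subP, , drop = FALSE], idxP,
                          config$max_mismatch_frac)
  alnP$sample <- substr(alnP$read_id, 1L, 2L)
  depthsP <- compute_depths(alnP, idxP$contig_lengths)
  pooled <- hybrid_merge(pooled, ch3, lr3, config$min_support,
                         depth_profiles = depthsP, max_depth_ratio = 3)
  log <- .log_add(log, "stage3", "cross_stratum_junctions",
                  attr(pooled, "n_junctions") %||% 0L)
  dedup <- remove_redundancy(pooled, k = 15L)
  log <- .log_add(log, "stage3", "contigs_removed_redundant",
                  attr(dedup, "n_removed"))
  all_reads <- seq_set(c(paste0(all_r1$id, "/1"), paste0(all_r2$id, "/2")),
                       c(all_r1$seq, all_r2$seq))
  hybrid <- polish(dedup, all_reads, rounds = 1L,
                   k = config$k_map,
                   max_mismatch_frac = config$max_mismatch_frac)
  log <- .log_add(log, "stage3", "polish_corrections",
                  sum(attr(hybrid, "n_corrections")))

  # --- per-sample depths and mapping ratio on the final contigs ------------
  message("[depthmeta] mapping reads to the polished assembly")
  idxH <- build_kmer_index(hybrid, k = config$k_map)
  alnH1 <- list(); alnH2 <- list(); alnHL <- list()
  for (s in labs) {
    alnH1[[s]] <- map_short_reads(demo$short[[s]]$r1, idxH,
                                  config$max_mismatch_frac)
    alnH2[[s]] <- map_short_reads(demo$short[[s]]$r2, idxH,
                                  config$max_mismatch_frac)
    alnH1[[s]]$sample <- s; alnH2[[s]]$sample <- s
    alnHL[[s]] <- map_long_reads(long_kept[[s]], idxH,
                                 config$min_chain_seeds)
  }
  alnH_short <- do.call(rbind, unname(c(alnH1, alnH2)))
  depthsH <- compute_depths(alnH_short, idxH$contig_lengths)
  map_ratio_hybrid <- nrow(alnH_short) / n_reads_total
  map_ratio_short <- nrow(short_aln0) / n_reads_total
  log <- .log_add(log, "report", "mapping_ratio_short_only",
                  sprintf("%.4f", map_ratio_short))
  log <- .log_add(log, "report", "mapping_ratio_hybrid",
                  sprintf("%.4f", map_ratio_hybrid))

  # --- gene catalogs -------------------------------------------------------
  message("[depthmeta] gene catalogs")
  genes_short <- find_orfs(stage0, config$min_gene_length,
                           config$min_contig_length)
  genes_hybrid <- find_orfs(hybrid, config$min_gene_length,
                            config$min_contig_length)
  hgc <- cluster_nr(genes_short, config$cluster_identity,
                    config$cluster_coverage, label = "HGC")
  pdgc <- cluster_nr(genes_hybrid, config$cluster_identity,
                     config$cluster_coverage, label = "PDGC")
  catalogs <- list(hgc, pdgc)
  pogc <- NULL
  if (isTRUE(config$run_pogc)) {
    # plain (unpartitioned) hybrid route: merge stage-1 contigs directly
    # with a long-read subsample, no depth stratification
    lsub <- .subsample_ids(all_long$id,
                           min(1, config$long_subsample_depth *
                                 sum(as.numeric(nchar(stage0$seq))) /
                                 max(1, sum(nchar(all_long$seq)))),
                           seed = config$seed + 3000L)
    lr <- seq_set(lsub, long_seq[lsub])
    ch0 <- anchor_contigs(stage0, lr, config$k_anchor,
                          config$min_anchor_kmers)
    plain <- hybrid_merge(stage0, ch0, lr, config$min_support)
    plain <- remove_redundancy(plain, k = 15L)
    genes_plain <- find_orfs(plain, config$min_gene_length,
                             config$min_contig_length)
    if (nrow(genes_plain) > 0L) {
      pogc <- cluster_nr(genes_plain, config$cluster_identity,
                         config$cluster_coverage, label = "POGC")
      catalogs <- list(hgc, pogc, pdgc)
    }
  }
  rgc <- merge_catalogs(catalogs, config$cluster_identity,
                        config$cluster_coverage, label = "RGC")
  stats_tab <- do.call(rbind, lapply(c(catalogs, list(rgc)), catalog_stats))
  log <- .log_add(log, "catalog", "rgc_n_orfs", length(rgc$reps))

  # --- taxonomy: simulated hit table + LCA ---------------------------------
  message("[depthmeta] taxonomy")
  reps <- catalog_representatives(rgc)
  gidx <- build_kmer_index(truth$genomes, k = config$k_map)
  ghits <- dm_map_long(gidx$ptr, reps$seq, 3L, 0.2)
  mapped <- !is.na(ghits$contig)
  gene_taxa <- data.frame(
    gene_id = reps$gene_id[mapped],
    taxon_id = truth$genome_taxon$taxon_id[
      match(truth$genomes$id[ghits$contig[mapped]],
            truth$genome_taxon$genome_id)],
    stringsAsFactors = FALSE)
  hit_table <- generate_hit_table(truth, gene_taxa, config$n_hits_per_gene,
                                  config$decoy_rate, seed = demo$seeds[7])
  assignments <- assign_genes(hit_table, truth$taxonomy, config$max_evalue,
                              config$score_margin)
  # genes whose representative never located on a genome stay unclassified
  missing <- setdiff(reps$gene_id, assignments$gene_id)
  if (length(missing))
    assignments <- rbind(assignments,
                         data.frame(gene_id = missing, taxon_id = NA,
                                    rank = NA, n_hits_used = 0L))
  phylum_tab <- rank_summary(assignments, truth$taxonomy, "phylum")
  genus_tab <- rank_summary(assignments, truth$taxonomy, "genus")

  # --- binning + QC (hybrid and short-only, for comparison) ----------------
  message("[depthmeta] binning")
  bins_out <- .bin_and_qc(hybrid, depthsH, truth, config, log,
                          r1 = all_r1, r2 = all_r2,
                          aln1 = do.call(rbind, unname(alnH1)),
                          aln2 = do.call(rbind, unname(alnH2)),
                          long_reads = all_long,
                          aln_long = do.call(rbind, unname(alnHL)),
                          reassemble = TRUE)
  log <- bins_out$log
  bins_out$lineages <- .bin_lineages(bins_out$bins_original, pdgc, rgc,
                                     assignments,
                                     truth$taxonomy, config$agreement)
  bins_short <- tryCatch(
    .bin_and_qc(stage0, depths0, truth, config, log, reassemble = FALSE),
    error = function(e) NULL)
  if (!is.null(bins_short)) log <- bins_short$log

  # --- reports -------------------------------------------------------------
  set.seed(config$seed + 4000L)
  sub_idx <- sort(sample.int(nrow(all_reads),
                             min(config$read_map_sample, nrow(all_reads))))
  sub_reads <- all_reads[sub_idx, , drop = FALSE]
  stats_short <- assembly_stats(stage0, reads = sub_reads)
  stats_hybrid <- assembly_stats(hybrid, reads = sub_reads)
  comparison <- compare_runs(list(stats_short, stats_hybrid),
                             c("short_only", "depth_hybrid"))
  log <- .log_add(log, "report", "n50_short_only", stats_short$n50)
  log <- .log_add(log, "report", "n50_hybrid", stats_hybrid$n50)
  log <- .log_add(log, "done", "elapsed_s",
                  sprintf("%.1f", as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
  res <- list(
    config = config, demo = demo, truth = truth,
    short_only = stage0, hybrid = hybrid,
    partition = part, depths_short_only = depths0, depths_hybrid = depthsH,
    pair_bins = pair_bin_all, long_bins = long_bin_all,
    catalogs = setNames(catalogs, vapply(catalogs, `[[`, "", "label")),
    rgc = rgc, catalog_stats = stats_tab,
    hit_table = hit_table, assignments = assignments,
    phylum_summary = phylum_tab, genus_summary = genus_tab,
    bins = bins_out$bins, bin_scores = bins_out$scores,
    bins_kept = bins_out$kept, bin_lineages = bins_out$lineages,
    bin_metrics_hybrid = bins_out$metrics,
    bin_metrics_short = if (!is.null(bins_short)) bins_short$metrics else NULL,
    bins_kept_short = if (!is.null(bins_short)) bins_short$kept else NULL,
    mapping_ratio_short_only = map_ratio_short,
    mapping_ratio_hybrid = map_ratio_hybrid,
    stats_short_only = stats_short, stats_hybrid = stats_hybrid,
    comparison = comparison, log = log)
  if (!is.null(out_dir)) .write_artifacts(res, out_dir)
  invisible(res)
}

# per-bin majority lineage: genes on the bin's contigs are followed through
# their catalog cluster representative into the merged-catalog assignment
.bin_lineages <- function(bins, catalog, rgc, assignments, tree, agreement) {
  g <- catalog$genes
  rep_in_rgc <- setNames(rgc$genes$rep_id, rgc$genes$gene_id)
  asg <- setNames(assignments$taxon_id, assignments$gene_id)
  out <- lapply(names(bins), function(b) {
    gsub <- g[g$contig_id %in% bins[[b]]$id, , drop = FALSE]
    if (nrow(gsub) == 0L)
      return(data.frame(bin_id = b, taxon_id = NA, rank = NA, share = NA,
                        n_genes = 0L, stringsAsFactors = FALSE))
    qual <- paste0(catalog$label, ":", gsub$rep_id)
    taxa <- asg[rep_in_rgc[qual]]
    taxa <- taxa[!is.na(taxa)]
    if (!length(taxa))
      return(data.frame(bin_id = b, taxon_id = NA, rank = NA, share = NA,
                        n_genes = nrow(gsub), stringsAsFactors = FALSE))
    ml <- majority_lineage(unname(taxa), tree, agreement)
    data.frame(bin_id = b, taxon_id = ml$taxon_id, rank = ml$rank,
               share = ml$share, n_genes = nrow(gsub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# binning, marker QC, filtering, lineage, optional re-assembly
.bin_and_qc <- function(contigs, depths, truth, config, log,
                        r1 = NULL, r2 = NULL, aln1 = NULL, aln2 = NULL,
                        long_reads = NULL, aln_long = NULL,
                        reassemble = FALSE) {
  binres <- bin_contigs(contigs, depths, config$bin_min_contig,
                        n_bins = "auto",
                        depth_weight = config$bin_depth_weight)
  asg <- binres$assignments
  bins <- lapply(split(asg$contig_id, asg$bin_id), function(ids) {
    out <- contigs[match(ids, contigs$id), , drop = FALSE]
    class(out) <- c("dm_seqs", "data.frame")
    out
  })
  bins_original <- bins
  scores <- do.call(rbind, lapply(names(bins), function(b) {
    ev <- evaluate_bin(bins[[b]], truth$marker_seqs)
    data.frame(bin_id = b, n_contigs = nrow(bins[[b]]),
               completeness = ev$completeness,
               contamination = ev$contamination, stringsAsFactors = FALSE)
  }))
  if (reassemble && !is.null(r1)) {
    # re-assemble every imperfect bin from its own mapped reads: a bin's
    # read set is organism-pure, so markers lost to inter-organism graph
    # breaks or error-ridden junction fills reassemble cleanly
    # (improve-or-keep guards against regressions)
    redo <- scores$bin_id[scores$contamination >
                            config$reassemble_contamination |
                            scores$completeness < 1]
    for (b in redo) {
      rb <- reassemble_bin(bins[[b]], r1, r2, aln1, aln2, long_reads,
                           aln_long, truth$marker_seqs,
                           k = config$k_assembly,
                           min_kmer_count = config$min_kmer_count,
                           k_anchor = config$k_anchor,
                           min_anchor_kmers = config$min_anchor_kmers,
                           min_support = config$min_support)
      log <- .log_add(log, "rebin", b,
                      sprintf("accepted=%s contam %.3f->%.3f", rb$accepted,
                              rb$before$contamination,
                              rb$scores$contamination))
      if (rb$accepted) {
        bins[[b]] <- rb$contigs
        i <- match(b, scores$bin_id)
        scores$completeness[i] <- rb$scores$completeness
        scores$contamination[i] <- rb$scores$contamination
        scores$n_contigs[i] <- nrow(rb$contigs)
      }
    }
  }
  kept <- filter_bins(scores, config$min_completeness,
                      config$max_contamination)
  lineages <- NULL
  metrics <- bin_metrics(bins, truth$marker_seqs,
                         config$min_gene_length, config$min_contig_length)
  log <- .log_add(log, "bin", "n_bins", nrow(scores))
  log <- .log_add(log, "bin", "n_bins_kept", nrow(kept))
  list(bins = bins, bins_original = bins_original, scores = scores,
       kept = kept, lineages = lineages, metrics = metrics, log = log)
}

.write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(res$short_only, file.path(out_dir, "contigs_short_only.fasta"))
  write_fasta(res$hybrid, file.path(out_dir, "contigs_depth_hybrid.fasta"))
  wt(res$partition$contigs, "contig_phylotypes.tsv")
  wt(res$depths_hybrid, "depths_hybrid.tsv")
  wt(res$catalog_stats, "catalog_stats.tsv")
  wt(res$phylum_summary, "taxonomy_phylum.tsv")
  wt(res$genus_summary, "taxonomy_genus.tsv")
  wt(res$bin_scores, "bin_scores.tsv")
  wt(res$bin_metrics_hybrid, "bin_metrics_hybrid.tsv")
  if (!is.null(res$bin_metrics_short))
    wt(res$bin_metrics_short, "bin_metrics_short_only.tsv")
  wt(res$comparison, "run_comparison.tsv")
  wt(res$log, "pipeline_log.tsv")
  manifest <- do.call(rbind, lapply(names(res$bins), function(b)
    data.frame(bin_id = b, contig_id = res$bins[[b]]$id,
               stringsAsFactors = FALSE)))
  wt(manifest, "bin_manifest.tsv")
  write_truth(res$truth, file.path(out_dir, "truth"), res$demo$abundances)
  invisible(out_dir)
}
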