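# Tetranucleotide-frequency + depth genome binning, single-copy-marker
# completeness/contamination, bin filters, majority lineage and the bin
# re-assembly loop.

#' Canonical tetranucleotide class labels
#' @return character vector of the 136 canonical 4-mers ((256 + 16) / 2),
#'   each the lexicographically smaller of a 4-mer and its reverse
#'   complement, sorted.
#' @export
canonical_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  all4 <- as.vector(outer(outer(outer(b, b, paste0), b, paste0), b, paste0))
  rc <- dm_revcomp(all4)
  sort(unique(pmin(all4, rc)))
}

#' Tetranucleotide frequency vector (canonical, 136 classes)
#'
#' 4-mers are identified with their reverse complements; windows containing
#' N are skipped; frequencies sum to 1.
#'
#' @param seq a single nucleotide string (length >= 4).
#' @return named numeric vector of length 136.
#' @export
tnf_vector <- function(seq) {
  .dm_assert(nchar(seq) >= 4L, "sequence shorter than 4 bp")
  v <- dm_tnf(seq)[1, ]
  names(v) <- canonical_tetramers()
  v
}

#' Bin contigs by tetranucleotide frequency and per-sample depth
#'
#' Contigs longer than `min_contig_length` (strict) are described by their
#' canonical TNF vector concatenated with `log10(depth + 0.1)` per sample;
#' features are standardized and block-normalized, with the depth block
#' up-weighted by `depth_weight`. Average-linkage agglomerative clustering
#' is cut either at a requested number of bins or, when `n_bins = "auto"`,
#' at a fixed height (1.5) on the standardized feature scale, validated by
#' the mean silhouette of the non-singleton clusters (weak structure
#' collapses to a single bin). Deterministic; contig input order is
#' irrelevant.
#'
#' @param contigs `dm_seqs`.
#' @param depths long-format depth table from [compute_depths()].
#' @param min_contig_length contigs at or below this length stay unbinned.
#' @param n_bins integer or `"auto"`.
#' @param depth_weight weight multiplier of the depth features.
#' @param seed kept for interface stability; the procedure is deterministic.
#' @return list with `assignments` (data.frame `contig_id`, `bin_id`),
#'   `unbinned` (contig ids below the length filter) and `n_bins`.
#' @export
bin_contigs <- function(contigs, depths, min_contig_length = 2500L,
                        n_bins = "auto", depth_weight = 2, seed = 1L) {
  len <- setNames(nchar(contigs$seq), contigs$id)
  eligible <- contigs$id[len[contigs$id] > min_contig_length]
  .dm_assert(length(eligible) >= 2L,
             "need at least 2 contigs above the length filter")
  eligible <- sort(eligible)
  tnf <- dm_tnf(contigs$seq[match(eligible, contigs$id)])
  samples <- sort(unique(depths$sample))
  dmat <- vapply(samples, function(s) {
    d <- depths[depths$sample == s, ]
    log10(d$mean_depth[match(eligible, d$contig_id)] + 0.1)
  }, numeric(length(eligible)))
  dmat <- matrix(dmat, nrow = length(eligible))
  feat <- cbind(tnf, dmat)
  sds <- apply(feat, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  feat <- sweep(sweep(feat, 2, colMeans(feat)), 2, sds, "/")
  # block-normalize so composition and depth contribute comparably, then
  # up-weight the depth block (differential coverage carries most signal)
  feat[, seq_len(ncol(tnf))] <- feat[, seq_len(ncol(tnf))] / sqrt(ncol(tnf))
  feat[, ncol(tnf) + seq_along(samples)] <-
    feat[, ncol(tnf) + seq_along(samples), drop = FALSE] *
    depth_weight / sqrt(length(samples))
  D <- stats::dist(feat)
  hc <- stats::hclust(D, method = "average")
  if (identical(n_bins, "auto")) {
    cl <- .auto_bins(D, hc)
    k <- length(unique(cl))
  } else {
    k <- max(1L, min(as.integer(n_bins), length(eligible)))
    cl <- stats::cutree(hc, k = k)
  }
  # label bins by decreasing total bp for stable, meaningful ids
  bp <- tapply(as.numeric(len[eligible]), cl, sum)
  ord <- order(-bp, as.integer(names(bp)))
  relabel <- setNames(seq_along(ord), names(bp)[ord])
  bin_id <- sprintf("GB%03d", relabel[as.character(cl)])
  list(assignments = data.frame(contig_id = eligible, bin_id = bin_id,
                                stringsAsFactors = FALSE),
       unbinned = setdiff(contigs$id, eligible),
       n_bins = k)
}

# cut the dendrogram at a fixed height on the standardized feature scale
# (same-organism contigs merge well below 1.5; different organisms above),
# then validate: if the resulting non-singleton clusters show no silhouette
# structure the data is homogeneous and everything collapses to one bin
.auto_bins <- function(D, hc, cut_height = 1.5, min_sil = 0.25) {
  n <- attr(D, "Size")
  if (n < 3L) return(rep(1L, n))
  cl <- stats::cutree(hc, h = cut_height)
  if (length(unique(cl)) %in% c(1L, n)) return(cl)
  Dm <- as.matrix(D)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]
    if (sum(own) == 1L) return(NA_real_)
    a <- mean(Dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(Dm[i, cl == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  if (all(is.na(s)) || mean(s, na.rm = TRUE) >= min_sil) cl else rep(1L, n)
}

#' Marker census, completeness and contamination of a bin
#'
#' Markers are detected by near-exact search (at least `min_identity` over
#' the full marker length) in the bin contigs. Completeness is the fraction
#' of markers present at least once; contamination is the summed excess copy
#' count over the marker-set size.
#'
#' @param bin_contigs `dm_seqs` of the bin's contigs.
#' @param markers `dm_seqs` of the single-copy marker sequences (size M).
#' @param min_identity detection identity threshold.
#' @param k seed size for the search.
#' @return list with `census` (named integer, copies per marker),
#'   `completeness` in \[0, 1\] and `contamination` >= 0.
#' @export
evaluate_bin <- function(bin_contigs, markers, min_identity = 0.95, k = 21L) {
  .dm_assert(nrow(markers) > 0L, "marker set is empty")
  census <- setNames(integer(nrow(markers)), markers$id)
  if (nrow(bin_contigs) > 0L) {
    idx <- build_kmer_index(bin_contigs, k = k)
    occ <- dm_map_occurrences(idx$ptr, markers$seq, 1 - min_identity)
    if (nrow(occ)) {
      tab <- table(markers$id[occ$query])
      census[names(tab)] <- as.integer(tab)
    }
  }
  M <- length(census)
  list(census = census,
       completeness = sum(census >= 1L) / M,
       contamination = sum(pmax(0L, census - 1L)) / M)
}

#' Filter bins on completeness and contamination
#'
#' Discard conditions are strict (completeness < `min_completeness` or
#' contamination > `max_contamination`), so boundary values are kept.
#'
#' @param scores data.frame with `bin_id`, `completeness`, `contamination`.
#' @param min_completeness completeness floor.
#' @param max_contamination contamination ceiling.
#' @return the kept rows of `scores`.
#' @export
filter_bins <- function(scores, min_completeness = 0.60,
                        max_contamination = 0.20) {
  keep <- scores$completeness >= min_completeness &
    scores$contamination <= max_contamination
  scores[keep, , drop = FALSE]
}

#' Majority lineage from per-marker classifications
#'
#' Walking from species upward, reports the deepest rank at which one taxon
#' holds at least `agreement` of the classifications (classifications that
#' do not reach a rank count in the denominator but agree with nothing).
#'
#' @param classifications character vector of taxon ids.
#' @param tree `dm_taxonomy`.
#' @param agreement required agreement fraction.
#' @return list with `taxon_id` (`NA` = UNRESOLVED), `rank`, `share`.
#' @export
majority_lineage <- function(classifications, tree, agreement = 0.75) {
  .dm_assert(length(classifications) >= 1L, "no classifications")
  n <- length(classifications)
  for (rank in rev(setdiff(.RANKS, "root"))) {
    proj <- vapply(classifications, function(t)
      tax_ancestor_at_rank(tree, t, rank), "", USE.NAMES = FALSE)
    proj <- proj[!is.na(proj)]
    if (!length(proj)) next
    tab <- sort(table(proj), decreasing = TRUE)
    if (tab[1] / n >= agreement)
      return(list(taxon_id = names(tab)[1], rank = rank,
                  share = as.numeric(tab[1]) / n))
  }
  list(taxon_id = NA_character_, rank = NA_character_, share = NA_real_)
}

#' Re-assemble a bin from its mapped reads
#'
#' Collects read pairs and long reads whose primary alignments target the
#' bin's contigs, reruns the short-read assembly, anchoring, hybrid merge and
#' polishing, and replaces the bin iff contamination decreases, or
#' completeness increases without a contamination increase.
#'
#' @param bin_contigs `dm_seqs` of the current bin.
#' @param r1,r2 short read mates (`dm_seqs`).
#' @param aln1,aln2 their primary alignments against the full contig set.
#' @param long_reads `dm_seqs` of long reads (may be empty).
#' @param aln_long long-read alignments.
#' @param markers marker set for scoring.
#' @param k assembly k-mer size.
#' @param min_kmer_count abundance floor, or `"auto"` (median-scaled) after
#'   the bin's reads are subsampled to ~60x coverage.
#' @param k_anchor,min_anchor_kmers,min_support stage knobs.
#' @return list with `contigs`, `scores` (completeness/contamination),
#'   `accepted` (TRUE when the re-assembly replaced the bin), `before`
#'   (original scores) and `n_reads_used`.
#' @export
reassemble_bin <- function(bin_contigs, r1, r2, aln1, aln2, long_reads,
                           aln_long, markers, k = 31L,
                           min_kmer_count = "auto",
                           k_anchor = 17L, min_anchor_kmers = 10L,
                           min_support = 2L) {
  before <- evaluate_bin(bin_contigs, markers)
  ids <- bin_contigs$id
  pair_ids <- union(aln1$read_id[aln1$contig_id %in% ids],
                    aln2$read_id[aln2$contig_id %in% ids])
  # paired-end link recruitment: an outside contig whose read pairs link
  # almost exclusively into this bin is a stranded fragment of the same
  # organism (short contigs fall below the binning length filter); shared
  # elements link into many bins and fail the purity requirement
  m1 <- setNames(aln1$contig_id, aln1$read_id)
  m2 <- setNames(aln2$contig_id, aln2$read_id)
  all_pairs <- union(aln1$read_id, aln2$read_id)
  c1 <- m1[all_pairs]; c2 <- m2[all_pairs]
  cross1 <- !is.na(c1) & !is.na(c2) & (c1 %in% ids) & !(c2 %in% ids)
  cross2 <- !is.na(c1) & !is.na(c2) & (c2 %in% ids) & !(c1 %in% ids)
  link_in <- table(c(c2[cross1], c1[cross2]))
  outside <- setdiff(unique(c(c1, c2)), c(ids, NA))
  for (X in names(link_in)[link_in >= 2L]) {
    on_x <- !is.na(c1) & c1 == X | !is.na(c2) & c2 == X
    partner <- ifelse(!is.na(c1) & c1 == X, c2, c1)
    ext <- on_x & !is.na(partner) & partner != X
    if (sum(ext) == 0L) next
    purity <- mean(partner[ext] %in% ids)
    if (purity >= 0.8) pair_ids <- union(pair_ids, all_pairs[on_x])
  }
  if (length(pair_ids) == 0L) {
    warning("bin has no mapped reads; returning it unchanged")
    return(list(contigs = bin_contigs,
                scores = before, accepted = FALSE, before = before,
                n_reads_used = 0L))
  }
  # cap coverage (very deep bins shred the graph with error k-mers) and let
  # the abundance floor adapt to the subsampled depth
  bin_bp <- sum(nchar(bin_contigs$seq))
  frac <- min(1, 60 * bin_bp / max(1, 300 * length(pair_ids)))
  if (frac < 1) {
    set.seed(20000L + length(pair_ids) %% 10000L)
    pair_ids <- sort(sample(pair_ids, ceiling(frac * length(pair_ids))))
  }
  reads <- rbind(r1[r1$id %in% pair_ids, c("id", "seq")],
                 r2[r2$id %in% pair_ids, c("id", "seq")])
  if (identical(min_kmer_count, "auto"))
    min_kmer_count <- max(2L, min(10L, as.integer(
      round(kmer_median_count(reads$seq, k) / 8))))
  asm <- assemble_short_reads(reads$seq, k = k,
                              min_kmer_count = min_kmer_count,
                              id_prefix = "rb")
  if (nrow(asm) == 0L)
    return(list(contigs = bin_contigs, scores = before, accepted = FALSE,
                before = before, n_reads_used = 2L * length(pair_ids)))
  lr_ids <- aln_long$read_id[aln_long$contig_id %in% ids]
  lr <- long_reads[long_reads$id %in% lr_ids, , drop = FALSE]
  if (nrow(lr) > 0L) {
    chains <- anchor_contigs(asm, lr, k_anchor = k_anchor,
                             min_anchor_kmers = min_anchor_kmers)
    asm <- hybrid_merge(asm, chains, lr, min_support = min_support)
  }
  asm <- remove_redundancy(asm)
  asm <- polish(asm, reads)
  after <- evaluate_bin(asm, markers)
  # improve-or-keep: a gain on one axis must not cost the other
  accept <- (after$contamination < before$contamination &&
               after$completeness >= before$completeness) ||
    (after$completeness > before$completeness &&
       after$contamination <= before$contamination)
  list(contigs = if (accept) asm else bin_contigs,
       scores = if (accept) after else before,
       accepted = accept, before = before,
       n_reads_used = 2L * length(pair_ids))
}

#' Per-bin metrics table
#'
#' @param bins named list of `dm_seqs` (one element per bin).
#' @param markers marker set for completeness/contamination.
#' @param min_gene_length,min_contig_length ORF scanner settings.
#' @return data.frame (`bin_id`, `n_contigs`, `total_bp`, `n50`, `n_genes`,
#'   `completeness`, `contamination`) with attribute `medians`.
#' @export
bin_metrics <- function(bins, markers = NULL, min_gene_length = 100L,
                        min_contig_length = 500L) {
  .dm_assert(length(bins) >= 1L, "no bins")
  rows <- lapply(names(bins), function(b) {
    ctg <- bins[[b]]
    ev <- if (!is.null(markers)) evaluate_bin(ctg, markers) else
      list(completeness = NA_real_, contamination = NA_real_)
    data.frame(bin_id = b, n_contigs = nrow(ctg),
               total_bp = sum(nchar(ctg$seq)),
               n50 = n50(nchar(ctg$seq)),
               n_genes = nrow(find_orfs(ctg, min_gene_length,
                                        min_contig_length)),
               completeness = ev$completeness,
               contamination = ev$contamination,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "medians") <- vapply(
    c("n_contigs", "total_bp", "n50", "n_genes"),
    function(cn) stats::median(out[[cn]]), numeric(1))
  out
}
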