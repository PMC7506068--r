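# ORF prediction on contigs, completeness classification, greedy
# non-redundant catalog construction, catalog merging and statistics.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.orfs_one_strand <- function(t, L, strand, min_gene_length) {
  rows <- list()
  for (f in 0:2) {
    n_codons <- (nchar(t) - f) %/% 3L
    if (n_codons < 1L) next
    starts <- f + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(t, starts, starts + 2L)
    stops <- which(codons %in% .STOP_CODONS)
    atgs <- which(codons == "ATG")
    if (length(stops)) {
      # first ATG strictly after the previous stop, per inter-stop segment
      prevs <- c(0L, stops[-length(stops)])
      ai <- findInterval(prevs, atgs) + 1L
      cand <- atgs[ai]
      has_atg <- !is.na(cand) & cand < stops
      a <- cand[has_atg]; s <- stops[has_atg]
      len <- 3L * (s - a + 1L)
      ok <- len >= min_gene_length
      if (any(ok))
        rows[[length(rows) + 1L]] <- cbind(f + 3L * (a[ok] - 1L),
                                           f + 3L * s[ok], 1L)
      # contig starts mid-gene: edge-truncated run up to the first stop
      if (!has_atg[1] && 3L * stops[1] >= min_gene_length)
        rows[[length(rows) + 1L]] <- cbind(f, f + 3L * stops[1], 0L)
    }
    # run after the last stop (or the whole frame when no stop): truncated
    prev <- if (length(stops)) stops[length(stops)] else 0L
    a <- atgs[atgs > prev]
    st <- if (length(a)) a[1] else if (prev == 0L) 1L else NA_integer_
    if (!is.na(st) && st <= n_codons) {
      len <- 3L * (n_codons - st + 1L)
      if (len >= min_gene_length)
        rows[[length(rows) + 1L]] <- cbind(f + 3L * (st - 1L),
                                           f + 3L * n_codons, 0L)
    }
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  df <- data.frame(start_t = m[, 1], end_t = m[, 2],
                   complete = m[, 3] == 1L)
  if (strand == "+") {
    df$start <- df$start_t; df$end <- df$end_t
  } else {
    df$start <- L - df$end_t; df$end <- L - df$start_t
  }
  df$seq <- substring(t, df$start_t + 1L, df$end_t)
  df$strand <- strand
  df[, c("start", "end", "strand", "seq", "complete")]
}

#' Predict open reading frames on contigs
#'
#' Contigs shorter than `min_contig_length` are skipped. All six frames are
#' scanned; an ORF is a maximal in-frame run ending at a stop codon
#' (TAA/TAG/TGA) and starting at the first ATG after the previous stop.
#' `complete` is TRUE iff both the ATG and the stop codon lie within the
#' contig; edge-truncated runs of at least `min_gene_length` are reported
#' with `complete = FALSE`. Reported lengths include the stop codon.
#'
#' @param contigs `dm_seqs`.
#' @param min_gene_length minimum ORF length in bp.
#' @param min_contig_length minimum contig length in bp.
#' @return data.frame (`gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `seq`, `complete`), coordinates 0-based half-open on the forward contig.
#' @export
find_orfs <- function(contigs, min_gene_length = 100L,
                      min_contig_length = 500L) {
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    L <- nchar(contigs$seq[i])
    if (L < min_contig_length) next
    fwd <- contigs$seq[i]
    rev <- dm_revcomp(fwd)
    df <- rbind(.orfs_one_strand(fwd, L, "+", min_gene_length),
                .orfs_one_strand(rev, L, "-", min_gene_length))
    if (is.null(df) || nrow(df) == 0L) next
    df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
    df$gene_id <- sprintf("%s_%d", contigs$id[i], seq_len(nrow(df)))
    df$contig_id <- contigs$id[i]
    out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      complete = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "contig_id", "start", "end", "strand", "seq", "complete")]
}

#' Rounded average representative length (2 decimals)
#' @param n_orfs number of representatives.
#' @param total_length summed representative length in bp.
#' @return `round(total_length / n_orfs, 2)`.
#' @export
catalog_average_length <- function(n_orfs, total_length) {
  .dm_assert(all(n_orfs > 0), "empty catalog")
  round(total_length / n_orfs, 2)
}

#' Rounded percentage (2 decimals)
#' @param count numerator.
#' @param total denominator (> 0).
#' @return `round(100 * count / total, 2)`.
#' @export
percentage <- function(count, total) {
  .dm_assert(all(total > 0), "percentage of an empty set")
  round(100 * count / total, 2)
}

#' Build a non-redundant gene catalog by greedy clustering
#'
#' Genes are sorted by length descending (ties: sequence ascending); each
#' gene joins the first existing cluster whose representative aligns to it
#' ungapped (best seed-voted offset, better strand) at >= `min_identity`
#' over >= `min_coverage` of the shorter sequence, else founds a new
#' cluster. Identity is matches / aligned columns; coverage is the aligned
#' overlap over the shorter length (CD-HIT convention). Deterministic.
#'
#' @param genes data.frame from [find_orfs()] (needs `gene_id`, `seq`,
#'   `complete`; a `source_catalog` column is carried through).
#' @param min_identity identity cut-off.
#' @param min_coverage length-coverage cut-off.
#' @param k seed k-mer size for the aligner.
#' @param label catalog label (HGC/POGC/PDGC/RGC/custom).
#' @return object of class `dm_catalog`: list with `label`, `genes` (sorted,
#'   with `rep_id`, `identity`, `coverage`), `clusters` (member to
#'   representative map) and `reps` (representative gene ids in founding
#'   order).
#' @export
cluster_nr <- function(genes, min_identity = 0.95, min_coverage = 0.90,
                       k = 15L, label = "custom") {
  .dm_assert(nrow(genes) >= 1L, "no genes to cluster")
  g <- genes[order(-nchar(genes$seq), genes$seq), , drop = FALSE]
  rownames(g) <- NULL
  cl <- dm_greedy_cluster(g$seq, as.integer(k), min_identity, min_coverage)
  g$rep_id <- g$gene_id[cl$rep]
  g$identity <- cl$identity
  g$coverage <- cl$coverage
  reps <- g$gene_id[cl$rep == seq_len(nrow(g))]
  structure(list(label = label, genes = g,
                 clusters = g[, c("gene_id", "rep_id", "identity", "coverage")],
                 reps = reps),
            class = "dm_catalog")
}

#' @export
print.dm_catalog <- function(x, ...) {
  cat(sprintf("dm_catalog '%s': %d clusters from %d genes\n",
              x$label, length(x$reps), nrow(x$genes)))
  invisible(x)
}

#' Representative gene records of a catalog
#' @param catalog `dm_catalog`.
#' @return data.frame of representative rows.
#' @export
catalog_representatives <- function(catalog) {
  catalog$genes[match(catalog$reps, catalog$genes$gene_id), , drop = FALSE]
}

#' Merge catalogs into a reference catalog
#'
#' Pools all representatives and re-clusters them with the same thresholds.
#' Each merged cluster records which source catalogs contributed members.
#'
#' @param catalogs list of >= 2 `dm_catalog` objects.
#' @param min_identity,min_coverage,k as in [cluster_nr()].
#' @param label label of the merged catalog.
#' @return `dm_catalog` whose `cluster_sources` maps representative id to the
#'   sorted, comma-separated source catalog labels.
#' @export
merge_catalogs <- function(catalogs, min_identity = 0.95, min_coverage = 0.90,
                           k = 15L, label = "RGC") {
  .dm_assert(length(catalogs) >= 2L, "need at least two catalogs to merge")
  pooled <- do.call(rbind, lapply(catalogs, function(ct) {
    r <- catalog_representatives(ct)
    r$source_catalog <- ct$label
    r[, c("gene_id", "contig_id", "start", "end", "strand", "seq",
          "complete", "source_catalog")]
  }))
  # gene ids may collide across catalogs; qualify with the source label
  pooled$gene_id <- paste(pooled$source_catalog, pooled$gene_id, sep = ":")
  out <- cluster_nr(pooled, min_identity = min_identity,
                    min_coverage = min_coverage, k = k, label = label)
  src <- tapply(out$genes$source_catalog, out$genes$rep_id, function(s)
    paste(sort(unique(s)), collapse = ","))
  out$cluster_sources <- setNames(as.character(src), names(src))
  out
}

#' Catalog statistics (table style)
#'
#' `n_orfs` counts clusters; lengths and completeness are over
#' representatives only. `average_length` and `pct_complete` are rounded to
#' two decimals.
#'
#' @param catalog `dm_catalog`.
#' @return one-row data.frame (`label`, `n_orfs`, `total_length`,
#'   `average_length`, `pct_complete`).
#' @export
catalog_stats <- function(catalog) {
  reps <- catalog_representatives(catalog)
  .dm_assert(nrow(reps) > 0L, "empty catalog")
  n <- nrow(reps)
  total <- sum(nchar(reps$seq))
  data.frame(label = catalog$label, n_orfs = n, total_length = total,
             average_length = catalog_average_length(n, total),
             pct_complete = percentage(sum(reps$complete), n),
             stringsAsFactors = FALSE)
}

#' Map short reads to catalog representatives
#'
#' @param reads `dm_seqs` of short reads.
#' @param catalog `dm_catalog`.
#' @param k,max_mismatch_frac mapper settings.
#' @return list with `mapping_ratio` (mapped / total reads) and
#'   `unmapped_gene_ids` (representatives receiving zero reads).
#' @export
map_reads_to_catalog <- function(reads, catalog, k = 21L,
                                 max_mismatch_frac = 0.05) {
  reps <- catalog_representatives(catalog)
  idx <- build_kmer_index(seq_set(reps$gene_id, reps$seq), k = k)
  aln <- map_short_reads(reads, idx, max_mismatch_frac = max_mismatch_frac)
  list(mapping_ratio = nrow(aln) / nrow(reads),
       unmapped_gene_ids = setdiff(reps$gene_id, unique(aln$contig_id)))
}
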