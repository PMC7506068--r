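# Built-in k-mer mapper, per-contig coverage depth, and the depth-based
# partitioning of contigs and reads into phylotypes.

#' Build a canonical k-mer seed index over contigs
#'
#' @param contigs `dm_seqs` data.frame (`id`, `seq`).
#' @param k odd seed length, 11-31.
#' @return object of class `dm_kmer_index`.
#' @export
build_kmer_index <- function(contigs, k = 21L) {
  .dm_assert(k %% 2L == 1L, "k must be odd")
  .dm_assert(k >= 11L && k <= 31L, "k must be in [11, 31]")
  .dm_assert(nrow(contigs) > 0L, "no contigs to index")
  ptr <- dm_index_build(contigs$seq, contigs$id, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), contig_ids = contigs$id,
                 contig_lengths = setNames(nchar(contigs$seq), contigs$id)),
            class = "dm_kmer_index")
}

#' @export
print.dm_kmer_index <- function(x, ...) {
  info <- dm_index_info(x$ptr)
  cat(sprintf("dm_kmer_index: k=%d, %d contigs, %.0f seed positions, %.0f distinct k-mers\n",
              x$k, length(x$contig_ids), info$n_positions, info$n_kmers))
  invisible(x)
}

#' Seed index summary (number of indexed positions and distinct k-mers)
#' @param index `dm_kmer_index`.
#' @return list with `k`, `n_positions`, `n_kmers`, `contig_ids`,
#'   `contig_lengths`.
#' @export
kmer_index_info <- function(index) dm_index_info(index$ptr)

#' Dump indexed k-mer positions (small indexes; test support)
#' @param index `dm_kmer_index`.
#' @return data.frame (`kmer`, `contig_id`, `pos`, `rc`).
#' @export
kmer_index_dump <- function(index) dm_index_dump(index$ptr)

.aln_from_cpp <- function(hits, read_ids, index, primary = TRUE) {
  mapped <- !is.na(hits$contig)
  out <- data.frame(
    read_id = read_ids[mapped],
    contig_id = index$contig_ids[hits$contig[mapped]],
    start = hits$start[mapped],
    end = hits$end[mapped],
    strand = hits$strand[mapped],
    score = hits$score[mapped],
    offset = if (is.null(hits$offset)) hits$start[mapped] else
      hits$offset[mapped],
    is_primary = rep(primary, sum(mapped)),
    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Map short reads by seed voting and ungapped verification
#'
#' The candidate placement with most seed hits wins (ties broken by contig id,
#' then position, then strand) and is accepted when its mismatch count does
#' not exceed `max_mismatch_frac` of the read length. One primary placement
#' per read at most; unmapped reads are excluded and counted in the
#' `n_unmapped` attribute.
#'
#' @param reads `dm_seqs`.
#' @param index `dm_kmer_index`.
#' @param max_mismatch_frac maximum mismatch fraction (of the overlap).
#' @param min_overlap_frac reads may overhang contig ends (end-clipping);
#'   the overlap must reach this fraction of the read length.
#' @return alignment data.frame with attribute `n_unmapped`; `start`/`end`
#'   are clipped to the contig, `offset` is the unclipped placement.
#' @export
map_short_reads <- function(reads, index, max_mismatch_frac = 0.05,
                            min_overlap_frac = 0.5) {
  hits <- dm_map_short(index$ptr, reads$seq, max_mismatch_frac,
                       min_overlap_frac)
  .aln_from_cpp(hits, reads$id, index)
}

#' Map long reads by banded seed chaining
#'
#' Seeds are binned by (contig, strand, diagonal) with a band of
#' `band_frac` x read length; the best adjacent-band window wins when it
#' holds at least `min_chain_seeds` seeds. The reported interval spans the
#' first to last chained seed.
#'
#' @param reads `dm_seqs`.
#' @param index `dm_kmer_index`.
#' @param min_chain_seeds minimum seeds in the winning window.
#' @param band_frac diagonal band width as a fraction of read length.
#' @return alignment data.frame with attribute `n_unmapped`.
#' @export
map_long_reads <- function(reads, index, min_chain_seeds = 5L,
                           band_frac = 0.2) {
  hits <- dm_map_long(index$ptr, reads$seq, as.integer(min_chain_seeds),
                      band_frac)
  .aln_from_cpp(hits, reads$id, index)
}

#' Per-contig mean coverage depth
#'
#' `mean_depth` is the sum of aligned reference-span bases divided by contig
#' length, computed per sample.
#'
#' @param alignments alignment data.frame; a `sample` column (or the `sample`
#'   argument) labels samples.
#' @param contig_lengths named integer vector of contig lengths.
#' @param sample optional single sample label applied to all alignments.
#' @return data.frame (`contig_id`, `sample`, `mean_depth`, `n_mapped_reads`)
#'   with one row per contig x sample (zeros included).
#' @export
compute_depths <- function(alignments, contig_lengths, sample = NULL) {
  if (!is.null(sample)) alignments$sample <- sample
  if (is.null(alignments$sample)) alignments$sample <- "sample1"
  .dm_assert(all(alignments$contig_id %in% names(contig_lengths)),
             "alignment references unknown contig")
  samples <- sort(unique(alignments$sample))
  if (length(samples) == 0L) samples <- "sample1"
  grid <- expand.grid(contig_id = names(contig_lengths), sample = samples,
                      stringsAsFactors = FALSE)
  if (nrow(alignments)) {
    dt <- data.table::as.data.table(alignments)
    agg <- dt[, list(bases = sum(as.numeric(end - start)),
                     n_mapped_reads = .N),
              by = c("contig_id", "sample")]
    m <- merge(grid, as.data.frame(agg), all.x = TRUE,
               by = c("contig_id", "sample"))
  } else {
    m <- grid; m$bases <- NA_real_; m$n_mapped_reads <- NA_integer_
  }
  m$bases[is.na(m$bases)] <- 0
  m$n_mapped_reads[is.na(m$n_mapped_reads)] <- 0L
  m$mean_depth <- m$bases / as.numeric(contig_lengths[m$contig_id])
  m <- m[order(m$contig_id, m$sample), c("contig_id", "sample", "mean_depth",
                                         "n_mapped_reads")]
  rownames(m) <- NULL
  m
}

#' Partition contigs into depth phylotypes
#'
#' Bin boundaries are geometric (log-uniform) between the smallest and
#' largest positive combined-sample mean depth; every contig with positive
#' combined depth falls in exactly one of `n_bins` intervals
#' `[low, high)` (the last interval is closed above). Bins may be empty.
#'
#' @param depths output of [compute_depths()] (any number of samples; depths
#'   are summed across samples per contig).
#' @param n_bins number of depth strata.
#' @param scheme boundary placement: `"geometric"` (log-uniform spacing,
#'   the default) or `"gap"` (natural breaks: boundaries at the largest
#'   log-depth gaps of at least `min_gap` decades, so that a tight depth
#'   cluster is never split by an arbitrary boundary).
#' @param min_gap minimum log10-depth gap (decades) for a `"gap"` boundary.
#' @return list with `contigs` (data.frame `contig_id`, `depth`, `bin`) and
#'   `boundaries` (length `n_bins + 1` for `"geometric"`; possibly fewer
#'   for `"gap"`). Zero-depth contigs are excluded; all-zero input is an
#'   error.
#' @export
partition_by_depth <- function(depths, n_bins = 11L,
                               scheme = c("geometric", "gap"),
                               min_gap = 0.1) {
  scheme <- match.arg(scheme)
  .dm_assert(n_bins >= 1L, "n_bins must be >= 1")
  agg <- tapply(depths$mean_depth, depths$contig_id, sum)
  combined <- data.frame(contig_id = names(agg), depth = as.numeric(agg),
                         stringsAsFactors = FALSE)
  combined <- combined[combined$depth > 0, , drop = FALSE]
  .dm_assert(nrow(combined) > 0L, "nothing mapped: all contig depths are zero")
  dmin <- min(combined$depth); dmax <- max(combined$depth)
  if (dmin == dmax) {
    boundaries <- c(dmin * (1 - 1e-9), rep(dmax * (1 + 1e-9), n_bins))
    combined$bin <- 1L
  } else if (scheme == "geometric") {
    boundaries <- exp(seq(log(dmin), log(dmax), length.out = n_bins + 1L))
    bin <- findInterval(combined$depth, boundaries,
                        rightmost.closed = TRUE, all.inside = TRUE)
    combined$bin <- as.integer(bin)
  } else {
    lx <- sort(unique(log10(combined$depth)))
    gaps <- diff(lx)
    cand <- which(gaps >= min_gap)
    cand <- cand[order(-gaps[cand], cand)]
    cuts <- sort(lx[head(cand, n_bins - 1L)] + gaps[head(cand, n_bins - 1L)] / 2)
    boundaries <- c(dmin * (1 - 1e-9), 10^cuts, dmax * (1 + 1e-9))
    combined$bin <- findInterval(log10(combined$depth), c(-Inf, cuts)) |>
      as.integer()
  }
  combined <- combined[order(combined$contig_id), , drop = FALSE]
  rownames(combined) <- NULL
  list(contigs = combined, boundaries = boundaries, n_bins = as.integer(n_bins))
}

#' Partition contigs by the per-sample depth vector (differential coverage)
#'
#' Runs the geometric depth binning of [partition_by_depth()] independently
#' per sample and crosses the per-sample strata: two contigs share a
#' phylotype iff they fall in the same depth interval in every sample
#' (contigs unmapped in a sample form their own "zero" level there).
#' With a single sample this reduces to [partition_by_depth()]. This is the
#' differential-coverage variant of depth stratification: organisms whose
#' summed depths collide are still separated whenever their per-sample
#' profiles differ.
#'
#' @param depths output of [compute_depths()] over one or more samples.
#' @param n_bins depth strata per sample.
#' @param scheme,min_gap boundary scheme, see [partition_by_depth()].
#' @return list with `contigs` (data.frame `contig_id`, `depth` (combined),
#'   `bin` (1..K relabeled joint stratum)), `boundaries` (per-sample list)
#'   and `n_bins` (K, number of occupied joint strata).
#' @export
partition_by_depth_joint <- function(depths, n_bins = 11L,
                                     scheme = c("geometric", "gap"),
                                     min_gap = 0.1) {
  scheme <- match.arg(scheme)
  samples <- sort(unique(depths$sample))
  if (length(samples) <= 1L)
    return(partition_by_depth(depths, n_bins, scheme, min_gap))
  per <- lapply(samples, function(s)
    partition_by_depth(depths[depths$sample == s, , drop = FALSE], n_bins,
                       scheme, min_gap))
  names(per) <- samples
  agg <- tapply(depths$mean_depth, depths$contig_id, sum)
  combined <- data.frame(contig_id = names(agg), depth = as.numeric(agg),
                         stringsAsFactors = FALSE)
  combined <- combined[combined$depth > 0, , drop = FALSE]
  codes <- vapply(samples, function(s) {
    b <- per[[s]]$contigs
    code <- b$bin[match(combined$contig_id, b$contig_id)]
    code[is.na(code)] <- 0L
    code
  }, integer(nrow(combined)))
  codes <- matrix(codes, nrow = nrow(combined))
  key <- apply(codes, 1, paste, collapse = "|")
  lev <- sort(unique(key))
  combined$bin <- match(key, lev)
  combined <- combined[order(combined$contig_id), , drop = FALSE]
  rownames(combined) <- NULL
  list(contigs = combined,
       boundaries = lapply(per, `[[`, "boundaries"),
       n_bins = length(lev))
}

#' Assign reads (and read pairs) to depth phylotypes
#'
#' Each mapped read inherits the phylotype of its primary alignment's contig.
#' For pairs, both mates follow mate 1's alignment; when mate 1 is unmapped
#' the pair follows mate 2 (documented fallback), and pairs with neither mate
#' mapped go to the `UNMAPPED` pool. Conservation is exact:
#' every id appears exactly once in the output.
#'
#' @param read_ids character vector of read (or pair) ids.
#' @param partition output of [partition_by_depth()].
#' @param aln1 primary alignments of the reads (mate 1 for pairs).
#' @param aln2 optional mate-2 alignments.
#' @return data.frame (`read_id`, `bin`) where `bin` is an integer stratum or
#'   `NA` for the UNMAPPED pool, plus attribute `n_unmapped`.
#' @export
assign_reads <- function(read_ids, partition, aln1, aln2 = NULL) {
  contig_bin <- setNames(partition$contigs$bin, partition$contigs$contig_id)
  bin1 <- contig_bin[aln1$contig_id[match(read_ids, aln1$read_id)]]
  bin <- as.integer(bin1)
  if (!is.null(aln2)) {
    bin2 <- as.integer(contig_bin[aln2$contig_id[match(read_ids, aln2$read_id)]])
    take2 <- is.na(bin) & !is.na(bin2)
    bin[take2] <- bin2[take2]
  }
  out <- data.frame(read_id = read_ids, bin = bin, stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(is.na(bin))
  out
}
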