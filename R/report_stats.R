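# Assembly contiguity statistics and run comparisons.

#' N50 of a length multiset
#'
#' Smallest length L such that the summed lengths of all members >= L is at
#' least half the total (the qualifying member's own length is reported).
#'
#' @param lengths positive numeric vector.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) nx(lengths, 50)

#' Nx statistic
#'
#' @param lengths positive numeric vector.
#' @param x percentage in (0, 100\].
#' @return smallest length L with `sum(lengths >= ...)` covering x% of the
#'   total, by descending sort and cumulative sum.
#' @export
nx <- function(lengths, x) {
  .dm_assert(length(lengths) >= 1L && all(lengths > 0),
             "need at least one positive length")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= sum(as.numeric(s)) * x / 100)[1]]
}

#' Cumulative assembled bases above length thresholds
#'
#' @param lengths contig lengths.
#' @param thresholds ascending thresholds in bp (0 gives the total).
#' @return data.frame (`threshold`, `n_contigs`, `cumulative_bp`); values are
#'   monotone non-increasing in the threshold.
#' @export
cumulative_curve <- function(lengths, thresholds) {
  .dm_assert(!is.unsorted(thresholds), "thresholds must be ascending")
  data.frame(
    threshold = thresholds,
    n_contigs = vapply(thresholds, function(t) sum(lengths >= t), 0L),
    cumulative_bp = vapply(thresholds, function(t)
      sum(as.numeric(lengths[lengths >= t])), numeric(1)))
}

#' Fraction of reads mapping to contigs
#'
#' @param reads `dm_seqs`.
#' @param contigs `dm_seqs`.
#' @param k,max_mismatch_frac mapper settings.
#' @return mapped primary alignments / total reads, in \[0, 1\].
#' @export
mapping_ratio <- function(reads, contigs, k = 21L, max_mismatch_frac = 0.05) {
  if (nrow(reads) == 0L || nrow(contigs) == 0L) return(0)
  idx <- build_kmer_index(contigs, k = k)
  aln <- map_short_reads(reads, idx, max_mismatch_frac = max_mismatch_frac)
  nrow(aln) / nrow(reads)
}

#' Assembly statistics record
#'
#' @param contigs `dm_seqs`.
#' @param thresholds length thresholds for the cumulative curve.
#' @param reads optional `dm_seqs`; adds the short-read mapping ratio.
#' @param nx_grid Nx percentages (default 10..90).
#' @return list of class `dm_assembly_stats`.
#' @export
assembly_stats <- function(contigs, thresholds = c(1e3, 1e4, 1e5, 1e6),
                           reads = NULL, nx_grid = seq(10, 90, by = 10)) {
  .dm_assert(nrow(contigs) >= 1L, "no contigs")
  len <- nchar(contigs$seq)
  out <- list(
    n_contigs = length(len),
    total_bp = sum(as.numeric(len)),
    max_contig = max(len),
    n50 = n50(len),
    nx = setNames(vapply(nx_grid, function(x) nx(len, x), numeric(1)),
                  paste0("N", nx_grid)),
    curve = cumulative_curve(len, thresholds),
    mapping_ratio = if (!is.null(reads)) mapping_ratio(reads, contigs)
    else NA_real_)
  class(out) <- "dm_assembly_stats"
  out
}

#' @export
print.dm_assembly_stats <- function(x, ...) {
  cat(sprintf("contigs: %d  total: %.0f bp  max: %d  N50: %d\n",
              x$n_contigs, x$total_bp, x$max_contig, x$n50))
  if (!is.na(x$mapping_ratio))
    cat(sprintf("short-read mapping ratio: %.2f%%\n", 100 * x$mapping_ratio))
  invisible(x)
}

.stats_as_vector <- function(s) {
  c(n_contigs = s$n_contigs, total_bp = s$total_bp, max_contig = s$max_contig,
    n50 = s$n50, s$nx,
    setNames(s$curve$cumulative_bp, paste0("bp_ge_", s$curve$threshold)),
    mapping_ratio = s$mapping_ratio)
}

#' Compare assembly runs against a baseline
#'
#' @param stats_list list of >= 2 [assembly_stats()] records.
#' @param labels run labels; the first is the baseline.
#' @return data.frame with one row per metric: per-run values, difference and
#'   ratio vs the baseline.
#' @export
compare_runs <- function(stats_list, labels) {
  .dm_assert(length(stats_list) >= 2L, "need at least two runs")
  .dm_assert(length(labels) == length(stats_list), "one label per run")
  vecs <- lapply(stats_list, .stats_as_vector)
  metr <- names(vecs[[1]])
  for (v in vecs[-1])
    .dm_assert(identical(names(v), metr), "runs report different metric sets")
  m <- do.call(cbind, vecs)
  colnames(m) <- labels
  out <- data.frame(metric = metr, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (lab in labels[-1]) {
    out[[paste0("diff_", lab)]] <- out[[lab]] - out[[labels[1]]]
    out[[paste0("ratio_", lab)]] <- out[[lab]] / out[[labels[1]]]
  }
  rownames(out) <- NULL
  out
}

#' Rand index between two labelings
#'
#' Agreement of co-membership over all element pairs, computed from the
#' contingency table.
#'
#' @param a,b equal-length label vectors.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  .dm_assert(length(a) == length(b), "label vectors differ in length")
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  total <- n * (n - 1) / 2
  (total + 2 * ch2(tab) - ch2(rowSums(tab)) - ch2(colSums(tab))) / total
}
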