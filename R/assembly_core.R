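# Desk-scale assembly machinery: de Bruijn unitig assembly of short reads,
# long-read contig anchoring and hybrid merging, containment-based redundancy
# removal, and short-read pileup polishing.

.contig_set <- function(seqs, prefix, provenance, phylotype = NA_integer_) {
  if (length(seqs) == 0L) {
    out <- data.frame(id = character(0), seq = character(0),
                      provenance = character(0), phylotype = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("dm_seqs", "data.frame")
    return(out)
  }
  out <- seq_set(sprintf("%s%05d", prefix, seq_along(seqs)), seqs)
  out$provenance <- provenance
  out$phylotype <- phylotype
  out
}

#' Assemble short reads into unitigs
#'
#' Builds a de Bruijn graph on canonical k-mers with count >=
#' `min_kmer_count` and emits maximal non-branching paths (unitigs), each in
#' its lexicographically smaller orientation, ordered by (length descending,
#' sequence ascending).
#'
#' @param reads `dm_seqs` (or character vector of sequences).
#' @param k odd k-mer size.
#' @param min_kmer_count abundance floor; k-mers seen fewer times are dropped.
#' @param id_prefix prefix for contig ids.
#' @param phylotype optional stratum label recorded on the contigs.
#' @return `dm_seqs` contig data.frame with `provenance = "short-only"`;
#'   empty (with a warning) when no k-mer survives the floor.
#' @export
assemble_short_reads <- function(reads, k = 31L, min_kmer_count = 2L,
                                 id_prefix = "ctg", phylotype = NA_integer_) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  unitigs <- dm_assemble(seqs, as.integer(k), as.integer(min_kmer_count))
  if (length(unitigs) == 0L) {
    warning("no k-mer survived the count filter; empty assembly")
  }
  .contig_set(unitigs, id_prefix, "short-only", phylotype)
}

#' Median multiplicity of retained k-mers
#'
#' Support for choosing an abundance floor adaptively: the median count of
#' canonical k-mers seen at least twice approximates the k-mer coverage of
#' the dominant organisms in the read set.
#'
#' @param reads `dm_seqs` or character vector.
#' @param k k-mer size.
#' @return median count (0 when nothing is seen twice).
#' @export
kmer_median_count <- function(reads, k = 31L) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  cnt <- dm_kmer_counts(seqs, as.integer(k), 2L)
  if (length(cnt) == 0L) return(0)
  stats::median(cnt)
}

#' Anchor contigs on long reads
#'
#' k-mers unique within the contig set locate contigs on each long read;
#' per (read, contig, orientation) diagonal band, clusters with at least
#' `min_anchor_kmers` hits become anchor intervals, which are chained left to
#' right per read (overlapping anchors discarded, keeping the higher k-mer
#' count).
#'
#' @param contigs `dm_seqs`.
#' @param long_reads `dm_seqs`.
#' @param k_anchor anchor k-mer size.
#' @param min_anchor_kmers minimum consistent-diagonal hits per anchor.
#' @param band_frac diagonal band width as fraction of read length.
#' @return anchor data.frame (`read_id`, `contig_id`, `orient`, `read_start`,
#'   `read_end`, `contig_start`, `contig_end`, `n_kmers`), chained per read.
#' @export
anchor_contigs <- function(contigs, long_reads, k_anchor = 17L,
                           min_anchor_kmers = 10L, band_frac = 0.2) {
  .dm_assert(nrow(contigs) > 0L && nrow(long_reads) > 0L,
             "contigs and long reads must be non-empty")
  a <- dm_anchor(contigs$seq, long_reads$seq, as.integer(k_anchor),
                 as.integer(min_anchor_kmers), band_frac)
  data.frame(read_id = long_reads$id[a$read],
             contig_id = contigs$id[a$contig],
             orient = a$orient,
             read_start = a$read_start, read_end = a$read_end,
             contig_start = a$contig_start, contig_end = a$contig_end,
             n_kmers = a$n_kmers, stringsAsFactors = FALSE)
}

# anchor end in oriented-contig coordinates
.cut_left <- function(len, cs, ce, o) if (o == 1L) ce else len - cs
.start_right <- function(len, cs, ce, o) if (o == 1L) cs else len - ce

.oriented <- function(seq, o) if (o == 1L) seq else dm_revcomp(seq)

#' Merge contigs into super-contigs using long-read chains
#'
#' Consecutive anchor pairs on each long read define edges of a
#' contig-adjacency multigraph. Edges supported by at least `min_support`
#' distinct reads are accepted (contradictory orientations with equal
#' support: neither accepted); each contig end joins at most one accepted
#' edge and cycles are refused, so accepted edges form simple paths, which
#' are merged into super-contigs. Junction gaps are filled with the long-read
#' subsequence between the anchor intervals, taken from the supporting read
#' with the highest anchor k-mer count; overlapping anchors trim the
#' downstream contig instead. Unmerged contigs pass through.
#'
#' @param contigs `dm_seqs`.
#' @param chains anchor data.frame from [anchor_contigs()].
#' @param long_reads `dm_seqs` (gap-fill source).
#' @param min_support minimum distinct supporting reads per junction.
#' @param depth_profiles optional per-sample depth table (as returned by
#'   [compute_depths()]) over the input contigs; when given, junctions whose
#'   endpoint contigs differ by more than `max_depth_ratio` in any sample's
#'   depth (with +1 pseudo-count) are refused. This differential-coverage
#'   gate keeps shared elements (repeats, marker stubs), whose apparent
#'   depth is a sum over organisms, from gluing unrelated contigs together.
#' @param max_depth_ratio maximum per-sample depth ratio across a junction.
#' @return `dm_seqs` with `provenance` `"merged"` (new super-contigs) or
#'   `"hybrid"` (pass-through); attribute `n_junctions` counts merges and
#'   `conflicts` the contig pairs dropped for contradictory orientation.
#' @export
hybrid_merge <- function(contigs, chains, long_reads, min_support = 2L,
                         depth_profiles = NULL, max_depth_ratio = 3) {
  if (is.null(chains) || nrow(chains) == 0L) {
    out <- contigs
    out$provenance <- "hybrid"
    attr(out, "n_junctions") <- 0L
    return(out)
  }
  .dm_assert(all(chains$contig_id %in% contigs$id),
             "chain references unknown contig")
  .dm_assert(all(chains$read_id %in% long_reads$id),
             "chain references unknown read")
  clen <- setNames(nchar(contigs$seq), contigs$id)
  cseq <- setNames(contigs$seq, contigs$id)
  rseq <- setNames(long_reads$seq, long_reads$id)

  ch <- chains[order(chains$read_id, chains$read_start), , drop = FALSE]
  occ <- list()
  for (rid in unique(ch$read_id)) {
    rows <- ch[ch$read_id == rid, , drop = FALSE]
    if (nrow(rows) < 2L) next
    for (j in seq_len(nrow(rows) - 1L)) {
      a <- rows[j, ]; b <- rows[j + 1L, ]
      if (a$contig_id == b$contig_id) next
      fwd <- paste(a$contig_id, a$orient, b$contig_id, b$orient, sep = "|")
      rev <- paste(b$contig_id, -b$orient, a$contig_id, -a$orient, sep = "|")
      key <- min(fwd, rev)
      occ[[length(occ) + 1L]] <- list(
        key = key, flip = !identical(key, fwd), read_id = rid,
        A = a$contig_id, oa = a$orient, B = b$contig_id, ob = b$orient,
        ra_end = a$read_end, rb_start = b$read_start,
        ca_s = a$contig_start, ca_e = a$contig_end,
        cb_s = b$contig_start, cb_e = b$contig_end,
        strength = min(a$n_kmers, b$n_kmers))
    }
  }
  if (length(occ) == 0L) {
    out <- contigs
    out$provenance <- "hybrid"
    attr(out, "n_junctions") <- 0L
    return(out)
  }
  keys <- vapply(occ, `[[`, "", "key")
  reads_of <- split(vapply(occ, `[[`, "", "read_id"), keys)
  support <- vapply(reads_of, function(x) length(unique(x)), 0L)
  # orientation conflicts: same unordered contig pair, different key
  pair_of <- vapply(strsplit(names(support), "|", fixed = TRUE), function(p)
    paste(sort(c(p[1], p[3])), collapse = "|"), "")
  conflicts <- character(0)
  keep_key <- rep(TRUE, length(support))
  for (pr in unique(pair_of[duplicated(pair_of)])) {
    idx <- which(pair_of == pr)
    s <- support[idx]
    if (sum(s == max(s)) > 1L) {
      keep_key[idx] <- FALSE
      conflicts <- c(conflicts, pr)
    } else {
      keep_key[idx] <- s == max(s)
    }
  }
  if (!is.null(depth_profiles)) {
    dmat <- tapply(depth_profiles$mean_depth,
                   list(depth_profiles$contig_id, depth_profiles$sample),
                   sum)
    compatible <- vapply(strsplit(names(support), "|", fixed = TRUE),
                         function(p) {
                           if (!(p[1] %in% rownames(dmat)) ||
                               !(p[3] %in% rownames(dmat))) return(TRUE)
                           r <- (dmat[p[1], ] + 1) / (dmat[p[3], ] + 1)
                           all(r < max_depth_ratio & r > 1 / max_depth_ratio)
                         }, TRUE)
    keep_key <- keep_key & compatible
  }
  accepted <- names(support)[keep_key & support >= min_support]
  if (length(accepted) == 0L) {
    out <- contigs
    out$provenance <- "hybrid"
    attr(out, "n_junctions") <- 0L
    attr(out, "conflicts") <- conflicts
    return(out)
  }
  # greedy end-matching with cycle refusal
  parent <- setNames(contigs$id, contigs$id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  port_used <- character(0)
  adj <- list()  # port -> list(other_port, key)
  ord <- accepted[order(-support[accepted], accepted)]
  edges_used <- character(0)
  for (key in ord) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    A <- p[1]; oa <- as.integer(p[2]); B <- p[3]; ob <- as.integer(p[4])
    portA <- paste0(A, ifelse(oa == 1L, ":t", ":h"))
    portB <- paste0(B, ifelse(ob == 1L, ":h", ":t"))
    if (portA %in% port_used || portB %in% port_used) next
    if (find(A) == find(B)) next
    parent[find(A)] <- find(B)
    port_used <- c(port_used, portA, portB)
    adj[[portA]] <- list(other_port = portB, key = key)
    adj[[portB]] <- list(other_port = portA, key = key)
    edges_used <- c(edges_used, key)
  }
  # best representative occurrence per accepted key
  best_occ <- list()
  for (key in edges_used) {
    cand <- occ[keys == key]
    st <- vapply(cand, `[[`, 0L, "strength")
    rid <- vapply(cand, `[[`, "", "read_id")
    best_occ[[key]] <- cand[[order(-st, rid)[1]]]
  }
  junction <- function(key, left_id) {
    # view of the junction walking out of `left_id`. Contig tails beyond the
    # anchored interval are kept in full (anchors stop early wherever k-mers
    # are shared between contigs, and contig sequence is far more accurate
    # than the read); the junction gap is the read segment between the
    # *projected* contig ends, a negative gap trimming the downstream contig.
    o <- best_occ[[key]]
    aend <- .cut_left(clen[[o$A]], o$ca_s, o$ca_e, o$oa)
    bstart <- .start_right(clen[[o$B]], o$cb_s, o$cb_e, o$ob)
    fs <- o$ra_end + (clen[[o$A]] - aend)   # projected end of A on the read
    fe <- o$rb_start - bstart               # projected start of B
    gap_fwd <- if (fe > fs) substr(rseq[[o$read_id]], fs + 1L, fe) else ""
    trim <- max(0L, fs - fe)
    if (o$A == left_id) {       # canonical/observed direction
      list(cut_left = clen[[o$A]], start_right = trim, gap = gap_fwd)
    } else {                    # reversed traversal
      list(cut_left = clen[[o$B]], start_right = trim,
           gap = if (nzchar(gap_fwd)) dm_revcomp(gap_fwd) else "")
    }
  }
  # traverse simple paths
  in_path <- unique(unlist(lapply(strsplit(edges_used, "|", fixed = TRUE),
                                  function(p) c(p[1], p[3]))))
  used_ports_of <- function(cid)
    intersect(paste0(cid, c(":h", ":t")), names(adj))
  endpoints <- sort(in_path[vapply(in_path, function(cid)
    length(used_ports_of(cid)) == 1L, TRUE)])
  visited <- character(0)
  merged_seqs <- character(0)
  n_junctions <- 0L
  for (ep in endpoints) {
    if (ep %in% visited) next
    # leave ep via its single used port
    leave <- used_ports_of(ep)[1]
    cur <- ep
    o_cur <- if (endsWith(leave, ":t")) 1L else -1L
    pieces <- character(0)
    pos0 <- 1L  # 1-based start within current oriented contig
    repeat {
      visited <- c(visited, cur)
      e <- adj[[leave]]
      if (is.null(e)) { # path end: emit remainder of current contig
        pieces <- c(pieces, substr(.oriented(cseq[[cur]], o_cur), pos0,
                                   clen[[cur]]))
        break
      }
      j <- junction(e$key, cur)
      n_junctions <- n_junctions + 1L
      cut <- max(pos0 - 1L, min(j$cut_left, clen[[cur]]))
      pieces <- c(pieces, substr(.oriented(cseq[[cur]], o_cur), pos0, cut),
                  j$gap)
      nxt_port <- e$other_port
      cur <- sub(":[ht]$", "", nxt_port)
      o_cur <- if (endsWith(nxt_port, ":h")) 1L else -1L
      pos0 <- min(j$start_right + 1L, clen[[cur]])
      other <- paste0(cur, if (endsWith(nxt_port, ":h")) ":t" else ":h")
      if (is.null(adj[[other]])) {
        visited <- c(visited, cur)
        pieces <- c(pieces, substr(.oriented(cseq[[cur]], o_cur), pos0,
                                   clen[[cur]]))
        break
      }
      leave <- other
    }
    merged_seqs <- c(merged_seqs, paste(pieces, collapse = ""))
  }
  passthrough <- contigs[!(contigs$id %in% visited), , drop = FALSE]
  merged <- .contig_set(merged_seqs, "merged", "merged")
  out <- passthrough
  out$provenance <- rep("hybrid", nrow(out))
  if (is.null(out$phylotype)) out$phylotype <- rep(NA_integer_, nrow(out))
  out <- rbind(out[, c("id", "seq", "provenance", "phylotype")],
               merged[, c("id", "seq", "provenance", "phylotype")])
  class(out) <- c("dm_seqs", "data.frame")
  attr(out, "n_junctions") <- n_junctions
  attr(out, "conflicts") <- conflicts
  out
}

#' Remove contained redundant contigs
#'
#' Contigs are processed longest-first; a contig contained in an earlier
#' (longer) survivor at >= `min_identity` over >= `min_containment` of its
#' own length (ungapped, best seed-voted offset, better strand) is removed.
#' Idempotent and deterministic.
#'
#' @param contigs `dm_seqs`.
#' @param min_identity minimum identity over the aligned overlap.
#' @param min_containment minimum fraction of the shorter contig covered.
#' @param k seed k-mer size.
#' @return `dm_seqs` of surviving contigs (input order of survivors is by
#'   decreasing length), with attribute `n_removed`.
#' @export
remove_redundancy <- function(contigs, min_identity = 0.95,
                              min_containment = 0.95, k = 15L) {
  if (nrow(contigs) <= 1L) {
    attr(contigs, "n_removed") <- 0L
    return(contigs)
  }
  ord <- order(-nchar(contigs$seq), contigs$seq)
  sorted <- contigs[ord, , drop = FALSE]
  cl <- dm_greedy_cluster(sorted$seq, as.integer(k), min_identity,
                          min_containment)
  keep <- cl$rep == seq_len(nrow(sorted))
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dm_seqs", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Polish contigs with short-read pileups
#'
#' Reads are mapped with the built-in short-read mapper; positions with
#' pileup depth >= `min_depth` whose majority base reaches `min_frac` are
#' substituted (substitution-only; no indel correction).
#'
#' @param contigs `dm_seqs`.
#' @param reads `dm_seqs` of short reads.
#' @param rounds mapping/correction rounds.
#' @param min_depth minimum pileup depth to call a correction.
#' @param min_frac minimum majority fraction.
#' @param k mapper seed size.
#' @param max_mismatch_frac mapper mismatch tolerance.
#' @return polished `dm_seqs` with attribute `n_corrections` (per round sum,
#'   named per contig for the final round).
#' @export
polish <- function(contigs, reads, rounds = 1L, min_depth = 3L,
                   min_frac = 0.6, k = 21L, max_mismatch_frac = 0.05) {
  if (nrow(contigs) == 0L || nrow(reads) == 0L) {
    attr(contigs, "n_corrections") <- setNames(integer(nrow(contigs)),
                                               contigs$id)
    return(contigs)
  }
  total <- setNames(integer(nrow(contigs)), contigs$id)
  for (r in seq_len(rounds)) {
    idx <- build_kmer_index(contigs, k = k)
    aln <- map_short_reads(reads, idx, max_mismatch_frac = max_mismatch_frac)
    if (nrow(aln) == 0L) break
    res <- dm_polish(contigs$seq,
                     match(aln$contig_id, contigs$id),
                     aln$offset, aln$strand,
                     setNames(reads$seq, reads$id)[aln$read_id],
                     as.integer(min_depth), min_frac)
    contigs$seq <- as.character(res$seq)
    total <- total + setNames(res$n_corrections, contigs$id)
  }
  attr(contigs, "n_corrections") <- total
  contigs
}
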