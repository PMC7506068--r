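# Readers/writers for FASTA, FASTQ (Phred+33) and a SAM subset, plus the
# long-read QC filter. Sequence collections are plain data.frames:
#   reads/contigs: id, seq [, qual (Phred string), read_quality (numeric)]
#   alignments:    read_id, contig_id, start, end, strand, score, is_primary
# Internal coordinates are 0-based half-open; SAM I/O converts at the border.

#' Construct a sequence collection
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of nucleotide sequences over A,C,G,T,N.
#' @param qual optional per-base Phred strings (same lengths as `seq`).
#' @param read_quality optional numeric read-level quality in \[0, 100\]
#'   (long-read convention).
#' @return data.frame with class `dm_seqs`.
#' @export
seq_set <- function(id, seq, qual = NULL, read_quality = NULL) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  .dm_assert(length(id) == length(seq), "id and seq lengths differ")
  .dm_assert(!anyDuplicated(id), "duplicate sequence ids")
  .dm_assert(all(nzchar(id)), "empty sequence id")
  .dm_assert(all(nchar(seq) >= 1L), "zero-length sequence")
  out <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    .dm_assert(all(nchar(qual) == nchar(seq)),
               "quality string length does not match sequence length")
    out$qual <- as.character(qual)
  }
  if (!is.null(read_quality)) out$read_quality <- as.numeric(read_quality)
  class(out) <- c("dm_seqs", "data.frame")
  out
}

#' Read a FASTA file
#'
#' Sequences are uppercased and record order is preserved. A malformed header
#' or an empty sequence raises an error naming the offending line.
#'
#' @param path file path.
#' @return `dm_seqs` data.frame (`id`, `seq`); empty file gives 0 rows.
#' @export
read_fasta <- function(path) {
  .dm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(seq_set(character(0), character(0))[0, , drop = FALSE])
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop(sprintf("FASTA format error at line 1: expected '>' header, got %s",
                 substr(lines[1], 1, 20)), call. = FALSE)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  bad <- which(is_hdr & !nzchar(sub("^>\\s*", "", lines)))
  if (length(bad))
    stop(sprintf("FASTA format error at line %d: empty header", bad[1]),
         call. = FALSE)
  grp <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste0, "",
                 collapse = "")
  full <- character(sum(is_hdr))
  names(full) <- as.character(seq_along(full))
  full[names(seqs)] <- seqs
  empty <- which(!nzchar(full))
  if (length(empty)) {
    ln <- which(is_hdr)[empty[1]]
    stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                 ln, ids[empty[1]]), call. = FALSE)
  }
  seq_set(ids, toupper(full))
}

#' Write a FASTA file (wrapped at 80 columns)
#'
#' @param x `dm_seqs`-style data.frame with `id` and `seq`.
#' @param path output path.
#' @param width wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    s <- x$seq[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(c(paste0(">", x$id[i]),
                 substring(s, starts, pmin(starts + width - 1L, n))), con)
  }
  invisible(path)
}

.PHRED_OFFSET <- 33L

#' Decode a Phred+33 quality string to integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - .PHRED_OFFSET)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' Long-read headers may carry a `rq:<value>` tag holding the read-level
#' quality score; when present it is returned in a `read_quality` column.
#'
#' @param path file path.
#' @return `dm_seqs` data.frame (`id`, `seq`, `qual` \[, `read_quality`\]).
#' @export
read_fastq <- function(path) {
  .dm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    out <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
    class(out) <- c("dm_seqs", "data.frame")
    return(out)
  }
  if (length(lines) %% 4L != 0L)
    stop(sprintf(
      "FASTQ format error: %d lines is not a multiple of 4 (truncated record near line %d)",
      length(lines), length(lines)), call. = FALSE)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("FASTQ format error at line %d: header must start with '@'",
                 (bad[1] - 1L) * 4L + 1L), call. = FALSE)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("FASTQ format error at line %d: expected '+' separator",
                 (bad[1] - 1L) * 4L + 3L), call. = FALSE)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf(
      "FASTQ format error at line %d: sequence/quality length mismatch (%d vs %d)",
      (bad[1] - 1L) * 4L + 2L, nchar(seqs[bad[1]]), nchar(qual[bad[1]])),
      call. = FALSE)
  hdr <- sub("^@", "", hdr)
  rq <- rep(NA_real_, length(hdr))
  has_rq <- grepl("\\brq:[0-9.]+", hdr)
  rq[has_rq] <- as.numeric(sub(".*\\brq:([0-9.]+).*", "\\1", hdr[has_rq]))
  ids <- sub("\\s.*$", "", hdr)
  out <- data.frame(id = ids, seq = seqs, qual = qual,
                    stringsAsFactors = FALSE)
  if (any(has_rq)) out$read_quality <- rq
  class(out) <- c("dm_seqs", "data.frame")
  out
}

#' Write a FASTQ file (Phred+33)
#'
#' A `read_quality` column, when present, is emitted as a `rq:` header tag so
#' that round-trips preserve the read-level score.
#'
#' @param x data.frame with `id`, `seq` and `qual` (and optionally
#'   `read_quality`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  .dm_assert(all(nchar(x$seq) == nchar(x$qual)),
             "sequence/quality length mismatch")
  hdr <- paste0("@", x$id)
  if (!is.null(x$read_quality)) {
    tag <- ifelse(is.na(x$read_quality), "",
                  sprintf(" rq:%.2f", x$read_quality))
    hdr <- paste0(hdr, tag)
  }
  out <- character(4L * nrow(x))
  out[seq(1L, length(out), by = 4L)] <- hdr
  out[seq(2L, length(out), by = 4L)] <- x$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- x$qual
  writeLines(out, path)
  invisible(path)
}

#' Reference span of a CIGAR string (M/I/D/S alphabet)
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of reference bases consumed (M + D).
#' @export
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stop(sprintf("malformed CIGAR: %s", cg), call. = FALSE)
    lens <- as.integer(sub("[A-Z=]$", "", ops))
    chars <- sub("^[0-9]+", "", ops)
    bad <- setdiff(chars, c("M", "I", "D", "S"))
    if (length(bad))
      stop(sprintf("unsupported CIGAR operator '%s' in %s", bad[1], cg),
           call. = FALSE)
    sum(lens[chars %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a SAM-subset alignment file
#'
#' Header lines (`@...`) are skipped; columns QNAME, FLAG, RNAME, POS (1-based),
#' MAPQ, CIGAR and SEQ are used. FLAG bit 0x10 sets strand `-`; bit 0x4 marks
#' the record unmapped - such records are excluded from the returned collection
#' but counted in the `n_unmapped` attribute. POS is converted to the internal
#' 0-based convention and `end = start + reference span(CIGAR)`.
#'
#' @param path file path.
#' @return alignment data.frame (`read_id`, `contig_id`, `start`, `end`,
#'   `strand`, `score`, `is_primary`) with attribute `n_unmapped`.
#' @export
read_alignments <- function(path) {
  .dm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    out <- .empty_alignments()
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6L))
    stop(sprintf("SAM format error at record %d: fewer than 6 fields",
                 which(nf < 6L)[1]), call. = FALSE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  cigar <- vapply(f, `[[`, "", 6L)
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_unmapped <- sum(unmapped)
  keep <- !unmapped
  span <- cigar_ref_span(cigar[keep])
  out <- data.frame(
    read_id = qname[keep],
    contig_id = rname[keep],
    start = pos[keep] - 1L,
    end = pos[keep] - 1L + span,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
    score = mapq[keep],
    is_primary = bitwAnd(flag[keep], 256L) == 0L,
    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

.empty_alignments <- function() {
  data.frame(read_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             score = integer(0), is_primary = logical(0),
             stringsAsFactors = FALSE)
}

#' Write alignments as a SAM subset
#'
#' Ungapped records: CIGAR is `<n>M` with n = end - start. Coordinates are
#' converted back to 1-based POS.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param path output path.
#' @param contig_lengths optional named integer vector for `@SQ` headers.
#' @param read_seqs optional named character vector (read id to sequence) for
#'   the SEQ column; `*` otherwise.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, contig_lengths = NULL,
                             read_seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(aln$is_primary, 0L, 256L)
    seqcol <- if (is.null(read_seqs)) "*" else
      unname(read_seqs[aln$read_id])
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       aln$read_id, flag, aln$contig_id, aln$start + 1L,
                       as.integer(aln$score), aln$end - aln$start, seqcol),
               con)
  }
  invisible(path)
}

#' Long-read QC filter
#'
#' Reads with length < `min_length` or read-level quality < `min_quality` are
#' excluded; both thresholds are strict exclusions, so boundary values are
#' kept. Counts are conserved: `nrow(kept) + n_removed = nrow(reads)`.
#'
#' @param reads `dm_seqs` data.frame with a `read_quality` column (unless
#'   `quality_filter = FALSE`).
#' @param min_length minimum length in bp.
#' @param min_quality minimum read-level quality score in \[0, 100\].
#' @param quality_filter set `FALSE` to filter on length only (reads without
#'   quality scores pass through).
#' @return list with `reads` (kept rows) and `n_removed`.
#' @export
qc_filter_long_reads <- function(reads, min_length = 50L, min_quality = 75,
                                 quality_filter = TRUE) {
  if (nrow(reads) == 0L) return(list(reads = reads, n_removed = 0L))
  keep_len <- nchar(reads$seq) >= min_length
  if (quality_filter) {
    .dm_assert(!is.null(reads$read_quality) && !anyNA(reads$read_quality),
               "reads lack a read-level quality score; set quality_filter = FALSE to skip")
    keep <- keep_len & reads$read_quality >= min_quality
  } else {
    keep <- keep_len
  }
  list(reads = reads[keep, , drop = FALSE], n_removed = sum(!keep))
}
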