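# Ground-truthed mock metagenomes: random genomes with planted single-copy
# markers, shared repeats and a small taxonomy; two samples sharing the genome
# panel under independently permuted abundances; HiSeq-like 150-bp pairs and
# error-prone PacBio-like long reads with recorded origins. Everything is
# driven by a single seed and is bit-reproducible.

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Build a small reference taxonomy for a genome panel
#'
#' One species per genome plus decoy sibling species (same genus) and cousin
#' species (same family) so that hit tables have a lineage neighborhood to
#' draw from. Genomes are grouped two-per-family; the last genome is placed
#' under Archaea, the rest under Bacteria.
#'
#' @param n_genomes number of genomes.
#' @param n_siblings decoy species per genus.
#' @param n_cousins decoy species in a sibling genus of each family.
#' @return `dm_taxonomy` data.frame (`taxon_id`, `parent_id`, `rank`, `name`).
#' @export
make_taxonomy <- function(n_genomes, n_siblings = 2L, n_cousins = 2L) {
  rows <- list(data.frame(taxon_id = "root", parent_id = "root",
                          rank = "root", name = "root",
                          stringsAsFactors = FALSE))
  add <- function(id, parent, rank, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = id, parent_id = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
  }
  add("sk_bact", "root", "superkingdom", "Bacteria")
  add("sk_arch", "root", "superkingdom", "Archaea")
  for (i in seq_len(n_genomes)) {
    archaeal <- i == n_genomes && n_genomes > 1L
    sk <- if (archaeal) "sk_arch" else "sk_bact"
    # archaeal genomes get their own lineage branch, never sharing a family
    # with a bacterial genome
    fam_idx <- if (archaeal) paste0(ceiling(i / 2), "a") else ceiling(i / 2)
    ph <- paste0("ph", fam_idx); cl <- paste0("cl", fam_idx)
    or <- paste0("or", fam_idx); fa <- paste0("fa", fam_idx)
    ge <- paste0("ge", i); sp <- paste0("sp", i)
    if (!any(vapply(rows, function(r) r$taxon_id[1] == ph, TRUE))) {
      add(ph, sk, "phylum", paste0("Phylum_", fam_idx))
      add(cl, ph, "class", paste0("Class_", fam_idx))
      add(or, cl, "order", paste0("Order_", fam_idx))
      add(fa, or, "family", paste0("Family_", fam_idx))
      gd <- paste0("ge", fam_idx, "_dec")
      add(gd, fa, "genus", paste0("DecoyGenus_", fam_idx))
      for (j in seq_len(n_cousins))
        add(paste0("sp_cous", fam_idx, "_", j), gd, "species",
            paste0("CousinSpecies_", fam_idx, "_", j))
    }
    add(ge, fa, "genus", paste0("Genus_", i))
    add(sp, ge, "species", paste0("Species_", i))
    for (j in seq_len(n_siblings))
      add(paste0("sp_sib", i, "_", j), ge, "species",
          paste0("SiblingSpecies_", i, "_", j))
  }
  taxonomy_tree(do.call(rbind, rows))
}

#' Generate a genome panel with planted markers and repeats
#'
#' Genomes are i.i.d. nucleotide sequences at per-genome GC targets. Each
#' genome carries each of `n_markers` fixed 120-bp marker sequences exactly
#' once (the same marker sequence in every genome, standing in for universal
#' single-copy marker genes). Repeats are exact copies of a shared element
#' inserted at recorded positions. All planted intervals are recorded.
#'
#' @param n_genomes number of genomes.
#' @param length_range total genome length range in bp (sampled uniformly,
#'   then rounded); lengths include planted elements.
#' @param gc_range GC-content targets, spread evenly across genomes between
#'   the two values.
#' @param n_markers markers per genome.
#' @param repeat_spec optional list of lists with `length`, `copies` and
#'   `genomes` (genome indices receiving `copies` exact copies each).
#' @param seed RNG seed (mandatory).
#' @return `dm_truth` list: `genomes`, `markers` (intervals),
#'   `marker_seqs`, `repeats`, `taxonomy`, `genome_taxon`, `gc_target`.
#' @export
generate_genomes <- function(n_genomes, length_range = c(50000L, 200000L),
                             gc_range = c(0.35, 0.65), n_markers = 6L,
                             repeat_spec = NULL, seed) {
  .dm_assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  marker_len <- 120L
  lens <- round(runif(n_genomes, length_range[1], length_range[2]))
  gc <- if (n_genomes == 1L) mean(gc_range) else
    seq(gc_range[1], gc_range[2], length.out = n_genomes)
  marker_ids <- if (n_markers > 0) paste0("marker", seq_len(n_markers)) else
    character(0)
  marker_seqs <- vapply(seq_len(n_markers), function(m)
    .random_dna(marker_len, 0.5), "")
  rep_seqs <- list()
  if (!is.null(repeat_spec)) {
    for (ri in seq_along(repeat_spec)) {
      rs <- repeat_spec[[ri]]
      .dm_assert(rs$length < min(lens[rs$genomes]),
                 "repeat length %d >= genome length", rs$length)
      rep_seqs[[ri]] <- .random_dna(rs$length, 0.5)
    }
  }
  genomes <- character(n_genomes)
  marker_rows <- list(); repeat_rows <- list()
  for (g in seq_len(n_genomes)) {
    # planted elements for this genome: all markers once + repeat copies
    elems <- marker_seqs
    elab <- marker_ids
    etype <- rep("marker", n_markers)
    if (!is.null(repeat_spec)) {
      for (ri in seq_along(repeat_spec)) {
        rs <- repeat_spec[[ri]]
        if (g %in% rs$genomes) {
          elems <- c(elems, rep(rep_seqs[[ri]], rs$copies))
          elab <- c(elab, rep(paste0("repeat", ri), rs$copies))
          etype <- c(etype, rep("repeat", rs$copies))
        }
      }
    }
    backbone_len <- lens[g] - sum(nchar(elems))
    .dm_assert(backbone_len > 1000L,
               "genome %d too short for its planted elements", g)
    backbone <- .random_dna(backbone_len, gc[g])
    if (length(elems) == 0L) {
      genomes[g] <- backbone
      next
    }
    cuts <- sort(sample.int(backbone_len - 1L, length(elems)))
    ord <- sample.int(length(elems))  # order of elements along the genome
    pieces <- character(2L * length(elems) + 1L)
    pos <- 0L; prev_cut <- 0L
    starts <- integer(length(elems))
    for (j in seq_along(elems)) {
      e <- ord[j]
      seg <- substr(backbone, prev_cut + 1L, cuts[j])
      pieces[2L * j - 1L] <- seg
      pos <- pos + nchar(seg)
      starts[e] <- pos
      pieces[2L * j] <- elems[e]
      pos <- pos + nchar(elems[e])
      prev_cut <- cuts[j]
    }
    pieces[2L * length(elems) + 1L] <- substr(backbone, prev_cut + 1L,
                                              backbone_len)
    genomes[g] <- paste(pieces, collapse = "")
    gid <- paste0("g", g)
    if (any(etype == "marker"))
      marker_rows[[g]] <- data.frame(
        marker_id = elab[etype == "marker"], genome_id = gid,
        start = starts[etype == "marker"],
        end = starts[etype == "marker"] + marker_len,
        stringsAsFactors = FALSE)
    if (any(etype == "repeat"))
      repeat_rows[[g]] <- data.frame(
        repeat_id = elab[etype == "repeat"], genome_id = gid,
        start = starts[etype == "repeat"],
        end = starts[etype == "repeat"] + nchar(elems[etype == "repeat"]),
        stringsAsFactors = FALSE)
  }
  tax <- make_taxonomy(n_genomes)
  truth <- list(
    genomes = seq_set(paste0("g", seq_len(n_genomes)), genomes),
    gc_target = gc,
    markers = if (length(marker_rows)) do.call(rbind, marker_rows) else NULL,
    marker_seqs = seq_set(marker_ids, marker_seqs),
    repeats = if (length(repeat_rows)) do.call(rbind, repeat_rows) else NULL,
    taxonomy = tax,
    genome_taxon = data.frame(genome_id = paste0("g", seq_len(n_genomes)),
                              taxon_id = paste0("sp", seq_len(n_genomes)),
                              stringsAsFactors = FALSE))
  class(truth) <- "dm_truth"
  truth
}

#' Sample per-sample relative abundances
#'
#' For the geometric profile the base vector is `r^(n-1), ..., r, 1`
#' normalized to sum 1; each sample receives an independent random permutation
#' of it, so the two samples share organisms but differ in who is abundant.
#'
#' @param n_genomes number of genomes.
#' @param profile either `list(type = "geometric", r = 4)` or an explicit
#'   non-negative numeric vector (normalized to sum 1, identical order in all
#'   samples).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @return matrix (genomes x samples), columns summing to 1.
#' @export
sample_abundances <- function(n_genomes, profile = list(type = "geometric", r = 4),
                              n_samples = 2L, seed) {
  .dm_assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  if (is.numeric(profile)) {
    .dm_assert(length(profile) == n_genomes, "abundance vector length mismatch")
    .dm_assert(all(profile >= 0), "negative abundance")
    base <- profile / sum(profile)
    out <- matrix(rep(base, n_samples), ncol = n_samples)
  } else {
    .dm_assert(profile$r > 1, "geometric ratio must be > 1")
    base <- profile$r ^ seq(n_genomes - 1L, 0L)
    base <- base / sum(base)
    out <- vapply(seq_len(n_samples), function(s) base[sample.int(n_genomes)],
                  numeric(n_genomes))
    out <- matrix(out, ncol = n_samples)
  }
  rownames(out) <- paste0("g", seq_len(n_genomes))
  colnames(out) <- paste0("sample", seq_len(n_samples))
  out
}

# pick genomes per fragment with probability proportional to abundance x length
.pick_genomes <- function(truth, abund, n) {
  lens <- nchar(truth$genomes$seq)
  w <- abund * lens
  sample.int(length(lens), n, replace = TRUE, prob = w / sum(w))
}

#' Simulate paired-end short reads
#'
#' Fragments are drawn from genomes with probability proportional to
#' abundance x genome length, fragment starts uniform. Mate 1 is the
#' fragment's 5' end, mate 2 the reverse complement of its 3' end; pairs may
#' overlap when the insert is shorter than twice the read length.
#' Substitutions are i.i.d. at `sub_rate`.
#'
#' @param truth `dm_truth` from [generate_genomes()].
#' @param n_pairs number of read pairs (> 0).
#' @param abundances abundance vector for this sample (one column of
#'   [sample_abundances()]).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert size model (normal, clamped at
#'   `read_length`).
#' @param sub_rate per-base substitution rate.
#' @param seed RNG seed.
#' @param sample_label prefix for read ids.
#' @return list with `r1`, `r2` (`dm_seqs` with `qual`) and `origins`
#'   (`read_id`, `genome_id`, `pos`, `strand`, `insert`).
#' @export
simulate_short_reads <- function(truth, n_pairs, abundances,
                                 read_length = 150L, insert_mean = 250L,
                                 insert_sd = 25, sub_rate = 0.001, seed,
                                 sample_label = "s1") {
  .dm_assert(n_pairs > 0, "n_pairs must be positive")
  .dm_assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  g <- .pick_genomes(truth, abundances, n_pairs)
  lens <- nchar(truth$genomes$seq)[g]
  ins <- pmax(read_length, pmin(round(rnorm(n_pairs, insert_mean, insert_sd)),
                                lens))
  start <- floor(runif(n_pairs) * (lens - ins + 1L))  # 0-based
  frag_by_g <- split(seq_len(n_pairs), g)
  r1 <- character(n_pairs); r2 <- character(n_pairs)
  for (gi in names(frag_by_g)) {
    idx <- frag_by_g[[gi]]
    gs <- truth$genomes$seq[as.integer(gi)]
    r1[idx] <- substring(gs, start[idx] + 1L, start[idx] + read_length)
    r2[idx] <- substring(gs, start[idx] + ins[idx] - read_length + 1L,
                         start[idx] + ins[idx])
  }
  r2 <- dm_revcomp(r2)
  if (sub_rate > 0) {
    r1 <- .apply_substitutions(r1, sub_rate)
    r2 <- .apply_substitutions(r2, sub_rate)
  }
  ids <- sprintf("%s_p%06d", sample_label, seq_len(n_pairs))
  qual <- strrep("I", read_length)
  list(r1 = seq_set(ids, r1, qual = rep(qual, n_pairs)),
       r2 = seq_set(ids, r2, qual = rep(qual, n_pairs)),
       origins = data.frame(read_id = ids,
                            genome_id = truth$genomes$id[g],
                            pos = start, strand = "+", insert = ins,
                            stringsAsFactors = FALSE))
}

.apply_substitutions <- function(seqs, rate) {
  total <- sum(nchar(seqs))
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  # flat positions over the concatenation, mapped back to (read, offset)
  flat <- sample.int(total, n_err)
  csum <- cumsum(nchar(seqs))
  rd <- findInterval(flat - 1L, csum) + 1L
  off <- flat - c(0L, csum)[rd]
  dm_apply_subs(seqs, rd, off, sample.int(3L, n_err, replace = TRUE))
}

#' Simulate error-prone long reads
#'
#' Lengths are log-normal (sigma 0.55) calibrated so the expected length
#' equals `mean_length`, truncated below at `min_length`. Per-base errors are
#' applied left to right: substitution, insertion of a random base before the
#' position, or deletion; the default mix 0.015/0.090/0.045 is
#' insertion-dominated and totals 15%. Each read carries a read-level quality
#' score in \[0, 100\].
#'
#' @param truth `dm_truth`.
#' @param n_reads number of reads.
#' @param abundances abundance vector for this sample.
#' @param mean_length target mean read length in bp.
#' @param min_length lower truncation in bp.
#' @param error_rates named vector with `sub`, `ins`, `del`, each in \[0, 0.3).
#' @param quality_model list with `mean` and `sd` of the read-level score.
#' @param seed RNG seed.
#' @param sample_label prefix for read ids.
#' @return list with `reads` (`dm_seqs` with `qual`, `read_quality`) and
#'   `origins` (`read_id`, `genome_id`, `pos`, `strand`, `template_length`).
#' @export
simulate_long_reads <- function(truth, n_reads, abundances,
                                mean_length = 7604L, min_length = 50L,
                                error_rates = c(sub = 0.015, ins = 0.090,
                                                del = 0.045),
                                quality_model = list(mean = 85, sd = 5),
                                seed, sample_label = "s1") {
  .dm_assert(n_reads > 0, "n_reads must be positive")
  .dm_assert(all(error_rates >= 0) && all(error_rates < 0.3),
             "error rates must be in [0, 0.3)")
  .dm_assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  sigma <- 0.55
  # indels change the emitted length by (1 + ins - del) on average; the
  # template-length model is deflated accordingly so the realized mean read
  # length matches mean_length
  expansion <- 1 + error_rates[["ins"]] - error_rates[["del"]]
  mu <- log(mean_length / expansion) - sigma^2 / 2
  tlen <- pmax(min_length, round(rlnorm(n_reads, mu, sigma)))
  g <- .pick_genomes(truth, abundances, n_reads)
  glen <- nchar(truth$genomes$seq)[g]
  tlen <- pmin(tlen, glen)
  start <- floor(runif(n_reads) * (glen - tlen + 1L))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    tmpl <- substr(truth$genomes$seq[g[i]], start[i] + 1L, start[i] + tlen[i])
    if (strand[i] == "-") tmpl <- dm_revcomp(tmpl)
    seqs[i] <- .apply_long_errors(tmpl, error_rates)
  }
  rq <- pmin(100, pmax(0, rnorm(n_reads, quality_model$mean, quality_model$sd)))
  ids <- sprintf("%s_L%06d", sample_label, seq_len(n_reads))
  list(reads = seq_set(ids, seqs,
                       qual = strrep("+", nchar(seqs)),
                       read_quality = rq),
       origins = data.frame(read_id = ids, genome_id = truth$genomes$id[g],
                            pos = start, strand = strand,
                            template_length = tlen,
                            stringsAsFactors = FALSE))
}

.apply_long_errors <- function(tmpl, rates) {
  if (sum(rates) == 0) return(tmpl)
  n <- nchar(tmpl)
  bases <- strsplit(tmpl, "", fixed = TRUE)[[1]]
  u <- runif(n)
  ps <- rates[["sub"]]; pi_ <- rates[["ins"]]; pd <- rates[["del"]]
  is_sub <- u < ps
  is_ins <- u >= ps & u < ps + pi_
  is_del <- u >= ps + pi_ & u < ps + pi_ + pd
  out <- bases
  if (any(is_sub)) {
    # substitute with one of the other three bases
    alpha <- c("A", "C", "G", "T")
    cur <- match(bases[is_sub], alpha)
    out[is_sub] <- alpha[((cur - 1L + sample.int(3L, sum(is_sub),
                                                 replace = TRUE)) %% 4L) + 1L]
  }
  out[is_del] <- ""
  if (any(is_ins)) {
    ins_base <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)
    out[is_ins] <- paste0(ins_base, out[is_ins])
  }
  paste(out, collapse = "")
}

#' Simulate a BLAST-style gene-hit table
#'
#' Stands in for protein searches against a reference database. For each gene
#' the best hit is its true species with probability `1 - decoy_rate`,
#' otherwise a random decoy species anywhere in the tree. Additional hits are
#' drawn from the true lineage neighborhood (same species, sibling species in
#' the genus, cousin species in the family, with decreasing probability) at
#' bitscores within the top-score margin; decoy e-values fall above the
#' conventional 1e-5 cut-off 60% of the time (and thus get filtered) and
#' below it otherwise.
#'
#' @param truth `dm_truth` (provides the taxonomy).
#' @param gene_taxa data.frame with `gene_id` and true `taxon_id` (species).
#' @param n_hits_per_gene hits per gene.
#' @param decoy_rate fraction of genes whose best hit is a decoy, in \[0, 1\].
#' @param seed RNG seed.
#' @return data.frame (`gene_id`, `taxon_id`, `bitscore`, `evalue`).
#' @export
generate_hit_table <- function(truth, gene_taxa, n_hits_per_gene = 5L,
                               decoy_rate = 0.1, seed) {
  .dm_assert(decoy_rate >= 0 && decoy_rate <= 1, "decoy_rate outside [0,1]")
  .dm_assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  tree <- truth$taxonomy
  .dm_assert(all(gene_taxa$taxon_id %in% tree$taxon_id),
             "gene true taxon absent from taxonomy")
  species <- tree$taxon_id[tree$rank == "species"]
  n <- nrow(gene_taxa)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- gene_taxa$taxon_id[i]
    genus <- tree$parent_id[match(tt, tree$taxon_id)]
    sibs <- setdiff(tree$taxon_id[tree$parent_id == genus & tree$rank == "species"], tt)
    fam <- tree$parent_id[match(genus, tree$taxon_id)]
    genera <- tree$taxon_id[tree$parent_id == fam & tree$rank == "genus"]
    cous <- tree$taxon_id[tree$parent_id %in% setdiff(genera, genus) &
                            tree$rank == "species"]
    best_score <- round(runif(1, 300, 600))
    is_decoy <- runif(1) < decoy_rate
    pool_p <- c(0.5, if (length(sibs)) 0.3 else 0, if (length(cous)) 0.2 else 0)
    pool <- list(tt, sibs, cous)
    n_extra <- n_hits_per_gene - 1L
    extra <- character(0); extra_mult <- numeric(0)
    if (n_extra > 0) {
      kind <- sample.int(3L, n_extra, replace = TRUE, prob = pool_p + 1e-9)
      extra <- vapply(kind, function(kd) {
        p <- pool[[kd]]
        if (!length(p)) tt else p[sample.int(length(p), 1L)]
      }, "")
      # score decay by taxonomic distance: same-species hits sit inside the
      # usual 0.90 top-score margin, siblings straddle it, cousins fall below
      lo <- c(0.91, 0.85, 0.55)[kind]; hi <- c(0.99, 0.95, 0.85)[kind]
      extra_mult <- runif(n_extra, lo, hi)
    }
    if (is_decoy) {
      decoy <- species[sample.int(length(species), 1L)]
      taxa <- c(decoy, tt, extra)
      scores <- c(best_score,
                  round(best_score * c(runif(1, 0.91, 0.99), extra_mult)))
      ev <- c(if (runif(1) < 0.6) 10^runif(1, -4.9, -3) else 10^runif(1, -30, -10),
              10^runif(1L + length(extra), -30, -10))
    } else {
      taxa <- c(tt, extra)
      scores <- c(best_score, round(best_score * extra_mult))
      ev <- 10^runif(1L + length(extra), -30, -10)
    }
    out[[i]] <- data.frame(gene_id = gene_taxa$gene_id[i], taxon_id = taxa,
                           bitscore = scores, evalue = ev,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write community truth tables as TSV
#'
#' @param truth `dm_truth`.
#' @param dir output directory (created if needed).
#' @param abundances optional abundance matrix from [sample_abundances()].
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir, abundances = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$genomes, file.path(dir, "genomes.fasta"))
  write_fasta(truth$marker_seqs, file.path(dir, "marker_seqs.fasta"))
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(truth$markers, "markers.tsv")
  if (!is.null(truth$repeats)) wt(truth$repeats, "repeats.tsv")
  wt(truth$taxonomy, "taxonomy.tsv")
  wt(truth$genome_taxon, "genome_taxon.tsv")
  if (!is.null(abundances))
    wt(data.frame(genome_id = rownames(abundances), abundances,
                  check.names = FALSE), "abundances.tsv")
  invisible(dir)
}
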