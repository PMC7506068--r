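# TNF binning, marker completeness/contamination, filters, lineage, re-assembly

test_that("tnf: mass placement, rc invariance, 136 canonical classes", {
  v <- tnf_vector(strrep("A", 100))
  expect_equal(unname(v[["AAAA"]]), 1)
  expect_equal(sum(v), 1)
  expect_equal(length(v), 136L)

  s <- random_dna(5000, seed = 41)
  expect_equal(tnf_vector(s), tnf_vector(revcomp(s)))
  expect_error(tnf_vector("ACG"), "4 bp")

  # enumeration oracle: 256 4-mers fold into (256 + 16)/2 = 136 classes
  b <- c("A", "C", "G", "T")
  all4 <- as.vector(outer(outer(outer(b, b, paste0), b, paste0), b, paste0))
  canon <- unique(pmin(all4, revcomp(all4)))
  expect_equal(length(canon), 136L)
  n_palindromes <- sum(all4 == revcomp(all4))
  expect_equal(n_palindromes, 16L)
  expect_equal((256 + 16) / 2, 136)
})

make_frag_community <- function(seed) {
  set.seed(seed)
  gcs <- c(0.35, 0.50, 0.65); depths1 <- c(80, 20, 5); depths2 <- c(5, 60, 30)
  contigs <- list(); depth_rows <- list(); truth <- character(0)
  for (g in 1:3) {
    genome <- random_dna(40000, gc = gcs[g])
    starts <- seq(1, 35001, by = 5000)
    for (j in seq_along(starts)) {
      id <- sprintf("g%d_f%02d", g, j)
      contigs[[id]] <- substr(genome, starts[j], starts[j] + 4999)
      truth[id] <- g
      depth_rows[[length(depth_rows) + 1L]] <- data.frame(
        contig_id = id, sample = c("s1", "s2"),
        mean_depth = c(depths1[g], depths2[g]) * runif(2, 0.9, 1.1),
        n_mapped_reads = 10L, stringsAsFactors = FALSE)
    }
  }
  list(contigs = seq_set(names(contigs), unlist(contigs)),
       depths = do.call(rbind, depth_rows), truth = truth)
}

test_that("bin_contigs recovers genomes from TNF + depth and filters length", {
  cm <- make_frag_community(42)
  res <- bin_contigs(cm$contigs, cm$depths, n_bins = "auto")
  asg <- res$assignments
  expect_equal(res$n_bins, 3L)
  # >= 95% of contigs co-binned with their genome majority
  tab <- table(cm$truth[asg$contig_id], asg$bin_id)
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)

  # 2,400 bp contig stays unbinned (strict > 2.5 kbp)
  cm2 <- cm
  cm2$contigs <- rbind(cm2$contigs,
                       seq_set("tiny", random_dna(2400, seed = 1)))
  class(cm2$contigs) <- c("dm_seqs", "data.frame")
  cm2$depths <- rbind(cm2$depths,
                      data.frame(contig_id = "tiny", sample = c("s1", "s2"),
                                 mean_depth = 10, n_mapped_reads = 1L))
  res2 <- bin_contigs(cm2$contigs, cm2$depths)
  expect_true("tiny" %in% res2$unbinned)

  # permutation invariance
  perm <- sample(nrow(cm$contigs))
  shuffled <- cm$contigs[perm, , drop = FALSE]
  class(shuffled) <- c("dm_seqs", "data.frame")
  res3 <- bin_contigs(shuffled, cm$depths, n_bins = "auto")
  expect_identical(res$assignments, res3$assignments)

  # a single genome's fragments give one bin
  one <- cm$contigs[startsWith(cm$contigs$id, "g1_"), , drop = FALSE]
  class(one) <- c("dm_seqs", "data.frame")
  r1 <- bin_contigs(one, cm$depths[cm$depths$contig_id %in% one$id, ],
                    n_bins = "auto")
  expect_equal(r1$n_bins, 1L)
})

test_that("evaluate_bin census arithmetic", {
  tr <- generate_genomes(2, c(30000, 30000), n_markers = 4, seed = 43)
  g1 <- seq_set("g1", tr$genomes$seq[1])
  ev <- evaluate_bin(g1, tr$marker_seqs)
  expect_equal(ev$completeness, 1.0)
  expect_equal(ev$contamination, 0.0)

  # 3 of 4 markers, no duplicates
  m <- tr$markers[tr$markers$genome_id == "g1", ]
  drop <- m[m$marker_id == "marker4", ]
  cut <- paste0(substr(g1$seq, 1, drop$start - 10),
                substr(g1$seq, drop$end + 10, nchar(g1$seq)))
  ev2 <- evaluate_bin(seq_set("c", cut), tr$marker_seqs)
  expect_equal(ev2$completeness, 0.75)
  expect_equal(ev2$contamination, 0.0)

  # merging two complete genomes doubles every marker
  both <- seq_set(c("a", "b"), tr$genomes$seq)
  ev3 <- evaluate_bin(both, tr$marker_seqs)
  expect_equal(ev3$completeness, 1.0)
  expect_equal(ev3$contamination, 1.0)
  expect_true(all(ev3$census == 2L))
})

test_that("bin filter keeps boundaries and discards strictly", {
  sc <- data.frame(bin_id = c("a", "b", "c", "d"),
                   completeness = c(0.59, 0.60, 1.00, 0.90),
                   contamination = c(0.00, 0.20, 0.21, 0.05))
  kept <- filter_bins(sc)
  expect_equal(kept$bin_id, c("b", "d"))
})

test_that("majority lineage: threshold, rank fallback, singleton", {
  tr <- make_taxonomy(4)
  # genus-level classifications: 3 say ge1, 1 says another genus of fa1;
  # 3/4 = 0.75 meets the threshold at genus
  ml <- majority_lineage(c("ge1", "ge1", "ge1", "ge2"), tr)
  expect_equal(ml$rank, "genus")
  expect_equal(ml$taxon_id, "ge1")
  expect_equal(ml$share, 0.75)
  # species-level classifications agreeing at 0.75 resolve at species
  mls <- majority_lineage(c("sp1", "sp1", "sp1", "sp_cous1_1"), tr)
  expect_equal(mls$rank, "species")

  # 2 vs 2 at genus within one family falls back to the family
  ml2 <- majority_lineage(c("sp1", "sp1", "sp2", "sp2"), tr)
  expect_equal(ml2$rank, "family")
  expect_equal(ml2$taxon_id, "fa1")

  ml3 <- majority_lineage("sp3", tr)
  expect_equal(ml3$taxon_id, "sp3")
  expect_equal(ml3$rank, "species")

  # agreement only at the superkingdom (3 of 4 bacterial)
  ml4 <- majority_lineage(c("sp1", "sp4", "sp3", "sp_cous2_1"), tr)
  expect_equal(ml4$rank, "superkingdom")
  # nothing agrees anywhere: 2 bacteria vs 2 archaea... use an even split
  tr2 <- make_taxonomy(2)   # sp2 is archaeal
  ml5 <- majority_lineage(c("sp1", "sp2"), tr2)
  expect_true(is.na(ml5$taxon_id))
})

test_that("bin re-assembly drops misbinned contigs without read support", {
  tr <- generate_genomes(2, c(40000, 40000), n_markers = 4, seed = 44)
  sim <- simulate_short_reads(tr, 16000, c(0.5, 0.5), seed = 45)
  idx <- build_kmer_index(tr$genomes, 21)
  a1 <- map_short_reads(sim$r1, idx)
  a2 <- map_short_reads(sim$r2, idx)
  # bin = genome 1 plus a contaminating slice of genome 2 that carries a
  # marker; the slice has no reads mapped to it (reads map to g2 itself)
  slice <- tr$markers[tr$markers$genome_id == "g2" &
                        tr$markers$marker_id == "marker1", ]
  contam <- substr(tr$genomes$seq[2], slice$start - 2000, slice$end + 2000)
  bin <- seq_set(c("g1", "bad"), c(tr$genomes$seq[1], contam))
  before <- evaluate_bin(bin, tr$marker_seqs)
  expect_gt(before$contamination, 0)
  empty_long <- seq_set(character(0), character(0))
  empty_aln <- a1[0, , drop = FALSE]
  rb <- reassemble_bin(bin, sim$r1, sim$r2, a1, a2, empty_long, empty_aln,
                       tr$marker_seqs)
  expect_true(rb$accepted)
  expect_lt(rb$scores$contamination, before$contamination)
  expect_gte(rb$scores$completeness, 0.75)
  expect_lte(rb$n_reads_used, 2L * nrow(sim$r1))

  # a clean bin is kept (or equal) - no degradation
  clean <- seq_set("g1", tr$genomes$seq[1])
  rb2 <- reassemble_bin(clean, sim$r1, sim$r2, a1, a2, empty_long, empty_aln,
                        tr$marker_seqs)
  expect_gte(rb2$scores$completeness, rb2$before$completeness)
  expect_lte(rb2$scores$contamination, rb2$before$contamination)

  # a bin with no mapped reads is returned unchanged with a warning
  alien <- seq_set("x", random_dna(5000, seed = 46))
  expect_warning(rb3 <- reassemble_bin(alien, sim$r1, sim$r2,
                                       a1[0, ], a2[0, ], empty_long,
                                       empty_aln, tr$marker_seqs),
                 "no mapped reads")
  expect_false(rb3$accepted)
})

test_that("bin metrics: single contig and manual medians", {
  tr <- generate_genomes(1, c(30000, 30000), seed = 47)
  single <- seq_set("c1", substr(tr$genomes$seq[1], 1, 5000))
  bm <- bin_metrics(list(B1 = single))
  expect_equal(bm$n_contigs, 1L)
  expect_equal(bm$n50, 5000)

  bins <- list(
    A = seq_set(c("a1", "a2"), c(substr(tr$genomes$seq[1], 1, 4000),
                                 substr(tr$genomes$seq[1], 4001, 10000))),
    B = seq_set("b1", substr(tr$genomes$seq[1], 10001, 13000)),
    C = seq_set(c("c1", "c2", "c3"),
                substring(tr$genomes$seq[1], c(13001, 18001, 23001),
                          c(18000, 23000, 28000))))
  bm3 <- bin_metrics(bins)
  med <- attr(bm3, "medians")
  expect_equal(unname(med["n_contigs"]), 2)
  expect_equal(unname(med["total_bp"]), median(c(10000, 3000, 15000)))
  expect_equal(bm3$n50[bm3$bin_id == "A"], 6000)
})
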