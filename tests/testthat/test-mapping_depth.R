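# k-mer index, short/long-read mapping, depth computation and partitioning

test_that("index enumerates canonical k-mer positions and validates k", {
  idx <- build_kmer_index(seq_set("c1", "ACGTACGT"), k = 11)  # shorter than k
  expect_equal(kmer_index_info(idx)$n_positions, 0)           # zero seeds, no error

  # enumeration oracle on a contig with k = 5 via a 5-mer walk
  # (k = 5 is outside the supported mapper range, so enumerate with k = 11)
  s <- random_dna(60, seed = 1)
  idx2 <- build_kmer_index(seq_set("c1", s), k = 11)
  expect_equal(kmer_index_info(idx2)$n_positions, 60 - 11 + 1)
  d <- kmer_index_dump(idx2)
  expect_equal(sort(d$pos), 0:(60 - 11))

  expect_error(build_kmer_index(seq_set("c1", s), k = 20), "odd")
  expect_error(build_kmer_index(seq_set("c1", s), k = 9), "11")

  # canonical k-mer set of a sequence equals that of its reverse complement
  idx3 <- build_kmer_index(seq_set("c1", revcomp(s)), k = 11)
  expect_setequal(kmer_index_dump(idx2)$kmer, kmer_index_dump(idx3)$kmer)
})

test_that("short-read mapping: true placement, unmapped, repeat tie-break", {
  set.seed(2)
  g <- random_dna(5000)
  idx <- build_kmer_index(seq_set("c1", g), 21)
  a <- map_short_reads(seq_set("r", substr(g, 1001, 1150)), idx)
  expect_equal(a$start, 1000L)
  expect_equal(a$end, 1150L)
  expect_equal(a$strand, "+")

  # reverse-complemented read maps to the same locus on the minus strand
  b <- map_short_reads(seq_set("r", revcomp(substr(g, 1001, 1150))), idx)
  expect_equal(b$start, 1000L)
  expect_equal(b$strand, "-")

  # a read sharing no seed with the contigs is unmapped
  rnd <- random_dna(150, seed = 99)
  d <- kmer_index_dump(build_kmer_index(seq_set("q", rnd), 21))
  stopifnot(!any(d$kmer %in% kmer_index_dump(idx)$kmer))   # fixture sanity
  u <- map_short_reads(seq_set("r", rnd), idx)
  expect_equal(nrow(u), 0L)
  expect_equal(attr(u, "n_unmapped"), 1L)

  # 2-copy exact repeat: deterministic tie-break to the first (contig, offset)
  rep_el <- random_dna(400, seed = 3)
  g2 <- paste0(random_dna(1000, seed = 4), rep_el, random_dna(800, seed = 5),
               rep_el, random_dna(1000, seed = 6))
  idx2 <- build_kmer_index(seq_set("c1", g2), 21)
  rd <- substr(rep_el, 100, 249)
  m <- map_short_reads(seq_set("r", rd), idx2)
  expect_equal(m$start, 1000L + 99L)   # lexicographically first placement
})

test_that("long-read mapping: correct locus error-free, robust at 15% error", {
  set.seed(7)
  g1 <- random_dna(50000); g2 <- random_dna(30000)
  idx <- build_kmer_index(seq_set(c("g1", "g2"), c(g1, g2)), 15)
  a <- map_long_reads(seq_set("L", substr(g1, 10001, 15000)), idx)
  expect_equal(a$contig_id, "g1")
  expect_equal(a$strand, "+")
  expect_lt(abs(a$start - 10000), 20)

  # read shorter than k is unmapped
  expect_equal(nrow(map_long_reads(seq_set("s", "ACGTACGTAC"), idx)), 0L)

  # 500 error-prone reads still find their source contig
  n <- 500
  src <- sample(c("g1", "g2"), n, TRUE, prob = c(5, 3))
  reads <- vapply(1:n, function(i) {
    g <- if (src[i] == "g1") g1 else g2
    s <- sample.int(nchar(g) - 3000, 1)
    depthmeta:::.apply_long_errors(substr(g, s, s + 2999),
                                   c(sub = 0.015, ins = 0.09, del = 0.045))
  }, "")
  hits <- map_long_reads(seq_set(paste0("L", 1:n), reads), idx)
  ok <- hits$contig_id == src[match(hits$read_id, paste0("L", 1:n))]
  expect_gte(sum(ok) / n, 0.95)
})

test_that("compute_depths matches arithmetic and the per-base pileup oracle", {
  aln <- data.frame(read_id = paste0("r", 1:10), contig_id = "c1",
                    start = seq(0, 900, 100), end = seq(100, 1000, 100),
                    strand = "+", score = 100L, is_primary = TRUE,
                    stringsAsFactors = FALSE)
  d <- compute_depths(aln, c(c1 = 1000L, c2 = 500L))
  expect_equal(d$mean_depth[d$contig_id == "c1"], 1.0)
  expect_equal(d$mean_depth[d$contig_id == "c2"], 0.0)
  expect_equal(d$n_mapped_reads[d$contig_id == "c2"], 0L)

  # random alignments vs brute-force pileup
  set.seed(8)
  lens <- c(a = 700L, b = 1200L)
  n <- 200
  ctg <- sample(names(lens), n, TRUE)
  st <- vapply(ctg, function(cn) sample.int(lens[[cn]] - 50, 1), 1L)
  en <- st + sample(20:50, n, TRUE)
  aln2 <- data.frame(read_id = paste0("r", 1:n), contig_id = ctg,
                     start = st, end = en, strand = "+", score = 1L,
                     is_primary = TRUE,
                     sample = sample(c("s1", "s2"), n, TRUE),
                     stringsAsFactors = FALSE)
  d2 <- compute_depths(aln2, lens)
  for (cn in names(lens)) for (sm in c("s1", "s2")) {
    pile <- numeric(lens[[cn]])
    sel <- aln2$contig_id == cn & aln2$sample == sm
    for (i in which(sel)) {
      pos <- (aln2$start[i] + 1):aln2$end[i]
      pile[pos] <- pile[pos] + 1
    }
    expect_equal(d2$mean_depth[d2$contig_id == cn & d2$sample == sm],
                 mean(pile))
  }
  expect_error(compute_depths(data.frame(read_id = "r", contig_id = "zz",
                                         start = 0L, end = 5L, strand = "+",
                                         score = 1L, is_primary = TRUE),
                              lens), "unknown contig")
})

test_that("geometric depth partition separates powers of two into 11 bins", {
  d <- data.frame(contig_id = sprintf("c%02d", 1:11), sample = "s1",
                  mean_depth = 2^(0:10), n_mapped_reads = 1L)
  p <- partition_by_depth(d, 11)
  bins <- p$contigs$bin[match(sprintf("c%02d", 1:11), p$contigs$contig_id)]
  expect_equal(bins, 1:11)                    # one contig per bin
  expect_equal(length(p$boundaries), 12L)
  expect_true(all(diff(p$boundaries) > 0))

  same <- d; same$mean_depth <- 7
  expect_equal(unique(partition_by_depth(same, 11)$contigs$bin), 1L)
  expect_equal(unique(partition_by_depth(d, 1)$contigs$bin), 1L)

  zero <- d; zero$mean_depth <- 0
  expect_error(partition_by_depth(zero), "nothing mapped")
})

test_that("differential partition separates depth-colliding genomes", {
  # two organisms with identical combined depth but opposite per-sample
  # profiles must not share a phylotype
  d <- rbind(
    data.frame(contig_id = c("a1", "a2"), sample = "s1", mean_depth = 100,
               n_mapped_reads = 1L),
    data.frame(contig_id = c("a1", "a2"), sample = "s2", mean_depth = 5,
               n_mapped_reads = 1L),
    data.frame(contig_id = c("b1", "b2"), sample = "s1", mean_depth = 5,
               n_mapped_reads = 1L),
    data.frame(contig_id = c("b1", "b2"), sample = "s2", mean_depth = 100,
               n_mapped_reads = 1L))
  p <- partition_by_depth_joint(d, 11)
  bin_of <- setNames(p$contigs$bin, p$contigs$contig_id)
  expect_equal(bin_of[["a1"]], bin_of[["a2"]])
  expect_equal(bin_of[["b1"]], bin_of[["b2"]])
  expect_false(bin_of[["a1"]] == bin_of[["b1"]])
  # single sample reduces to the 1D scheme
  d1 <- d[d$sample == "s1", ]
  expect_identical(partition_by_depth_joint(d1, 5)$contigs,
                   partition_by_depth(d1, 5)$contigs)
})

test_that("assign_reads conserves reads and routes pairs by mate 1", {
  part <- list(contigs = data.frame(contig_id = c("c1", "c2"),
                                    depth = c(10, 100), bin = c(1L, 2L),
                                    stringsAsFactors = FALSE))
  aln1 <- data.frame(read_id = c("p1", "p2"), contig_id = c("c1", "c2"),
                     start = 0L, end = 100L, strand = "+", score = 1L,
                     is_primary = TRUE, stringsAsFactors = FALSE)
  aln2 <- data.frame(read_id = c("p2", "p3"), contig_id = c("c1", "c1"),
                     start = 0L, end = 100L, strand = "-", score = 1L,
                     is_primary = TRUE, stringsAsFactors = FALSE)
  out <- assign_reads(c("p1", "p2", "p3", "p4"), part, aln1, aln2)
  expect_equal(out$bin, c(1L, 2L, 1L, NA))  # p2 follows mate 1; p3 rescued
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_equal(nrow(out), 4L)               # conservation: all ids present

  none <- assign_reads(c("a", "b"), part, aln1[0, ], aln2[0, ])
  expect_true(all(is.na(none$bin)))
})

test_that("phylotype recovery on a 3-genome community with separated depths", {
  tr <- generate_genomes(3, c(30000, 30000), n_markers = 0, seed = 91)
  ab <- c(0.76, 0.19, 0.05)                 # ratio 4 geometric, ~60x top
  sim <- simulate_short_reads(tr, 8000, ab, seed = 92)
  idx <- build_kmer_index(tr$genomes, 21)
  a1 <- map_short_reads(sim$r1, idx)
  a2 <- map_short_reads(sim$r2, idx)
  a1$sample <- "s1"; a2$sample <- "s1"
  d <- compute_depths(rbind(a1, a2), idx$contig_lengths)
  p <- partition_by_depth(d, 11)
  asg <- assign_reads(sim$origins$read_id, p, a1, a2)
  ok <- !is.na(asg$bin)
  expect_gte(mean(ok), 0.99)
  # >= 95% of reads land in the phylotype of their true genome's contigs
  truth_bin <- p$contigs$bin[match(sim$origins$genome_id, p$contigs$contig_id)]
  expect_gte(mean(asg$bin[ok] == truth_bin[ok]), 0.95)
  expect_gte(rand_index(asg$bin[ok], sim$origins$genome_id[ok]), 0.95)
  # determinism
  p2 <- partition_by_depth(d, 11)
  expect_identical(p, p2)
})
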