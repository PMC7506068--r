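# ground-truthed community generator

test_that("generate_genomes plants every marker exactly once and repeats verbatim", {
  tr <- generate_genomes(1, c(30000, 30000), n_markers = 4, seed = 11)
  g <- tr$genomes$seq[1]
  for (i in 1:4) {
    m <- tr$marker_seqs$seq[i]
    expect_equal(length(gregexpr(m, g, fixed = TRUE)[[1]]), 1L)
  }
  # marker intervals extract the marker sequence verbatim
  for (r in seq_len(nrow(tr$markers))) {
    mi <- tr$markers[r, ]
    expect_identical(substr(g, mi$start + 1L, mi$end),
                     tr$marker_seqs$seq[match(mi$marker_id,
                                              tr$marker_seqs$id)])
  }

  tr2 <- generate_genomes(2, c(30000, 40000), n_markers = 2,
                          repeat_spec = list(list(length = 2000, copies = 2,
                                                  genomes = 1L)),
                          seed = 12)
  reps <- tr2$repeats
  expect_equal(nrow(reps), 2L)
  g1 <- tr2$genomes$seq[1]
  copies <- substring(g1, reps$start + 1L, reps$end)
  expect_identical(copies[1], copies[2])  # exact copies
})

test_that("realized GC tracks the target within binomial tolerance", {
  tr <- generate_genomes(1, c(100000, 100000), gc_range = c(0.60, 0.60),
                         n_markers = 0, seed = 13)
  g <- strsplit(tr$genomes$seq[1], "")[[1]]
  gc <- mean(g %in% c("G", "C"))
  expect_lt(abs(gc - 0.60), 0.01)
})

test_that("sample_abundances normalizes and permutes a geometric profile", {
  ab <- sample_abundances(3, list(type = "geometric", r = 5), n_samples = 2,
                          seed = 5)
  for (s in 1:2) {
    expect_equal(sum(ab[, s]), 1, tolerance = 1e-9)
    expect_equal(sort(ab[, s], decreasing = TRUE),
                 c(25, 5, 1) / 31, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(unname(sample_abundances(1, seed = 1)[, 1]), 1.0)
  expect_error(sample_abundances(2, c(-1, 2), seed = 1), "negative")
  # explicit vectors are normalized and shared across samples
  ab2 <- sample_abundances(2, c(3, 1), n_samples = 2, seed = 2)
  expect_equal(unname(ab2[, 1]), c(0.75, 0.25))
  expect_identical(ab2[, 1], ab2[, 2])
})

test_that("error-free short reads are exact genomic substrings; depth obeys n*2L/G", {
  tr <- generate_genomes(1, c(100000, 100000), n_markers = 0, seed = 21)
  g <- tr$genomes$seq[1]
  grc <- revcomp(g)
  sim <- simulate_short_reads(tr, 500, 1, sub_rate = 0, seed = 22)
  hits <- vapply(seq_len(500), function(i)
    grepl(sim$r1$seq[i], g, fixed = TRUE) &&
      grepl(sim$r2$seq[i], grc, fixed = TRUE), TRUE)
  expect_true(all(hits))

  sim2 <- simulate_short_reads(tr, 10000, 1, sub_rate = 0, seed = 23)
  depth <- 10000 * 2 * 150 / 100000              # 30x expected
  realized <- sum(nchar(c(sim2$r1$seq, sim2$r2$seq))) / 100000
  expect_lt(abs(realized - depth), 1)
})

test_that("read counts follow abundance x length within binomial noise", {
  tr <- generate_genomes(2, c(50000, 50000), n_markers = 0, seed = 31)
  ab <- c(0.9, 0.1)
  sim <- simulate_short_reads(tr, 20000, ab, seed = 32)
  n1 <- sum(sim$origins$genome_id == "g1")
  p <- 0.9  # equal lengths: fragment probability = abundance
  expect_lt(abs(n1 - 20000 * p), 3 * sqrt(20000 * p * (1 - p)))
})

test_that("long reads: exact when error-free, ~15% edit distance at defaults", {
  tr <- generate_genomes(1, c(60000, 60000), n_markers = 0, seed = 41)
  g <- tr$genomes$seq[1]
  sim0 <- simulate_long_reads(tr, 20, 1, error_rates = c(sub = 0, ins = 0, del = 0),
                              seed = 42)
  both <- paste0(g, "NN", revcomp(g))
  expect_true(all(vapply(sim0$reads$seq, grepl, TRUE, x = both, fixed = TRUE)))

  sim <- simulate_long_reads(tr, 30, 1, seed = 43)
  # edit distance to the true template, via the independent base-R oracle.
  # the generative process applies exactly 0.15 events per template base,
  # which upper-bounds the minimal edit distance; chance matches between
  # random edits and their neighborhood push the Levenshtein minimum ~7%
  # below the generative rate (measured ~0.139), so the band is one-sided
  # at the top and generous at the bottom
  dists <- vapply(1:30, function(i) {
    o <- sim$origins[i, ]
    tmpl <- substr(g, o$pos + 1, o$pos + o$template_length)
    if (o$strand == "-") tmpl <- revcomp(tmpl)
    as.integer(utils::adist(sim$reads$seq[i], tmpl)) / nchar(tmpl)
  }, numeric(1))
  expect_lt(mean(dists), 0.151)
  expect_gt(mean(dists), 0.125)
  # realized length expansion matches 1 + ins - del
  expect_lt(abs(mean(nchar(sim$reads$seq) / sim$origins$template_length) -
                  1.045), 0.01)
  expect_true(all(sim$reads$read_quality >= 0 & sim$reads$read_quality <= 100))
})

test_that("realized mean long-read length matches the 7,604 bp calibration target", {
  tr <- generate_genomes(1, c(150000, 150000), n_markers = 0, seed = 51)
  sim <- simulate_long_reads(tr, 10000, 1, seed = 52)
  m <- mean(nchar(sim$reads$seq))
  expect_lt(abs(m - 7604) / 7604, 0.05)
})

test_that("identical seeds give bit-identical simulator outputs", {
  tr1 <- generate_genomes(2, c(30000, 40000), seed = 61)
  tr2 <- generate_genomes(2, c(30000, 40000), seed = 61)
  expect_identical(tr1$genomes, tr2$genomes)
  expect_identical(tr1$markers, tr2$markers)
  a <- simulate_short_reads(tr1, 100, c(0.5, 0.5), seed = 62)
  b <- simulate_short_reads(tr1, 100, c(0.5, 0.5), seed = 62)
  expect_identical(a, b)
  la <- simulate_long_reads(tr1, 20, c(0.5, 0.5), seed = 63)
  lb <- simulate_long_reads(tr1, 20, c(0.5, 0.5), seed = 63)
  expect_identical(la, lb)
})

test_that("hit tables: noiseless recovery, e-value decoys, genus-level recovery", {
  tr <- generate_genomes(3, c(30000, 30000), seed = 71)
  genes <- data.frame(gene_id = paste0("G", 1:60),
                      taxon_id = rep(paste0("sp", 1:3), 20),
                      stringsAsFactors = FALSE)
  ht0 <- generate_hit_table(tr, genes, n_hits_per_gene = 1, decoy_rate = 0,
                            seed = 72)
  asg0 <- assign_genes(ht0, tr$taxonomy)
  expect_identical(asg0$taxon_id[match(genes$gene_id, asg0$gene_id)],
                   genes$taxon_id)

  # a hit at e-value 1e-4 is excluded downstream at the 1e-5 cut-off
  one <- data.frame(gene_id = "G1", taxon_id = "sp1", bitscore = 500,
                    evalue = 1e-4)
  expect_true(is.na(assign_genes(one, tr$taxonomy)$taxon_id))

  expect_error(generate_hit_table(tr, genes, decoy_rate = 1.5, seed = 1),
               "decoy_rate")

  # 1,000 genes at decoy_rate 0.2: genus-level recovery >= 90%
  big <- data.frame(gene_id = paste0("B", 1:1000),
                    taxon_id = sample(paste0("sp", 1:3), 1000, TRUE),
                    stringsAsFactors = FALSE)
  ht <- generate_hit_table(tr, big, n_hits_per_gene = 5, decoy_rate = 0.2,
                           seed = 73)
  asg <- assign_genes(ht, tr$taxonomy)
  true_genus <- vapply(big$taxon_id, tax_ancestor_at_rank, "",
                       tree = tr$taxonomy, rank = "genus")
  got_genus <- vapply(asg$taxon_id[match(big$gene_id, asg$gene_id)],
                      function(t) if (is.na(t)) NA_character_ else
                        tax_ancestor_at_rank(tr$taxonomy, t, "genus"), "")
  expect_gte(mean(!is.na(got_genus) & got_genus == true_genus), 0.90)
})

test_that("read origins recompute true per-genome depth (n*L/G identity)", {
  tr <- generate_genomes(2, c(40000, 40000), n_markers = 0, seed = 81)
  sim <- simulate_short_reads(tr, 5000, c(0.7, 0.3), seed = 82)
  for (gid in c("g1", "g2")) {
    n <- sum(sim$origins$genome_id == gid)
    exp_n <- 5000 * c(g1 = 0.7, g2 = 0.3)[[gid]]
    expect_lt(abs(n - exp_n), 4 * sqrt(exp_n))
    depth <- n * 300 / 40000
    # depth identity: reads x bases / genome length
    expect_equal(depth, n * 2 * 150 / 40000)
  }
})
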