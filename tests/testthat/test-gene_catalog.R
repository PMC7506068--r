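# ORF prediction, greedy NR clustering, catalog merging and statistics

make_gene <- function(n_codons, seed) {
  set.seed(seed)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""), "TAA")
}

gene_df <- function(seqs, complete = TRUE) {
  data.frame(gene_id = sprintf("g%03d", seq_along(seqs)), contig_id = "c",
             start = 0L, end = nchar(seqs), strand = "+", seq = seqs,
             complete = complete, stringsAsFactors = FALSE)
}

test_that("find_orfs honors both length filters and completeness", {
  gene <- make_gene(100, 20)          # 300 bp incl. stop
  stuffing <- strrep("C", 150)        # stop- and ATG-free
  ctg <- seq_set("c1", paste0(stuffing, gene, stuffing))
  o <- find_orfs(ctg)
  hit <- o[o$complete & o$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 150L)
  expect_equal(hit$end, 450L)
  expect_equal(nchar(hit$seq), 300L)
  expect_identical(hit$seq, gene)

  # contigs under 500 bp yield nothing regardless of content
  short <- seq_set("s", substr(paste0(stuffing, gene, stuffing), 1, 499))
  expect_equal(nrow(find_orfs(short)), 0L)

  # contig beginning mid-gene: no ATG before the first stop, reported truncated
  midgene <- paste0(substr(make_gene(120, 21), 100, 460), strrep("C", 400))
  o2 <- find_orfs(seq_set("m", midgene))
  trunc <- o2[o2$strand == "+" & o2$start == 0 & !o2$complete, ]
  expect_gte(nrow(trunc), 1L)
})

test_that("ORF invariants: frame, bounds, strand-aware extraction", {
  set.seed(22)
  ctgs <- seq_set(paste0("c", 1:5),
                  vapply(rep(3000, 5), function(L) random_dna(L), ""))
  o <- find_orfs(ctgs)
  expect_true(all(nchar(o$seq) >= 100))
  expect_true(all(o$end <= 3000))
  expect_true(all(nchar(o$seq[o$complete]) %% 3 == 0))
  expect_true(all(substr(o$seq[o$complete], 1, 3) == "ATG"))
  expect_true(all(substring(o$seq[o$complete],
                            nchar(o$seq[o$complete]) - 2) %in%
                    c("TAA", "TAG", "TGA")))
  # coordinates and strand reproduce the stored sequence
  for (i in seq_len(nrow(o))) {
    sub <- substr(ctgs$seq[match(o$contig_id[i], ctgs$id)],
                  o$start[i] + 1L, o$end[i])
    if (o$strand[i] == "-") sub <- revcomp(sub)
    expect_identical(sub, o$seq[i])
  }
})

test_that("greedy clustering: duplicates, prefixes, and post-hoc thresholds", {
  g <- make_gene(200, 23)
  cl <- cluster_nr(gene_df(c(g, g)))
  expect_equal(length(cl$reps), 1L)
  expect_equal(nrow(cl$genes), 2L)

  # an exact 80% prefix joins (coverage of the shorter sequence is 1.0)
  pre <- substr(g, 1, round(nchar(g) * 0.8))
  cl2 <- cluster_nr(gene_df(c(g, pre)))
  expect_equal(length(cl2$reps), 1L)

  # every member aligns to its representative at the thresholds,
  # and the representative is the longest member of its cluster
  set.seed(24)
  seqs <- c(vapply(1:8, function(i) make_gene(sample(60:140, 1), 30 + i), ""))
  noisy <- vapply(seqs[1:4], function(s) {
    n <- nchar(s); k <- max(1, round(0.03 * n))
    depthmeta:::dm_apply_subs(s, rep(1L, k), sort(sample.int(n, k)),
                              sample.int(3L, k, TRUE))
  }, "")
  cl3 <- cluster_nr(gene_df(c(seqs, noisy)))
  for (r in seq_len(nrow(cl3$genes))) {
    row <- cl3$genes[r, ]
    rep_seq <- cl3$genes$seq[match(row$rep_id, cl3$genes$gene_id)]
    expect_gte(nchar(rep_seq), nchar(row$seq))
    if (row$rep_id != row$gene_id) {
      al <- depthmeta:::dm_pair_align(rep_seq, row$seq, 15L)
      expect_gte(al$identity, 0.95)
      expect_gte(al$coverage, 0.90)
    }
  }
  # idempotence: clustering the representatives changes nothing
  reps <- catalog_representatives(cl3)
  expect_equal(length(cluster_nr(reps)$reps), length(cl3$reps))
})

test_that("clustering matches the all-pairs greedy oracle on planted duplicates", {
  set.seed(25)
  base <- vapply(1:10, function(i) make_gene(sample(40:70, 1), 40 + i), "")
  copies <- unlist(lapply(base[1:6], function(s) {
    vapply(1:2, function(j) {
      n <- nchar(s); k <- max(1, round(runif(1, 0.01, 0.04) * n))
      depthmeta:::dm_apply_subs(s, rep(1L, k), sort(sample.int(n, k)),
                                sample.int(3L, k, TRUE))
    }, "")
  }))
  genes <- gene_df(c(base, copies))
  got <- cluster_nr(genes)

  # oracle: brute-force best-offset ungapped alignment over all offsets and
  # strands, then the same greedy sweep
  ora_align <- function(a, b) {
    best <- 0
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "")[[1]]
    for (bs in c(b, revcomp(b))) {
      bv <- strsplit(bs, "")[[1]]
      for (off in (-lb + 1):(la - 1)) {
        qs <- max(0, -off); as <- max(0, off)
        ov <- min(lb - qs, la - as)
        if (ov < 0.90 * min(la, lb)) next
        mm <- sum(av[(as + 1):(as + ov)] != bv[(qs + 1):(qs + ov)])
        id <- (ov - mm) / ov
        if (id > best) best <- id
      }
    }
    best
  }
  ord <- order(-nchar(genes$seq), genes$seq)
  sorted <- genes[ord, ]
  reps <- integer(0)
  assign <- integer(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    joined <- 0L
    for (r in reps) {
      if (ora_align(sorted$seq[r], sorted$seq[i]) >= 0.95) { joined <- r; break }
    }
    if (joined == 0L) { reps <- c(reps, i); assign[i] <- i }
    else assign[i] <- joined
  }
  want <- sorted$gene_id[assign]
  expect_identical(got$genes$rep_id, want)
})

test_that("merge_catalogs is additive on disjoint and idempotent on identical input", {
  a <- cluster_nr(gene_df(vapply(1:5, function(i) make_gene(80, 50 + i), "")),
                  label = "A")
  b <- cluster_nr(gene_df(vapply(1:4, function(i) make_gene(90, 60 + i), "")),
                  label = "B")
  m <- merge_catalogs(list(a, b))
  expect_equal(length(m$reps), 9L)

  m2 <- merge_catalogs(list(a, a))
  expect_equal(length(m2$reps), 5L)

  # planted common core across three catalogs
  core <- vapply(1:3, function(i) make_gene(100, 70 + i), "")
  mk <- function(extra_seed, lab) {
    cluster_nr(gene_df(c(core, vapply(1:3, function(i)
      make_gene(70, extra_seed + i), ""))), label = lab)
  }
  cats <- list(mk(80, "X"), mk(90, "Y"), mk(100, "Z"))
  m3 <- merge_catalogs(cats)
  shared <- sum(m3$cluster_sources == "X,Y,Z")
  expect_equal(shared, 3L)
  expect_error(merge_catalogs(list(a)), "two catalogs")
})

test_that("catalog statistics follow the printed-table arithmetic", {
  one <- cluster_nr(gene_df(make_gene(100, 110)))
  st <- catalog_stats(one)
  expect_equal(st$n_orfs, 1L)
  expect_equal(st$total_length, 300)
  expect_equal(st$average_length, 300.00)
  expect_equal(st$pct_complete, 100.00)

  # all-complete synthetic catalog
  allc <- cluster_nr(gene_df(vapply(1:6, function(i) make_gene(60, 120 + i), "")))
  expect_equal(catalog_stats(allc)$pct_complete, 100.00)

  # average * count = total within rounding, on random catalogs
  set.seed(26)
  for (i in 1:5) {
    ct <- cluster_nr(gene_df(vapply(1:sample(3:9, 1), function(j)
      make_gene(sample(40:200, 1), 1000 * i + j), "")))
    st <- catalog_stats(ct)
    expect_lt(abs(st$average_length * st$n_orfs - st$total_length),
              0.005 * st$n_orfs + 1e-9)
  }
})

test_that("reads map back to catalog representatives", {
  set.seed(27)
  genes <- vapply(1:6, function(i) make_gene(130, 130 + i), "")
  ct <- cluster_nr(gene_df(genes))
  reads <- unlist(lapply(genes[1:5], function(g)
    substring(g, seq(1, nchar(g) - 149, 50), seq(150, nchar(g), 50))))
  res <- map_reads_to_catalog(seq_set(paste0("r", seq_along(reads)), reads), ct)
  expect_equal(res$mapping_ratio, 1.0)
  expect_equal(res$unmapped_gene_ids, ct$genes$gene_id[match(genes[6], ct$genes$seq)])

  # substring oracle on the error-free case
  reps <- catalog_representatives(ct)
  ora <- mean(vapply(reads, function(r) any(
    grepl(r, reps$seq, fixed = TRUE) | grepl(revcomp(r), reps$seq, fixed = TRUE)),
    TRUE))
  expect_equal(res$mapping_ratio, ora)
})
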