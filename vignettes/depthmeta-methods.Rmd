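---
title: "depthmeta: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{depthmeta: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which knobs
matter, what the synthetic data does and does not emulate, and where the
design was genuinely open. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

A metagenome is a mixture of genomes at very uneven abundance. Short reads
(150 bp pairs, 250 bp insert, ~0.1% substitution error) give accurate but
fragmented assemblies; long reads (log-normal lengths around a 7,604 bp
mean, 15% indel-dominated error) span repeats but cannot carry an assembly
alone. The pipeline's central idea is that **coverage depth is an organism
signature**: reads mapped back to a merged assembly can be stratified by
the depth of the contig they hit, and each stratum re-assembled as an
almost single-organism problem. Long reads then only need to *order and
join* accurate short-read contigs, not to contribute base-level sequence
except inside junction gaps.

Formally, for contig $c$ and sample $s$, `mean_depth(c, s)` is aligned
reference bases over contig length. Stratification assigns each contig the
vector of per-sample depth classes; a read pair inherits the stratum of its
mate-1 contig (mate 2 as fallback). Per stratum, a de Bruijn graph on
canonical $k$-mers ($k = 31$) with an abundance floor yields unitigs;
anchors (runs of $k_a = 17$-mers unique within the contig set, clustered
per diagonal band) locate contigs on long reads; contig adjacencies
supported by at least `min_support = 2` distinct reads become junctions of
simple paths, merged into super-contigs with read sequence filling the
junction gaps. Redundancy removal drops contigs contained in a longer one
at >= 95% identity over >= 95% of their own length; polishing substitutes
per-position pileup majorities (depth >= 3, majority >= 0.6).

## 2. Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `k_assembly` | 31 | bp | long enough to be unique in ~100 kbp genomes, short enough for 150 bp reads |
| `min_kmer_count` | `"auto"` | count | see §5; fixed floors fail at 300x vs 20x depth in one graph |
| `k_map` | 21 | bp | seed size of the mapper; ~4% of a long read's 21-mers survive 15% error, still hundreds of seeds |
| `k_anchor` | 17 | bp | anchor seeds must survive 15% error locally (survival $0.85^{17} \approx 6\%$) |
| `min_anchor_kmers` | 10 | count | rejects spurious single-seed anchors |
| `min_support` | 2 | reads | one chimeric long read cannot create a junction |
| `n_bins` | 11 | strata/sample | the stratum count of the modeled study design |
| `max_mismatch_frac` | 0.05 | fraction | short-read acceptance; 0.1% true error plus mapping slack |
| `min_overlap_frac` | 0.5 | fraction | end-clipping floor (§6) |
| cluster identity/coverage | 0.95 / 0.90 | fraction | the conventional non-redundant catalog cut-offs |
| `max_evalue`, `score_margin` | 1e-5, 0.90 | — | hit filter and top-score LCA margin |
| bin filter | >= 0.60 / <= 0.20 | fraction | completeness / contamination keep rule (strict discards) |
| `agreement` | 0.75 | fraction | majority-lineage rule |

## 3. What the generator emulates — and what it does not

The synthetic community provides: per-genome GC targets (TNF signal),
exact planted 120-bp single-copy markers shared across genomes (so
completeness and contamination are exactly computable, and so that
marker loci behave like the conserved genes that fragment real merged
assemblies), an exact shared repeat, two samples with independently
permuted geometric abundances, read-level origins for every simulated
read, and a small taxonomy with decoy sibling and cousin species.

It does **not** emulate: coding-biased base composition (ORFs arise from
random stop-codon spacing, so genes average ~180 bp rather than ~900 bp and
absolute catalog counts are meaningless), strain-level mixtures, chimeric
reads, GC-coverage bias, or empirical quality-score profiles. A green test
therefore establishes that the *machinery* behaves as specified on a
community whose combinatorial structure (repeats, shared loci, abundance
spread) matches the modeled design — not that real-data numbers would be
reproduced.

Error composition for long reads defaults to 1.5/9/4.5% sub/ins/del
(insertion-dominated, 15% total). The template-length scale is deflated by
the expected net indel expansion $(1 + p_{ins} - p_{del})$ so the realized
mean read length matches the configured target. Only the mean is
calibrated; reported per-sample long-read N50 values in the modeled design
are inconsistent with a unimodal 7.6-kbp-mean model and are not targets.

Hit tables fix their noise model a priori: with probability `decoy_rate`
the best hit is a random species; decoy e-values fall above the 1e-5
cut-off 60% of the time. Neighborhood hits decay with taxonomic distance
(same species 0.91–0.99 of the best bitscore, siblings 0.85–0.95, cousins
0.55–0.85), so same-genus hits straddle the 0.90 LCA margin and cousins
stay outside it; the expected genus-level loss is
`decoy_rate` × 0.4 (the below-cut-off decoys).

## 4. Depth stratification: two deliberate deviations

**Differential coverage.** With abundances permuted independently across
samples, the *summed* two-sample depth of distinct organisms collides
generically (two pairs of genomes in the standard seeded panel differ by
under 2%). A one-dimensional combined-depth stratification then mixes two
abundant organisms in one stratum by construction. The pipeline therefore
stratifies on the **per-sample depth vector**: geometric (or gap) binning
per sample, crossed across samples. Organisms collide only if they match
in *every* sample, which permutations of distinct geometric values cannot
do. The 1D combined scheme remains available
(`partition_scheme = "combined"`).

**Boundary placement.** Log-uniform boundaries between the observed depth
extremes are the natural default, but any fixed grid will sometimes fall
*inside* an organism's tight depth cluster and split its reads between two
strata — an artifact of the grid, not a property of the data. The
`"gap"` scheme places boundaries only at log-depth gaps of at least 0.1
decades (natural breaks), which cannot split a cluster and reduces exactly
to one-stratum-per-organism when organisms are 4-fold separated. On depth
ladders with uniform spacing (the powers-of-two check) it coincides with
the geometric scheme.

## 5. Numerical choices

- **Adaptive abundance floor.** A fixed `min_kmer_count = 2` is correct at
  30–60x but fails at 300x, where recurrent sequencing errors at one
  position exceed the floor and shred the graph with bubbles. The pipeline
  uses `clamp(median retained k-mer count / 8, 2, 10)` per read set, and
  caps per-stratum coverage at 60x (30x for long reads) by deterministic
  subsampling — the stand-in for the error correction and multi-k logic of
  production assemblers.
- **Junction projection.** Anchors stop wherever a k-mer is shared between
  contigs (markers, repeat edges), so cutting contigs at anchor ends would
  discard accurate contig tails and replace them with 15%-error read
  sequence. Junctions instead keep contig tails in full and take only the
  read segment between the *projected* contig ends; negative gaps trim the
  downstream contig. On error-free constructed cases the merged sequence
  equals the genome exactly, including when contigs overlap.
- **Depth-compatibility gate.** The stage-3 cross-stratum merge refuses
  junctions whose endpoint contigs differ by more than 3x depth in any
  sample (+1 pseudo-count): shared elements carry summed depth and would
  otherwise splice unrelated organisms together.
- **Auto bin count.** Features are standardized, the TNF block scaled by
  $1/\sqrt{136}$ and the depth block by `depth_weight`$/\sqrt{S}$, so
  composition and abundance contribute comparably; the dendrogram is cut at
  a fixed height 1.5 on this scale and the cut is kept only if the
  non-singleton clusters reach a mean silhouette of 0.25 (otherwise one
  bin). A plain best-silhouette $k$ under-splits whenever correct bins are
  single contigs, because singletons score zero.
- **Ties.** Mapper ties break by (contig id, offset, strand); unitigs are
  emitted in their lexicographically smaller orientation, sorted by
  (length desc, sequence); clustering processes (length desc, sequence)
  order. Everything is deterministic under a fixed seed, including
  subsampling (seeds derived from the configured seed, all below $2^{31}$).
- **Degenerate inputs.** Contigs shorter than the seed size index zero
  seeds; empty read sets assemble to empty output (with a warning when the
  abundance floor removes everything); all-zero depth is an error
  ("nothing mapped"); empty taxon sets and empty catalogs are errors.

## 6. End-clipping in the short-read mapper

The merged stage-1 assembly breaks exactly at loci shared between organisms
(conserved single-copy genes; in the simulator, the planted markers). A
full-containment mapper cannot place any read overlapping such a
breakpoint, so marker interiors lose their reads in *every* stratum and
bin completeness collapses. The mapper therefore scores placements over the
read–contig overlap (minimum half the read length), like the local mode of
production mappers; `start`/`end` are clipped, and the unclipped `offset`
is carried for polishing pileups.

## 7. Bin quality control and re-assembly

Completeness and contamination come from a census of near-exact marker
placements (>= 95% identity over the full 120 bp, tolerant of polishing
residue). Bins failing the keep rule are discarded; imperfect bins are
re-assembled from their own mapped reads: the read set of one bin is
essentially organism-pure, so loci fragmented by *inter*-organism graph
structure reassemble cleanly. Reads are also recruited from outside
contigs whose pairs link into the bin with >= 80% purity (stranded
fragments of the same organism that fell below the 2.5-kbp binning filter;
shared marker or repeat stubs link into many bins and fail the purity
requirement). A re-assembly replaces the bin only on a Pareto improvement
(contamination down without completeness loss, or completeness up without
contamination gain) — the literal "contamination decreases" rule would
accept re-assemblies that trade completeness for contamination.

The per-bin majority lineage projects the bin's gene assignments (followed
through their catalog cluster representatives into the merged-catalog LCA
calls) from species upward and reports the deepest rank at which one taxon
holds >= 75% of the classifications.

## 8. Known limitations

- Substitution-only polishing: indels inside long-read junction gaps
  persist; tests assert improvement, not perfection, and the bin
  re-assembly loop is the mechanism that restores such loci from short
  reads.
- The ORF scanner has no coding-potential model; every qualifying open
  reading frame is reported, so absolute gene counts are not comparable to
  model-based predictors.
- Nucleotide-space clustering only; protein-space catalogs are out of
  scope.
- The unmapped read pool is not re-introduced into stratum assemblies:
  experiments showed foreign breakpoint-flank k-mers above the abundance
  floor excise shared loci in every stratum — the pair-rescue rule plus
  end-clipping recovers those loci instead.
- Paired-end insert-size information is used for read routing and bin
  recruitment, not for scaffolding.
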