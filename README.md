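# depthmeta

Depth-partitioned hybrid metagenome assembly, gene catalogs and genome
binning — at desk scale, fully deterministic, and testable offline.

## The problem

Short-read metagenome assemblies of complex communities (for example the
anaerobic-digestion microbiomes of biogas fermenters) fragment at repeated
elements and at loci shared between organisms, which truncates predicted
genes and leaves genome bins scattered over hundreds of contigs. Error-prone
long reads (PacBio-like: ~7.6 kbp mean length, 10–15% indel-dominated error)
can span those repeats, but are too inaccurate to assemble rare organisms on
their own. A practical middle road is a **three-stage depth-based hybrid
strategy**:

1. **Stage 1** — assemble all short reads, map every short and long read
   back to the merged contigs, and divide contigs and reads into
   *phylotypes*: strata of similar sequencing depth (organism abundance).
   With two samples the stratification uses the per-sample depth vector
   (differential coverage).
2. **Stage 2** — re-assemble each phylotype's short reads separately
   (the graph is now mostly one organism, so repeats shared *between*
   organisms vanish), then anchor the phylotype's long reads on the contigs
   and merge contigs connected by ≥ 2 spanning reads into super-contigs.
3. **Stage 3** — pool all phylotypes, run one more anchoring/merge pass
   (joining contigs of one organism that landed in different strata, gated
   by depth-profile compatibility), remove contained redundant contigs
   (≥ 95% identity over ≥ 95% of the shorter contig) and polish with
   short-read pileup majorities.

Downstream, the package predicts ORFs (≥ 100 bp on contigs ≥ 500 bp),
builds non-redundant gene catalogs by greedy clustering (95% identity, 90%
coverage of the shorter sequence, CD-HIT-style), merges catalogs into a
reference catalog, assigns taxonomy by a bitscore-margin LCA over simulated
hit tables (e-value ≤ 1e-5, margin 0.90), bins contigs > 2.5 kbp by
canonical tetranucleotide frequency (136 classes) plus per-sample depth,
scores bins with single-copy markers (completeness = markers present / M;
contamination = excess copies / M), discards bins with < 60% completeness or
> 20% contamination, calls a 75%-agreement majority lineage per bin, and
re-assembles imperfect bins from their own mapped reads.

Everything runs against a ground-truthed **synthetic community generator**
(150-bp paired reads at 250-bp insert; log-normal long reads calibrated to a
7,604 bp mean with 1.5/9.0/4.5% sub/ins/del errors; planted markers, shared
repeats, and a small taxonomy), so every stage is checked against planted
truth without downloading anything.

## Worked example

```r
library(depthmeta)
res <- run_pipeline(demo_config(seed = 42), out_dir = "demo_run")
```

On the standard panel (5 genomes of 50–120 kbp, geometric abundances with
ratio 4 permuted independently across two samples, one shared 3-kbp repeat,
6 markers per genome; 101,684 read pairs + 1,003 long reads per sample) this
prints stage progress and leaves, among others:

```r
res$stats_short_only$n50   # 19192   (merged short-read assembly)
res$stats_hybrid$n50       # 71487   (depth-based hybrid assembly)
res$bin_scores
#   bin_id n_contigs completeness contamination
#   GB001          1          1.0             0      <- one genome each,
#   ...                                                 5 of 5 recovered
res$catalog_stats
#   label n_orfs total_length average_length pct_complete
#   HGC     1556       279303         179.50        98.01
#   POGC    1564       ...
#   PDGC    1623       ...                          99.56
#   RGC     1668       ...
```

Read it as: the hybrid route more than triples contig N50, yields a higher
complete-ORF percentage in its catalog, and recovers every sufficiently
covered genome as a single-contig bin with zero marker contamination —
the three directional claims the pipeline is built to demonstrate. The
phylotype stratification recovers genome-of-origin co-membership of reads
with a Rand index of 0.99 on this panel.

A command-line entry point covers the common operations:

```sh
inst/exec/depthmeta run --seed 42 --out-dir demo_run
inst/exec/depthmeta simulate --seed 7 --out-dir community/
inst/exec/depthmeta stats --contigs demo_run/contigs_depth_hybrid.fasta
inst/exec/depthmeta genes --contigs demo_run/contigs_depth_hybrid.fasta --out genes.fasta
inst/exec/depthmeta qc --in community/long_s1.fastq --out kept.fastq
```

## Layout

- `R/`, `src/` — implementation (R API over an Rcpp k-mer core: seed index,
  clipped short-read mapper, banded long-read mapper, de Bruijn unitig
  assembler, anchorer, greedy containment clusterer, pileup polisher, TNF).
- `vignettes/depthmeta-methods.Rmd` — the model, parameter and design notes.
- `tests/testthat/` — unit, property and acceptance suites.
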