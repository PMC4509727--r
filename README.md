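# dualpollen

Identifying the plant species in a mixed pollen sample — a bee's foraging
record, a honey sample, an airborne pollen trap — by meta-barcoding: a
short marker region (ITS2 for plants) is amplified from every grain in
the sample, sequenced in bulk, and each read is assigned a taxonomy.
`dualpollen` implements the complete analysis side of a *dual-indexed*
version of this workflow, in which every sample carries a unique
combination of a forward and a reverse 8-nt index built directly into the
amplification oligos, so that hundreds of samples (16 × 24 indices = 384
combinations) share a single Illumina MiSeq run with no separate library
preparation.

The package is aimed at pollination ecologists and molecular ecologists
who want to run, audit, or simulate this workflow end to end in R:

* **Oligo scaffold & QC** — assemble
  `adapter | index(8) | pad(10) | linker(2) | primer` amplification
  oligos, derive the custom Read1/Read2/Index sequencing primers
  (`index primer = revcomp(Read2)`), and compute length, GC, melting
  temperature (Wallace, Marmur–Doty, nearest-neighbor) and longest
  self/cross dimer.
* **Demultiplexing** — exact (or bounded-Hamming) dual-index matching
  with conservative ambiguity handling.
* **Read preparation** — overlap-based paired-end merging with a
  consensus quality model, and the standard `<150 nt / <Q20 / ambiguous
  base` filter with exact boundary semantics.
* **Reference databases** — seven-rank lineages
  (kingdom…species) attached via a taxonomy tree, written/read in the
  UTAX-annotated FASTA and RDP training-file dialects, plus checklist
  coverage reports.
* **Classification** — a naive Bayes k-mer classifier with bootstrap
  confidence. For a read's distinct k-mers *w* and a candidate leaf with
  *M* training sequences, the leaf conditional is
  `P(w|leaf) = (m(w) + P(w)) / (M + 1)` with word prior
  `P(w) = (n(w) + 0.5) / (N + 1)`; the winner maximizes
  `Σ log P(w|leaf)`, and confidence at each rank is the agreement rate of
  100 bootstrap trials on `⌊W/8⌋`-word subsamples.
* **Community matrix** — per-read assignments aggregated into a
  taxa × samples count table with lineage side-table, the strict 0.1%
  per-sample rare-taxon filter, the 2,000-read minimum-depth filter,
  relative abundances and rank summaries; exportable to TSV or phyloseq.
* **Rarefaction** — analytic species-accumulation curves
  `E[S(d)] = Σᵢ (1 − C(N−Nᵢ, d)/C(N, d))` via log-gamma arithmetic,
  a seeded Monte-Carlo alternative, and saturation-depth detection.
* **Simulator** — hierarchically structured mock reference databases,
  log-normally skewed communities and dual-indexed paired-read runs with
  per-read ground truth, so the entire pipeline is testable with no
  external data.

## Worked example

Oligo QC for the bundled ITS2 scaffold:

```r
library(dualpollen)
qc_report(its2_scaffold())
#> Read-primer region QC
#>   read1: 32 nt, GC 50.0%, Tm 64.39 C, self-dimer 4 bp
#>   read2: 32 nt, GC 50.0%, Tm 64.39 C, self-dimer 4 bp
#>   cross-dimer read1 x read2: 4 bp
```

Both read-primer regions are 32 nt at exactly 50% GC with a Marmur–Doty
melting temperature of 64.4 °C (the ~65 °C needed for the custom
sequencing primers to bind), and the worst dimer either region can form
is a 4-bp duplex — too short to matter in PCR.

A simulated two-sample run through the whole pipeline:

```r
p <- sim_params(n_samples = 2, reads_per_sample = 2500, rng_seed = 1)
sim <- simulate_default_run(p)
res <- pollen_pipeline(sim$run, db = sim$db)

res$demux
#> Demultiplexed 5000 read pairs into 2 samples (0 undetermined, 0.0%)
res$prep
#>   sample_id  raw merged kept merge_rate keep_rate
#> 1  sample01 2500   2495 2495     0.9980         1
#> 2  sample02 2500   2496 2496     0.9984         1
res$community
#> CommunityMatrix: 31 taxa x 2 samples, 4991 reads
```

Every read pair demultiplexes to its true sample (index reads are
error-free by default); ~99.8% of pairs merge (the few failures are
pairs whose 1%-error reads disagree too much inside a short overlap),
and all merged reads pass the quality filter. After classification and
the 0.1% rare-taxon filter, 31 taxa remain across the two samples.

```r
rank_summary(res$community, "genus", top_n = 5)
#>       name  share
#> 1 o1_f2_g5 0.1831
#> 2 o1_f1_g5 0.1338
#> 3 o2_f2_g4 0.0958
#> 4 o1_f1_g2 0.0844
#> 5 o1_f1_g1 0.0717
#> 6    other 0.4312

curves <- accumulation_curves(res$community)
vapply(curves, saturation_depth, integer(1))
#> sample01 sample02
#>      431      228
```

The genus table shows the skewed (log-normal) community the simulator
drew, recovered from the reads; the accumulation curves saturate after a
few hundred reads — these 20-species mock communities are far simpler
than real pollen samples, which typically need 2,000–3,000 quality reads
to plateau. Comparing the recovered per-sample relative abundances with
the simulator's ground truth gives a Pearson correlation of 1.00 (to 4
decimals) for each sample at this error rate.

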