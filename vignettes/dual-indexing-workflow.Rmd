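---
title: "Dual-indexed pollen meta-barcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-indexed pollen meta-barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualpollen)
```

`dualpollen` implements a complete analysis workflow for highly
multiplexed amplicon meta-barcoding of mixed pollen samples: from the
design and QC of dual-indexed amplification oligos, through
demultiplexing, read merging and filtering, naive Bayes taxonomic
classification, down to the community matrix and species-accumulation
analysis. This vignette explains the models behind each stage, the
tunable parameters and their defaults, the numerical choices, and what
the bundled simulator does and does not emulate.

## The oligo scaffold

Samples are labelled during PCR by amplification oligos of the form

```
adapter | 8-nt index | 10-nt pad | 2-nt linker | amplifying primer
```

Each sample receives a unique combination of a forward and a reverse
index, so a plate of 16 forward and 24 reverse index oligos labels up to
`16 * 24 = 384` samples in a single run. Because the custom pad and
linker sit between the index and the marker primer, the sequencing
primers are not the standard Illumina ones: Read1 is the forward
`pad + linker + primer` region, Read2 the reverse equivalent, and the
index-read primer is the reverse complement of Read2.
`derive_sequencing_primers()` encodes exactly that construction, and the
identity `revcomp(index_primer) == read2` is a tested invariant.

The pad/linker choice matters only through the melting temperature of the
read-primer region, which must be near 65 °C for the custom primers to
bind during sequencing. `qc_report()` computes per region: length, GC
fraction, melting temperature, and the longest possible antiparallel
Watson–Crick duplex (self- and cross-dimer). For the bundled ITS2
scaffold (`its2_scaffold()`) both regions are 32 nt at exactly 50% GC
with a maximum self/cross dimer of 4 bp.

**Melting temperature models.** Published primer Tm values rarely state
the formula used, so three standard models are provided:

| model | formula | intended range |
|---|---|---|
| `wallace` | 2(A+T) + 4(G+C) | ≤ 14 nt (warns above) |
| `marmur_doty` | 64.9 + 41 (GC − 16.4)/L | ~14–70 nt, **default** |
| `nearest_neighbor` | unified NN thermodynamics (SantaLucia 1998) with terminal initiation and 16.6 log10[Na+] salt correction | any |

On the 32-nt ITS2 read regions Marmur–Doty gives 64.39 °C, a plausible
match to the conventionally cited ~65 °C; no model choice reproduces a
published value to the decimal without knowing the original tool, which
is why the package treats Tm as a band (±2 °C) rather than a point in its
own acceptance checks.

**Dimer definition.** "Longest dimer complement" is read as the longest
contiguous antiparallel Watson–Crick complementary stretch, i.e. the
longest common substring between one sequence and the reverse complement
of the other (G·T wobble not counted). This is the simplest definition
consistent with observed 4-bp dimers on the ITS2 regions, and it is
verified in the tests against a brute-force all-substring-pairs oracle.

## Demultiplexing

`demultiplex()` assigns a read pair to a sample iff both index reads are
within `max_mismatch` Hamming distance of that sample's index pair and
the assignment is unique. The default is `max_mismatch = 0` (perfect
matches only), matching on-instrument demultiplexing behaviour. Under
relaxed matching, a read within distance of two different samples is
*always* sent to `undetermined`, never to the nearest match — index
hopping and near-collisions should surface as losses, not as wrong
assignments. `N` bases in index reads count as mismatches. The counts
always satisfy the conservation identity
`sum(per-sample) + undetermined == total`.

Index orientation dialects differ between instrument chemistries; the
sample sheet stores indices as-sequenced, and the file-level wrapper
`demux_fastq()` accepts either separate I1/I2 FASTQ files or
Casava-style `<i1>+<i2>` header tokens (auto-detected).

## Paired-end merging and quality filtering

`merge_pair()` reverse-complements the reverse read and scans **all**
overlap lengths `L ≥ min_overlap`, choosing the candidate with the
smallest mismatch fraction (ties towards the longer overlap) and
accepting it iff that fraction is at most `max_mismatch_frac`. Defaults
are `min_overlap = 6` and `max_mismatch_frac = 0.08`, the conventional
defaults of paired-end joining tools. Failure reasons are
`no_overlap` (no candidate of at least `min_overlap` exists) and
`too_many_mismatches` (best candidate over budget).

Consensus rule inside the overlap: agreeing bases keep the higher of the
two qualities; disagreeing positions keep the higher-quality base with
quality `|q1 − q2|`, floored at 2 and capped at Q41 so merged qualities
stay within the printable Phred+33 range.

`quality_filter()` implements the standard post-merge filter with
defaults `min_len = 150` nt, `min_mean_q = 20` and `max_ambiguous = 0`,
checked in that order (the first failing rule is the reported reason),
with strict boundaries: a 149-nt read is discarded, a 150-nt read kept; a
mean of Q19.99 fails, Q20.00 passes. "Quality below Q20" is interpreted
as *mean* Phred below 20 over the merged read — the most literal reading
when no exact filter invocation is recorded; per-base or expected-error
variants would discard different (generally more) reads.

## Reference databases and lineages

All taxonomy in the package lives on seven fixed ranks
(`r paste(SEVEN_RANKS, collapse = ", ")`). `assign_lineages()` expands a
sequence-id → taxon-id mapping through a taxonomy tree, keeping only
nodes whose rank is one of the seven levels (intermediate ranks such as
subfamily or tribe are skipped; unranked internal nodes ignored).
Missing ranks are filled with `unclassified_<nearest named ancestor>`;
the kingdom must always be named, and normalization is idempotent. A
named rank below a gap keeps its name — the placeholder refers upward to
the closest real name, which matches how partial NCBI lineages are
conventionally flattened for classifier training.

Two serialization dialects are provided, and both round-trip:

* **UTAX-annotated FASTA** — headers
  `>seq_id;tax=d:K,p:P,c:C,o:O,f:F,g:G,s:S;`.
* **RDP training files** — a star-delimited taxonomy file
  (`taxid*name*parent_taxid*depth*rank`, one node per distinct lineage
  prefix plus a Root node) and a training FASTA with
  `>seq_id<TAB>Root;K;P;...;S` headers.

Since `; , : *` and tab are dialect delimiters, they are sanitized to
`_` in names on writing. Database construction deliberately does not
de-duplicate multiple sequences per species: keeping all records lets the
classifier's per-leaf word counts reflect within-species variation.

`coverage_report()` measures checklist coverage (e.g. against a regional
flora) by case-insensitive exact name match at a chosen rank; a genus
counts as covered if any of its species is present.

## The naive Bayes k-mer classifier

The classifier follows the classical RDP design. Training on `N`
sequences, with `n(w)` of them containing word `w` (distinct `k`-mers,
presence not multiplicity):

* word prior: `P(w) = (n(w) + 0.5) / (N + 1)`
* leaf conditional, for a leaf with `M` sequences of which `m(w)` contain
  `w`: `P(w | leaf) = (m(w) + P(w)) / (M + 1)`

A read is scored against every leaf by the sum of
`log P(w | leaf)` over its distinct words; words never seen in training
contribute their prior mass `0.5/(N + 1)` through the same formula. The
winning leaf maximizes the score, with ties broken towards the
lexicographically smallest leaf so results are deterministic. Leaves are
the species-level labels of the training lineages.

**Bootstrap confidence.** Each of `n_bootstrap = 100` trials draws
`floor(W/8)` of the read's `W` distinct words with replacement and
records the winning leaf; the confidence at a rank is the fraction of
trials agreeing with the full-word winner at that rank. Raw bootstrap
fractions need not be monotone down the ranks, so a cumulative-minimum
pass from kingdom to species enforces the natural non-increasing shape
before reporting.

**Cutoffs.** `apply_cutoff()` truncates ranks whose confidence falls
below `min_confidence` (default 0.80, the classifier's canonical value)
to `unclassified_<deepest surviving named rank>`. A second, score-based
floor handles reads that resemble nothing in the database: if the
winner's *mean per-word log-likelihood* (`raw_score`) falls below
`min_raw_score`, the read is truncated to kingdom. This mirrors the
raw-score cutoffs used by other assignment tools, but on this model's
natural-log scale — the default of −4 is **not** numerically
interchangeable with score cutoffs of other software; it sits far below
the typical score of a read with a close reference (around −0.5 at 1%
sequencing error) and rejects only reads scoring no better than noise
(around −5 against an unrelated leaf in a small database).

**Determinism and order invariance.** `classify_sample()` derives an
independent RNG seed for every read from the master seed and a
polynomial hash of the read id. Two consequences: identical seeds give
byte-identical tables, and permuting the input permutes the output rows
without changing any value.

**Numerics.** Words are encoded as base-4 integers; for `k ≤ 10` a
direct lookup table of length `4^k` maps read words to model rows, and
bootstrap trial scores are accumulated with `rowsum()` on the gathered
log-probability rows — the whole classifier is vectorized R with no
per-word interpreted loop. `k` is capped at 12 to keep codes exact in
doubles and memory bounded.

## Community matrix and filters

`aggregate_assignments()` keys taxa by their **full seven-rank lineage**
(not the bare name, avoiding homonym collisions) and labels rows by the
deepest named rank; two distinct lineages sharing a label is an error
rather than a silent merge. Column sums equal per-sample assigned read
counts — aggregation conserves reads.

Two filters follow, in this default order:

1. `filter_rare()` — in each sample, counts strictly below
   `rare_frac = 0.001` (0.1%) of the sample total are zeroed; a taxon at
   exactly 0.1% is kept. The rule is evaluated in a **single pass
   against the original column totals**: zeroing changes column sums, so
   iterating to a fixed point would silently tighten the threshold.
2. `drop_low_depth_samples()` — samples with fewer than
   `min_sample_reads = 2000` assigned reads are removed (and reported);
   2,000 is the conventional minimum saturation depth for pollen
   communities, and a sample at exactly 2,000 is kept.

Whether the rare-taxon filter runs before or after the depth filter is
not standardized; both orders are available, and the pipeline default
(rare filter first) means the depth filter judges samples on the reads
that survive taxon-level cleaning.

Abundances should be interpreted only relatively;
`relative_abundance()` divides by library size, and `rank_summary()`
produces most-abundant-taxon tables at any rank with the tail folded into
`"other"` (shares including `"other"` sum to 1).

## Rarefaction

For a sample with total `N` reads and per-taxon counts `N_i`, the
expected richness of a uniform subsample of `d` reads without
replacement is

```
E[S(d)] = sum_i ( 1 - C(N - N_i, d) / C(N, d) )
```

with `C(a, b) = 0` for `a < b`. `rarefy_analytic()` evaluates the
binomial ratios with log-gamma arithmetic (`lchoose`), which is within
1e-12 of exact subset enumeration on toy inputs and overflow-free at any
depth. `rarefy_montecarlo()` estimates the same curve by averaging over
seeded random permutations; because each replicate counts cumulative
distinct taxa along one permutation, every replicate's curve is exactly
monotone, and the two modes agree within Monte-Carlo error (tested at 3
standard errors). Both are provided because published accumulation
curves may come from either; the analytic mode is the package default.

`accumulation_curves()` computes per-sample curves from a community
matrix, applying the 0.1% rare-taxon rule first by default (saturation
should reflect real community members, not singleton noise — and the
filter provably never raises a curve). The default depth grid is 50
log-spaced points capped at 5,000 reads, the conventional plotting range
for pollen samples, and `saturation_depth()` reports the first depth
reaching 99% of the curve's final richness.

## The simulator

`simulate_refdb()` grows a reference set as a four-level tree: one root
amplicon (uniform ACGT, length drawn from 350–480 nt — the sequenced
ITS2 fragment range) is copied down order → family → genus → species,
applying a fixed substitution fraction at each descent
(defaults 0.20 / 0.10 / 0.05 / 0.02). This gives the hierarchical
similarity structure a classifier actually faces: congeneric species are
~4% apart while genera differ by ≥10%.

`simulate_community()` draws species without replacement and assigns
log-normal abundances (`sigma = 1` by default, giving the skewed
few-dominant/many-rare shape typical of pollen loads), converted to
integer counts by largest-remainder rounding so truth counts sum exactly
to the sample depth. `simulate_run()` then emits 2 × 250 nt read pairs
from each read's true reference (forward = first 250 nt, reverse =
reverse complement of the last 250 nt), with per-base substitution errors
(default 1%), linearly decaying quality (Q38 → Q25, so the mean sits
well above the Q20 filter and filter losses come from injected defects,
not from the default profile), and index reads carrying the sample's
index pair (error-free by default; perturbable). All randomness flows
from one seed and reruns are bit-identical.

Default scale of the standard run: 8 samples × 5,000 read pairs over a
40-species (20-genus) reference — small enough that the complete
simulate–demultiplex–merge–classify–aggregate cycle runs in about two
minutes on one core, large enough that per-sample abundance estimates
are statistically meaningful.

**What the simulator does *not* emulate** — and hence what passing tests
do not show about real data: indels (substitution-only errors keep
overlap lengths exact so the merge oracle stays analytic), chimeras, PCR
abundance bias, realistic MiSeq error profiles (quality-dependent,
position-correlated), length variation between taxa within one run, and
reference databases with missing or mislabelled lineages. Recovery
statistics on simulated runs are therefore upper bounds on real-data
performance.

## Known limitations

* The classifier's `raw_score` scale is model-specific; cutoffs cannot
  be transplanted from other tools without recalibration.
* The merge step is overlap-only (no indel-tolerant alignment) and does
  not trim primers.
* Checklist coverage uses exact name matching; synonyms and spelling
  variants count as misses.
* Analytic rarefaction assumes exchangeable reads within a sample; it
  cannot correct for PCR duplicates.

## A minimal end-to-end run

```{r example, eval = FALSE}
p <- sim_params(n_samples = 2, reads_per_sample = 500, rng_seed = 1)
sim <- simulate_default_run(p)
res <- pollen_pipeline(sim$run, db = sim$db,
                       aparams = aggregate_params(min_sample_reads = 100))
res$community
rank_summary(res$community, "family")
curves <- accumulation_curves(res$community)
saturation_depth(curves[[1]])
```
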