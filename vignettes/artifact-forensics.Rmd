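---
title: "Artifact forensics for de novo mutation call sets"
author: "mutbleed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact forensics for de novo mutation call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutbleed)
```

## The problem

Calling de novo (somatic or germline) mutations from short-read resequencing
is dominated not by the mutations themselves but by errors: the per-base
sequencing error rate is orders of magnitude above the mutation rate, and
read mis-mapping adds correlated false calls on top. Two error classes leave
characteristic fingerprints in a call set:

* **Homopolymer bleed.** Illumina-type chemistry mis-reads bases within or
  near homopolymeric runs as the run base, so that `AAAGAAA` is read as
  `AAAAAAA`, or `AAAAC` as `AAAAA`. The resulting false substitutions and
  single-base indels (i) carry the run base as the alternate allele,
  (ii) sit within a few bp of an A/T run, (iii) are usually supported by
  reads of only one strand, (iv) co-occur in the same read
  (`AAAAACACACA` read as a pure A run yields three calls at once),
  (v) occur at a per-bp rate that grows log-linearly with run length, and
  (vi) decay in rate with distance from the run end.
* **Mis-mapping.** Reads placed at the wrong locus produce tightly
  clustered calls (two or more calls within ~10 bp), calls recurring across
  implausibly many samples, and an excess of calls in repeat-rich
  centromeric regions.

Left in a call set, these artifacts distort every downstream summary:
the intron:CDS mutation-rate ratio inflates (introns and intergenic DNA
carry far more error-prone A/T runs than coding sequence), the 96-class
dinucleotide mutation spectrum acquires an excess of events whose resolved
dinucleotide is AA or TT (a neighbouring base "bleeding" into an A/T run),
the equilibrium dinucleotide content implied by the mutation matrix
over-predicts AA/TT, and the mutation-rate profile around transcription
start and termination sites (TSS/TTS) develops dips and shoulders that
mimic biological protection of gene bodies. `mutbleed` implements detectors
for each fingerprint, the downstream summaries, and a synthetic-data
generator with a ground-truth ledger so that every detector can be
validated by parameter recovery.

## The detectors

**Conventional filter and concordance.** `filterPolicy()` encodes the
classical rules: at least `min_support_per_strand` (default 2) supporting
reads on each strand, `min_total_support` (default 4) in total, and the
identical site shared by at most `max_samples_sharing` (default 10)
samples. Unknown support fails positive thresholds: absence of evidence is
not evidence. `classifyConcordance()` partitions a query set against a
reference into concordant (identical call present and policy-passing in
the reference), uncallable (the query call's own evidence fails the
policy), and discordant-but-callable; the non-concordant calls form the
low-quality (LQ) set.

**Homopolymer bleed.** `findRuns()` indexes all maximal single-base runs
of at least `min_run_length` (default 4) bp. `classifyBleed()` flags a
call as bleed-type when an A/T run lies within `proximity_window`
(default 5) bp — distance measured from the run boundary, with distance 0
meaning inside the run or touching its boundary base — and the call's
bleed allele (alternate allele of an SNV; inserted/deleted base of a
single-base indel) equals the run base. Requiring allele identity is the
conservative reading of the bleed mechanism; a
`require_allele_match = FALSE` relaxation is provided. Ties between
candidate runs go to the smaller distance, then the lower run coordinate.
`bleedClusters()` flags co-read groups among the remaining nearby calls
(same run, same alt, within the window of each other);
`runLengthRegression()` fits unweighted OLS of log10(calls per bp of
homopolymeric sequence at run length L) on L at the bin level, dropping
and reporting zero-call bins (df = bins − 2); `distanceDecay()` tabulates
calls per integer distance and reports a Spearman monotonicity check.

**Mis-mapping.** `findClusters()` chains calls whose consecutive spacing
is at most `window` (default 10) bp; chains of two or more calls are
clusters, across samples by default because mis-mapping afflicts a locus,
not a sample (`per_sample = TRUE` is available). `findRecurrent()` flags
sites carried by strictly more than `sample_threshold` (default 10)
distinct samples. `clusterReport()` combines both with the centromeric
call fraction and also reports the clustered percentage after excluding
recurrent-site calls, since the two categories overlap.

**Spectra.** `diSpectrum()` classifies each SNV into the 96 dinucleotide
mutation classes — source dinucleotide (16) × mutated position within it
(first/second) × resulting base (3). A single flanking base does not
determine the class: with only the 3′ flank every event is a
"first-position" mutation, half the classes are structurally empty, the
χ² comparison cannot reach df = 95, and the 16×16 dinucleotide chain
decomposes into disconnected components with no equilibrium. The default
`flank = "both"` therefore counts each SNV once through its 5′ and once
through its 3′ flanking dinucleotide, mirroring the overlapping-window
convention used for the genomic context counts (every base belongs to two
dinucleotides); `"3prime"` and `"5prime"` single-flank modes are provided
for sensitivity analysis. This representational choice is the largest
open decision in the package and is deliberately exposed. Normalized
rates are counts per source-dinucleotide occurrence; `shareAATT()` is the
percentage of relative normalized rates whose resolved dinucleotide is AA
or TT; `compareSpectra()` is a two-sample χ² on the 2×96 table (zero-total
classes pooled out and reported) with ranked standardized residuals.

**Equilibrium content.** `buildRateMatrix()` lays the 96 normalized rates
into a continuous-time 16×16 rate matrix (structural zeros between
dinucleotides differing at both positions; diagonal = −row sum). A
discrete per-generation transition formulation differs only in time
scaling and has the same stationary vector. `stationaryDistribution()`
checks irreducibility of the positive-rate graph, solves π·Q = 0 with
Σπ = 1 by a direct linear solve, and cross-checks internally against
power iteration (tolerance 1e−6; the test suite requires 1e−8 agreement
against an independent oracle). `equilibriumContent()` compares predicted
equilibrium frequencies with observed intergenic dinucleotide
frequencies, on the raw scale because several states can be rare in small
synthetic genomes. The AA/TT outlier test fits the regression excluding
the designated states, computes each state's externally studentized
prediction residual, and combines them by the maximum absolute residual
with a Šidák correction for the number of designated states. This exact
construction is the package's own; published analyses of this kind state
single p-values without naming the test, so those values are not
reproduction targets.

**Region rates and metagenes.** `regionRates()` partitions the genome by
the precedence CDS > intron > TE > centromere > intergenic (overlaps are
real: TEs live in intergenic space, centromeres contain TEs) and assigns
each call to exactly one class; the precedence is configurable because no
canonical order exists. `pairedRateTest()` is a paired t-test across the
96 normalized per-class rates of two regions, dropping undefined classes
and adjusting df; both the mean per-class ratio and the ratio of means
are reported because the two summaries differ and either may be wanted.
`geneClassRates()` tests heterogeneity between the four gene classes
(essential, morphological, cellular/biochemical, environmental) by a χ²
goodness of fit of per-class call counts against bp-proportional
expectations (df = 3), with per-gene rates giving class s.e.m. and a
validity flag when any expected count drops below 5.
`metageneProfile()` bins events by strand-oriented offset from TSS or TTS
(window 3,000 bp, bin 100 bp by default — the axis conventions of
published figures being unavailable, these are package choices, and
profiles are compared internally, never against a printed figure);
density is events per bp per anchored gene, so density × bin × anchors
recovers the in-window event count exactly. `simulateHomopolymerErrors()`
drops errors by the bleed placement model onto the run index so the
artifact-induced TSS/TTS profile can be reproduced from the genome alone,
and `teMetagene()` profiles TE bp density with the same orientation
rules.

## The synthetic-data generator

`simulationConfig()` fixes the study conditions; `simulateCallSets()`
produces a genome, annotation, truth set, observed set and a ledger
tagging every call as `true_mutation`, `bleed_error`, `cluster_error` or
`recurrent_error`, with ledger counts equal to the configured counts
exactly (collisions are redrawn) and byte-identical output under a fixed
seed. One master seed drives four named substreams (genome, truth, bleed,
cluster) so stages can be regenerated independently.

Defaults describe a 5 Mb genome (5 chromosomes of 1 Mb) at 36% GC —
Arabidopsis-like composition — with 1,000 genes of 2 kb (three 400 bp
exons; exons are CDS; UTRs are not modelled), a centred centromere
covering 10% of each chromosome, and TE blocks of 500 bp tiling 20% of
intergenic space. The observed call set mirrors the composition of a
heavily contaminated ~4.4k-call putative mutation set: 400 true mutations,
2,400 bleed errors, 600 clusters of 2 calls (40% centromeric) and 32
recurrent sites in 12 samples each, across 100 samples.

Specific modelling choices:

* **Background sequence is run-free.** Natural random sequence contains an
  A/T run of length ≥ 4 roughly every 200 bp, which would swamp any
  configured enrichment. The generator caps background runs at
  `min_run_length − 1` and then seeds maximal runs (lengths uniform on
  4–12, nine distinct lengths, enough bins for the run-length regression)
  at a per-bp density `homopolymer_enrichment`-fold (default 5) higher in
  introns+intergenic space than in CDS. Every indexed run is therefore a
  seeded run with known length, and run-density enrichment is exactly
  recoverable. Seeded runs keep ≥ 15 bp apart so that bleed distances are
  unambiguous. A minimum run length of 4 is a package choice; the
  literature rarely states one.
* **True mutations.** Site weights are 1 everywhere; C and G in CpG
  context carry weight (m+2)/3 and mutate to the transition with
  probability m/(m+2), making the CpG>TpG rate exactly m-fold (default
  10, the scale expected from methylated-CpG hyperinstability) that of any
  single non-CpG substitution and giving a closed-form expected CpG>TpG
  call share that the tests invert. TE bp carry a further ×4 (the
  methylation-driven TE rate excess), essential-gene bp ×1 by default
  (rate homogeneity between gene classes is the null the package is built
  to test). All truth calls have ≥ 2 reads per strand.
* **Bleed errors.** A run is chosen with probability ∝ L·10^(slope·L)
  (slope default 0.27), which makes the per-bp rate at length L
  ∝ 10^(slope·L) — the estimand of the run-length regression — rather
  than the per-run rate; then a distance d ∈ [0, 5] from the run boundary
  with probability ∝ exp(−d/scale) (scale default 1 bp; the decay family
  is a package choice, only monotone decay being established). 15% of
  errors are single-base indels of the run base inside the run; 25% spawn
  2–3 same-read co-errors 2 bp apart (same sample, same strand pattern);
  80% have zero support on one strand.
* **Mis-mapping.** Clusters are pairs spaced uniformly within 10 bp,
  placed inside centromeres with probability 0.4 and strictly outside
  otherwise, so the centromeric fraction is exactly recoverable.
  Recurrent sites are single positions carried by 12 > 10 samples. Both
  classes get strand-balanced support: they pass per-call filters and are
  caught only by the cluster/recurrence screens, as in real data.

What the generator does **not** emulate: read-level data (no FASTQ, no
quality strings, no coverage variation), machine-specific chemistry (the
AT-vs-GC bleed bias is fixed to AT; the package only measures the
asymmetry), UTRs and alternative splicing, natural homopolymers beyond
the seeded ones, selection, and GC-biased gene conversion. Passing tests
therefore demonstrate that the detectors recover what the generative
model puts in — parameter recovery, not biological validity on real data.

## Numerical choices and degenerate inputs

Internal coordinates are 1-based closed throughout, the GRanges
convention; GFF3/VCF conversion is handled at the file boundary by
rtracklayer and the VCF reader/writer. Strand support travels in VCF
through two FORMAT integer fields (`FAD`/`RAD`, forward/reverse
alt-supporting reads); absent fields read back as unknown (NA), which
positive filter thresholds treat as failing. Indels are anchored at the
base preceding the event (VCF convention) and inter-call distances are
measured between anchor positions. Duplicate calls collapse with a
warning at construction. Zero-rate regression bins are dropped, not
pseudocounted, and the dropped count is reported. The paired t-test
returns t = 0, p = 1 on identical vectors rather than NaN. The stationary
solve refuses reducible matrices and names the reachable component.
`compareSpectra()` errors on empty spectra; `cpgTpgRatio()` errors on
CG-free regions; `regionFraction()` errors when the feature class is
absent.

Problem sizes in the shipped tests are chosen to keep the default suite
fast while leaving recovery statistics well-powered: module tests run on
2 × 250 kb genomes with a ~1.9k-call composition, and the acceptance
checks use the full 5 Mb study conditions with 20 replicate error draws
(20,000 bleed errors each) for the slope, 20,000 truth draws for the
multiplier recoveries, and 20 replicates each for the gene-class size and
power checks.

## Known limitations

* The 96-class flank convention ("both", the default) is a modelling
  decision, not an established standard; single-flank spectra are
  supported but cannot feed the equilibrium analysis.
* "Uncallable" is judged from the query call's own evidence; a real
  reanalysis would also use reference coverage, which a call set alone
  does not carry.
* The AA/TT outlier test's exact form (joint max-residual with Šidák) is
  a reconstruction; alternative reasonable tests would give different
  p-values on the same data.
* Cluster detection treats co-located calls from different samples at the
  same position as clustered; recurrent sites therefore also appear
  clustered unless the exclusive tally is used.
* The generator's artifact classes are phenomenological. Recovering the
  configured parameters shows internal consistency of detector and
  generator; it cannot certify detector performance on error modes the
  generator lacks.
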