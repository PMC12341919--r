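---
title: "Dual-reference somatic SNV detection in highly heterozygous genomes"
author: "dualsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-reference somatic SNV detection in highly heterozygous genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsom)
library(data.table)
```

## The problem

Somatic mutations in long-lived plants are mostly *layer-specific*: the
shoot apical meristem maintains clonally segregated cell layers (L1 →
epidermis, L2 → photosynthetic and germ tissue, L3 → ground tissue), and a
mutation fixed in one layer is carried only by that layer's descendants.
In whole-tissue sequencing the variant allele frequency (VAF) of even a
*fixed* layer mutation is therefore well below 0.5: it is
`layer_dna_fraction × cell_fraction / 2` (one haplotype, one layer, a
fraction of that layer's cells).

Calling such low-VAF variants is hard in highly heterozygous genomes
(here ~1.6% heterozygosity, typical of outcrossing trees such as oaks):

* Against a **haploid** assembly, reads from the divergent haplotype
  accumulate mismatches or fail to map at all, inflating false positives
  and negatives.
* Against a **diploid** (phased) assembly, reads from
  haplotype-identical regions map equally well to both copies, get MAPQ
  0, and per-haplotype coverage is halved — low-frequency variants
  drown.

`dualsom` implements a dual-reference strategy: align every read against
both assemblies and assign it to exactly one of them, then call variants
per reference mode with a control-masked stringent filter cascade, and
merge the two call sets.

## Read assignment

For each read (each mate separately), with a primary alignment record
against each reference:

1. if the alignment scores (`AS`, BWA convention: +1 per match, −4 per
   mismatch) differ, the read goes to the reference with the higher
   score;
2. on a score tie, to the reference with the higher MAPQ (255, the SAM
   "unavailable" value, loses any tie against a numeric MAPQ);
3. on a full tie, to the diploid assembly.

A read mapped against only one reference is assigned there. Clipped
reads (CIGAR `S`/`H`) are removed after assignment — from both outputs,
since an alignment distrusted against one reference is distrusted
against both — and duplicate-flagged reads are excluded from pileups.
Assignment is per read, not per fragment, so mates may be split across
references; a fragment-level variant would be a different design and is
intentionally not implemented.

The structural consequence, visible in every simulation: reads spanning
at least one heterozygous site are distinguishable between haplotypes
(diploid MAPQ 60) and end up in the diploid set, while reads from
haplotype-identical spans go to the haploid set via the MAPQ rule. At
1.6% heterozygosity and 150 bp reads about 91% of reads span a het site,
so the diploid mode carries most of the signal and the haploid mode
covers the homozygous remainder.

## Pileup counting

A bam-readcount-style engine (`pileup_table()`, `count_site()`,
`depth_track()`) aggregates, per site and allele: read counts, forward
and reverse strand counts, mean base quality, and the mean per-read
mismatch fraction (`NM /` aligned `M` length — the candidate variant
base is *not* subtracted; the differential filter below absorbs its
1/read-length contribution, which is at most 0.01 for reads of 100 bp or
longer). Reads with an insertion or deletion touching a position
(insertions anchored to the base on their left, deletions spanning their
deleted bases) count as indel evidence and contribute no base allele at
the deleted positions. Overlapping mates count twice, mirroring
bam-readcount's default; the study design never relies on within-pair
double counting because calls need both-strand support.

## Somatic calling

Calling is asymmetric between a *mutant* and a *control* sample (two
branches of the same tree, each serving as the other's control):

* **Control positions** — computed at deliberately lenient thresholds
  (MAPQ ≥ 0, BQ ≥ 0) so that *any* alternate evidence in the control
  disqualifies a position (`max_control_alt = 0`; configurable). A
  position qualifies with coverage ≥ 20× (diploid mode) or > 40×, i.e.
  ≥ 41 (haploid mode — the haploid reference sees both haplotypes'
  reads), no indel evidence, and no non-reference base.
* **Mutant filter cascade** — pileups at MAPQ ≥ 10, BQ ≥ 30; a site is
  called iff: position in the control set; depth ≤ 70× (diploid) or
  ≤ 120× (haploid), counted after the quality thresholds; exactly two
  base alleles (reference plus one alternate, with at least one
  reference read — otherwise the reference mismatch mean is undefined);
  no indel evidence; ≥ 3 alternate reads with at least one on each
  strand; reference-read mean mismatch ≤ 0.01; alternate-minus-reference
  mean mismatch ≤ 0.01. All inequality directions follow the printed
  thresholds literally (boundaries are tested exactly: 19/20, 40/41,
  70/71, 120/121, 2/3 reads, Q29/Q30, MAPQ 9/10, 0.01/0.011).

Haploid- and diploid-mode calls are merged through a coordinate map; for
simulated data the map is exact by construction (divergent blocks are
same-length replacements, so haplotype coordinates are collinear, with
block intervals excluded from the hapB mapping). Identical site+allele
pairs collapse with dual provenance; different alternates at one mapped
site are kept and flagged as conflicts.

```{r calling-demo}
study <- simulate_paired_study(chrom_len = 3e4, n_per_layer = c(L2 = 5),
                               depth = 60, seed = 11)
res <- run_dual_calling(study)
res
score_against_truth(res$merged, study$implants)$recall
```

## Mismap validation

Short reads mismap more readily than the long reads an assembly is built
from. `classify_read_mapping()` checks each diploid-aligned read by
extracting its diploid-assembly window (read footprint ± 2 kb, ~4.1 kb
for a 150 bp read, clipped at contig ends), aligning the window to the
haploid assembly, and comparing the read's *direct* haploid alignment
with the window's haploid footprint:

* window alignment spanning < 4 kb → verdict **undefined** (the strict
  boundary: a 4,000 bp span is defined, 3,999 is not);
* direct position inside the footprint → **proper**;
* outside it, or direct alignment missing → **improper**.

The flank aligner is a pluggable contract (`function(query, targets)` →
best footprint). The default, `exact_seed_aligner()`, chains exact
60-mer seeds sampled every 250 bp and reports the footprint of the best
co-linear chain (diagonal scatter ≤ 10 kb; multi-part alignments beyond
that would take the longest part). Exact seeding is sufficient for
synthetic data; note that windows extracted from the *other* haplotype
carry the genome's heterozygous divergence, so a fraction of their
seed chains legitimately span under 4 kb and classify as undefined —
the invariant that holds without paralogy is that 100% of *defined*
verdicts are proper. Production use can plug in a long-read aligner
under the same contract.

`crosscheck_germline_variants()` implements the complementary
germline-level check: short-read variants with depth within 0.5–2×
sample coverage (inclusive), VAF ≥ 0.3 and FILTER PASS are looked up in
a long-read pileup; ≥ 5 supporting long reads count as reproduced, and
the non-reproduced fraction is reported per 0.05-wide VAF bin.

## Layer model and mutation rates

Mutations shared between leaves and embryonic tissue mark L2 (embryos
derive from L2). With a central shared-mutation VAF of 0.3, L2
constitutes `2 × 0.3 = 60%` of sample DNA; the remaining 40% splits
between L1 and L3 with L1 < L3, so L1 < 20% and a fixed L1 mutation is
expected below VAF 0.1 against a haploid reference. Transmissible (L2)
candidates are selected at VAF ≥ 0.2 (haploid mode) or ≥ 0.4 (diploid
mode, where per-haplotype coverage halving doubles observed VAF). The
median is the default VAF summary (the mean is available via
`center = "mean"`).

```{r layer-demo}
estimate_layer_model(0.3)
```

Rates divide the transmissible-candidate count by the effective site
count (control-sample positions with depth strictly above 20× in the
diploid assembly):

```{r rate-demo}
mutation_rate(77, 1.3e9, age_years = 234, generation_years = 50)
```

Reported rates default to 2 significant digits; `print(x, sigfigs = 1)`
reproduces 1-significant-digit rounding. The mutation spectrum folds
purine-reference substitutions onto the pyrimidine strand (G>A ≡ C>T,
reported as C:G>T:A) over the six standard classes.

## What the simulator emulates — and what it does not

`simulate_diploid_genome()` / `implant_somatic_mutations()` /
`simulate_reads()` / `emit_truth_alignments()` generate:

* a diploid genome at a uniform heterozygous SNV rate (default 0.016)
  with optional haplotype-divergent blocks (hapB replaced by unrelated
  same-length sequence — the reads mappable only to a diploid
  assembly);
* layer-tagged somatic implants placed off het sites, each recording
  `expected_vaf = layer_fraction × cell_fraction / 2`; default layer
  fractions L1 = 0.18, L2 = 0.60, L3 = 0.22 (L2 from the shared-VAF
  argument above; L1 below, L3 above 20%);
* paired 150 bp reads (insert 400 ± 60 bp — placeholder values, not
  estimates from any particular dataset) drawn equally from both
  haplotypes, with one carrier draw per *fragment* per implant so mates
  never disagree; substitution errors at 0.1% emitted at Q20 against a
  Q38 baseline, so the BQ ≥ 30 filter has sub-threshold bases to act
  on;
* truth alignments with exact `NM` (recomputed by sequence comparison),
  `AS = matches − 4 × mismatches`, MAPQ 60/0 by haplotype-span
  distinguishability, and hapB divergent-block reads unmapped in
  haploid mode. Truth alignments are ungapped and unclipped; clipped
  and indel-bearing records for filter tests are constructed explicitly
  in fixtures.

Not emulated: indel and structural-variant errors, PCR duplicates,
quality-score miscalibration, GC / coverage bias, alignment-heuristic
artifacts of real aligners, and paralogy (unless planted). Passing
tests therefore demonstrate the *logic* of the pipeline — filter
arithmetic, assignment hierarchy, masking, merging — under controlled
conditions, not robustness to every real-data artifact; the mismap and
germline cross-check modules exist precisely because real alignments
violate the simulator's idealizations.

## Numerical and design choices

* Coordinates are 1-based closed throughout the R API (SAM/VCF
  convention); BED output is 0-based half-open.
* The haploid control threshold "> 40×" is implemented as ≥ 41; the
  mutant caps "≤ 70×/120×" are inclusive; effective sites require depth
  *strictly* above 20.
* Simulation problem sizes in the test-suite and acceptance script:
  30–100 kb genomes at 60× with 10 null replicates and 50 L2 implants —
  large enough that every per-site law (binomial coverage, VAF
  sampling) is exercised at study-scale depth while the whole suite
  stays fast. At 60× total coverage the diploid mode sees ~27×
  per haplotype, so the 20× control mask is the binding constraint for
  recovering implants; the acceptance script reports the measured
  recall.
* Ties and degenerate inputs: both-sides-unmapped reads are a caller
  error; empty implant lists, empty call sets and zero-mutation rate
  requests return well-defined empty/zero results; zero effective
  sites is an error.
* Determinism: every stochastic function takes a `seed` and restores
  the caller's RNG state; identical seeds give byte-identical FASTQ and
  SAM output.

## Limitations

False-negative rates are not modelled (no attempt to extrapolate how
many sub-threshold mutations exist). The manual inspection step real
studies apply between raw and final call sets is not algorithmically
specified and is out of scope, as are assembly construction, organelle
genomes, centromere analyses, and external variant callers. The
per-mode breakdown used downstream of the transmissible-candidate count
is reproducible only from the count itself (n = 77 in the worked
example), not re-derived from raw data.
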