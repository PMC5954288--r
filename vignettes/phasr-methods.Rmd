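---
title: "Models and methods behind phasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasr)
```

# The phasing model

A PHAS locus emits siRNAs whose 5' ends fall at exact p-nt increments
(p = 21 or 24) from a fixed register, on both strands of a duplex with
2-nt 3' overhangs. `phasr` evaluates every genomic window of
m = 10 phase cycles (`p * m` nt) against the null hypothesis that the
unique small RNAs inside it are placed uniformly over the window's
positions.

## Register space

All positions are 1-based. A plus-strand read occupies its leftmost
coordinate; a minus-strand read is mapped into the shared register
space as `leftmost + 2`, because the minus-strand partner of a phased
duplex starts two nucleotides upstream on the plus strand
(`phase_position()`). After this offset, duplex partners are
congruent modulo p, which is what makes a single combined register
space for both strands valid. The register of a read relative to a
window starting at `s` is `(effective - s) mod p`; register 0 is "in
phase".

## The hypergeometric P-value

A window holds `pm` positions of which `m` are in phase. If `n`
unique p-nt sRNAs fall in the window and `k` of the `m` phased
positions are occupied, the probability of at least `k` occupied
phased positions under uniform placement is the hypergeometric upper
tail

$$P = \sum_{j=k}^{m} \frac{\binom{(p-1)m}{n-j}\binom{m}{j}}{\binom{pm}{n}}.$$

Two readings of `k` are possible: distinct phased *sequences* or
occupied phased *positions*. `phasr` counts occupied positions
(capping `k` at `m`), because that keeps the hypergeometric support
valid when several unique sequences pile on one phased position; all
of their reads still contribute to the phase score through $P_i$.
For the same reason `n` is capped at `pm`.

Numerically, each tail term is evaluated in log space with
`lchoose()` and the positive terms are summed; no cancellation can
occur, so the result matches an exact integer-arithmetic evaluation
to near machine precision (the test suite checks `1e-12` relative
agreement against an arbitrary-precision big-integer oracle and
against `stats::phyper`). `k = 0` returns exactly 1.

## The phase score

For a window whose start has `k >= 3` occupied phased positions,

$$S = (k-2)\,\ln\!\left(1 + 10\,\frac{\sum_{i=1}^{m} P_i}{1+\sum_{i=1}^{m} U_i}\right),$$

with $P_i$ and $U_i$ the phased and non-phased *read* counts at the
i-th cycle downstream of the window start ("downstream-only" is the
reading adopted for "from the position"; the window defines the m
cycles). Windows with `k < 3` carry no score. The score is
increasing in phased reads, decreasing in noise reads and linear in
the number of distinct phased positions.

## From windows to loci

Windows slide in 1-nt steps (the score is defined "for each
position", so every register is evaluated; merging later collapses
the redundancy). Then:

1. windows with raw P < 0.05 **and** `k >= 3` are extended 100 bp on
   both sides and transitively merged;
2. each merged region inherits its minimum member P-value; regions
   are corrected by Benjamini–Hochberg (a Storey-style q-value is
   available via `fdr_method = "qvalue"`);
3. regions with maximal phase score > 5, corrected P < 0.05 and at
   least 4 unique phased tags become PHAS loci, named
   `P{p}_{chromosome}_{serial}`; their phased tags are extracted as
   phasiRNAs `{locus}_siR{serial}` in positional order;
4. same-chromosome, same-phase-length loci closer than 2000 bp are
   chained into clusters.

The `k >= 3` seeding gate in step 1 deserves its own paragraph, as it
is the one place where the implementation restricts the textual rule
"extend windows with P < 0.05". For a window holding a single
isolated tag, the tail is $m/(pm) \approx 0.048 < 0.05$; in a
sparse-coverage regime every stray background read therefore creates
a swath of extended "significant" windows, and these swaths chain
unrelated loci kilobases apart into one merged region (observed
directly on synthetic data: two planted ladders 7 kb apart were
reported as a single locus). Windows with `k < 3` can never carry
the phase score a reported locus must have, so restricting seeding to
score-bearing windows changes region *boundaries* only, never which
loci can be called, and removes the sparse-data pathology. In dense
real libraries nearly every window has n large and k small, singleton
windows are rare, and the gate is inert.

The region's "anchor" is the start of its maximal-score window; the
locus register is the anchor modulo p, and phasiRNA extraction takes
the unique tags congruent to that register inside the region.

# Tag mapping

Mapping is ungapped with a bounded number of substitutions
(defaults: 2 for genome/homolog mapping, 0 for category annotation
and degradome placement), reports *all* placements on both strands,
and reports minus-strand hits by leftmost plus-strand coordinate.
Multi-mapping tags contribute to every placement, which preserves
phased ladders on near-duplicated loci. The scan is delegated to
Biostrings (`vmatchPattern`, with a `PDict` fast path for exact
matching); a brute-force Hamming oracle in the test suite pins the
exhaustive-scan semantics. A seed-and-extend index was deliberately
not used for the mismatch search: with the minimum practical word
size of 8, two substitutions in a 21-nt tag can intersect every
8-mer window, so seeding cannot guarantee sensitivity. The exact-word
index (`build_index`/`lookup_word`) remains available for word
queries.

# miRNA discovery

Conserved candidates come from catalog homology (<= 2 substitutions);
for each hit, six windows (80/130/180-nt flanks, upstream- and
downstream-extended) are folded and screened. The MIRcheck-style
screen counts unpaired mature positions (cap 5), bulged or
asymmetrically unpaired nucleotides (cap 2) and the longest unpaired
run (cap 3). An unpaired run of length `a` facing an opposing-arm gap
of length `b` contributes `min(a, b)` mismatches and `|a - b|`
bulges; runs touching the mature boundary count as bulges since the
opposing gap is undefined there. A mature whose positions pair
*within* the mature interval spans the terminal loop and fails
outright.

Novel calling requires expression evidence: the most abundant tag on
the candidate precursor is the mature; some other tag must sit on the
opposite arm such that the folded structure pairs the mature 5' end
two nucleotides inside the star 3' end and vice versa (2-nt 3'
overhangs; tolerance 1 nt for folding ambiguity); the mature:star
duplex must hold >= 18 base pairs; and the folding energy must be
below -40 kcal/mol. Criteria are reported in the order pairing,
energy, star, and the first failure is returned. "18 paired
nucleotides" is evaluated over the mature:star duplex (the
Meyers-criteria reading) rather than the whole hairpin.

## Folding

The default folder is a built-in maximum base-pairing dynamic program
(Watson–Crick + G:U, minimum hairpin loop 3, deterministic
traceback) with a simple stacking energy: -3 kcal/mol per stacked
G:C, -2 per A:U, -1 per G:U, 0 for isolated pairs. These are *not*
thermodynamic free energies; the -40 kcal/mol gate is therefore
asserted only on synthetic constructs whose baseline energy is
unambiguous (a perfect 21-bp stem scores around -50). When ViennaRNA
is installed, `fold(seq, engine = "rnafold")` returns true MFE
structures and the gate applies as printed.

# Degradome analysis and targets

Complementary sites are scored by an ungapped reverse-complement
scan; query position q pairs site position `end - q + 1`; each
mispair costs 1 and each G:U wobble 0.5 (configurable to 1). A
degradome read is *valid* for a site when its 5' end lies at a
transcript position pairing query positions 9-11 — the canonical
slicing window. Acceptance rules per query class: conserved miRNAs,
score <= 4; novel miRNAs, >= 1 valid read and score < 4; phasiRNAs,
score 0 or (>= 1 valid read and score <= 3); trigger search on PHAS
transcripts, >= 1 valid read or score < 4. TAS3 loci additionally
require miR390 complementary sites strictly on both sides of the
mapped tasiARF region (<= 2 substitutions for the tasiARF, 250-nt
cut-outs).

# Expression summaries

RPTM is `count / library_total * 1e7`; the default denominator is
the total tags entering the matrix (a "mapped-only" denominator can
be supplied explicitly). Clustering keeps rows with >= 5 RPTM in
>= 2 libraries and sd >= 1, transforms by ln(x+1) (natural log; the
base is a convention choice), and clusters libraries on 1 - Pearson
correlation with complete linkage. PCA keeps rows with mean RPTM
>= 5, transforms identically, and decomposes the column-centered
library-by-feature matrix by SVD; component signs are arbitrary.

# The synthetic data generator

`sim_config()`/`make_genome()` build uniform-random chromosomes with
planted features recorded as ground truth: phased ladders (an
interval, cycle count, strand, per-cycle abundance and off-phase
noise rate) and hairpins (mature + 8-nt loop + reverse complement,
giving a perfect stem whose recorded star is the 3' arm shifted by
two positions — exact Dicer duplex geometry). Libraries emit the
planted reads deterministically, noise reads at off-phase offsets,
and background reads drawn uniformly with lengths
21/22/23/24 at 0.35/0.10/0.10/0.45, mimicking the twin 21/24-nt
abundance peaks of real plant sRNA libraries. Quality strings are
constant Phred 40; QC tests construct degraded reads explicitly, so
QC behavior is decoupled from simulation realism.

What the generator does *not* emulate: sequencing errors beyond the
optional uniform substitutions, adapter-ligation and PCR biases,
genome repeat structure, transcript-space phasing, and the
long-tailed abundance distributions of real libraries. Passing the
planted-recovery tests therefore demonstrates correctness of the
statistics and bookkeeping, not performance on real tissue
libraries.

Default study sizes — 20-kb chromosomes, one library of ~300
background reads, ladders of 10 cycles at 2-3 reads per cycle with
10-20% off-phase noise, hairpin mature at 100 reads and star at 5 —
were fixed once as a realistic sparse-coverage toy regime and are
used unchanged by the test suite and the acceptance script (10-20
simulated studies per run).

# Numerical and degenerate-input choices

* Tail sums: log-space terms, positive summation, no cancellation.
* `phase_score` with all-zero phased reads returns 0 (ln 1).
* Windows with zero p-nt tags are skipped; empty inputs yield empty,
  correctly-typed tables throughout.
* Merged-region P-value = minimum member P-value (the region is its
  best window).
* Ties in the maximal-score window resolve to the smallest P, then
  the leftmost start, keeping anchors deterministic.
* Cluster chaining uses strict `< 2000 bp`; a gap of exactly 2000 bp
  separates clusters.
* Category annotation uses exact matching by default (the stringency
  of database mapping is a convention; a mismatch flag is exposed).
* The mature-only catalog match uses <= 2 substitutions by default,
  likewise exposed.

# Known limitations

* The baseline folder maximizes pairing, not free energy; its
  structures can differ from MFE structures on long, loosely paired
  candidates. Use the ViennaRNA engine for real data.
* No gapped or spliced alignment; tags crossing indels or introns are
  lost.
* Transcript-space PHAS scanning is supported only by treating
  transcripts as additional reference sequences.
* No differential-expression statistics; the count matrix export is
  compatible with count-based DE tools.
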