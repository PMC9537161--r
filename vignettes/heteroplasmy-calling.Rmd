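---
title: "Calling mitochondrial heteroplasmy from Cas9-enriched full-length long reads"
author: "MitoLongCall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial heteroplasmy from Cas9-enriched full-length long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoLongCall)
```

## The problem

Human mitochondrial DNA (mtDNA) is a 16,569 bp circular genome present in
hundreds to thousands of copies per cell.  Pathogenic variants are usually
*heteroplasmic*: only a fraction of the molecules carry them, and that
fraction — the variant allele fraction (VAF) — can take any value in
[0, 1].  Calling mtDNA variants therefore resembles somatic or pooled-sample
calling far more than diploid genotyping: there is no prior on the number of
alleles per site nor on their frequencies, and clinically relevant VAFs
reach below 1%.

One way to read native (PCR-free) mtDNA at full length is Cas9 enrichment:
each sample aliquot receives one guide-directed double-strand break at a
known position, sequencing adapters are ligated at the cut, and the position
where a read starts and ends then *is* the barcode identifying the aliquot.
MitoLongCall implements the complete informatics side of such an
experiment:

1. **Demultiplexing** reads to cut-sites from PAF alignments against a
   whole-genome reference;
2. **Custom reference construction** — a doubled, masked reference per
   cut-site so circular molecules map in one piece;
3. **Pileup and coordinate collapse** back onto the circular genome;
4. **Maximum-likelihood heteroplasmy calling** with Fisher scoring, a
   quality-stratified error model, likelihood-ratio call qualities, long
   deletion disentangling and local indel-haplotype merging;
5. **Phasing** from a per-read × per-position view matrix;
6. a **simulator** that generates reads, truth tables and ideal PAF/SAM
   alignments, so every stage is testable at desk scale without an external
   aligner or any download.

## Demultiplexing model

Reads are assigned to cut-sites from their PAF alignment segments.  A read
is considered only if all segments target the mitochondrial contig on one
strand, the segment order is consistent with one pass around the circle,
the circular genomic span is at most one genome length, and at least
`minMappedFrac` (default 0.90 — our operationalisation of "almost all of
the read mapped") of its bases are aligned.  Its 5′ end matches a cut-site
if it lies at most `tolerance` (default 100) bp *after* the cut in the
direction of synthesis, its 3′ end if at most `tolerance` bp *before* it.
Four selection strategies trade stringency for yield: `both` (full-length
reads only), `start`, `either`, and the deliberately degraded `xor`
(never full-length).  A read whose start and end match different
cut-sites, or that matches several cut-sites, is rejected as ambiguous
under every strategy — we prefer losing a read to risking cross-sample
assignment, and this choice is also what makes the assigned sets nest
(`both` ⊆ `start` ⊆ `either`, `xor` = `either` \ `both`).  Reads with
MAPQ 0 on all segments are treated as non-uniquely aligned and dropped.

## Doubled, masked references

For genome length $l$ and padding $d$ (default 5 bp), the custom reference
for a cut at 0-based position $x$ is
$\mathrm{last}_d(R)\,R\,R\,\mathrm{first}_d(R)$ — total length $2(l+d)$ —
with every base outside $[x,\; x+l+2d]$ (0-based, inclusive) masked to
`N`.  Both copies of the cut-site remain, each flanked by $d$ bases of
context, so full-length *and* partial reads assigned to that cut map
exactly once, and every alignment column collapses back to the circular
genome by $x' = (x - d) \bmod l$.  All cut-site references share this
layout, so alignments from different cut-sites of one sample can be merged
without coordinate translation.  The masked sentence of the construction is
ambiguous about which copy of the cut "x" refers to; we anchor the unmasked
window at the *first* cut copy minus $d$, the only reading that leaves both
copies usable with context.

## The likelihood model

At a site with $m$ alleles and observations stratified into quality levels
$j$ with error probabilities $e_j = 10^{-q_j/10}$, the probability of one
observation of allele $i$ at level $j$ is the two-component mixture

$$p(f_i, e_j) = f_i (1 - e_j) + (1 - f_i)\, e_j,$$

and the log-likelihood is $L(f) = \sum_{i,j} c_{ij} \ln p(f_i, e_j)$ with
counts $c_{ij}$.  Frequencies sum to one, leaving $m-1$ free parameters
with $f_0 = 1 - \sum_{i>0} f_i$ for the reference allele.  The score and
expected information are

$$S_i = \sum_j (1-2e_j)\Big(\frac{c_{ij}}{p(f_i,e_j)} -
  \frac{c_{0j}}{p(f_0,e_j)}\Big), \qquad
I_{ii} = \sum_j (1-2e_j)^2 c_j \Big(\frac{1}{p(f_i,e_j)} +
  \frac{1}{p(f_0,e_j)}\Big),$$

with identical off-diagonal entries
$\sum_j (1-2e_j)^2 c_j / p(f_0,e_j)$ and $c_j = \sum_i c_{ij}$.  Fisher
scoring iterates $f' = f + a I^{-1} S$, with $a \in (0,1]$ found by
halving from the largest step that keeps all frequencies non-negative
until the likelihood does not decrease.  A frequency driven to zero whose
score is negative is fixed there and its allele removed; iteration stops
when no positive step improves the likelihood or the relative
log-likelihood change falls below `tol` with a negligible step.  Standard
errors come from the inverse information at the optimum; each retained
allele gets a likelihood-ratio test against a refit with its frequency
pinned at zero, reported as a phred-scaled $\chi^2_1$ tail probability.

This per-allele "one-vs-rest" error channel is exact for two-allele sites
and an approximation for more; it is the price of a model whose score and
information have the closed forms above.  Note three numerical choices:

* $e$ is capped at `eCap` = 0.45 and bases under `qMin` = 5 are discarded,
  so $(1-2e) > 0$ and the likelihood stays increasing in $f$ (no cap or
  floor is inherent to the model; both are configurable);
* non-candidate alleles (fewer than 2 observations on either strand) are
  carried as fixed-zero alleles — their observations still contribute to
  the likelihood and to the totals $c_j$ rather than being silently
  dropped;
* convergence requires both a small relative likelihood change and a small
  applied step, which in the two-allele single-quality case reproduces the
  closed form $\hat f = \mathrm{clip}\big((\hat p - e)/(1 - 2e), 0, 1\big)$
  to $10^{-6}$.

## Candidate alleles, deletions and haplotype windows

An allele becomes a candidate if it has **more than one observation on
each strand**.  Deletions inherit the quality of the preceding read base;
insertions anchor at the preceding reference position with the lowest
component-base quality and do not add depth.

Long deletions are found as maximal runs of at least `longDelMin` (default
64 bp) consecutive positions carrying a candidate deletion allele.  The
per-read CIGAR deletion intervals in a region are clustered greedily —
start and length each within `mergeTol` (default 10 bp) of the running
cluster medians — and each cluster becomes a deletion allele whose
frequency is fitted by the same scoring machinery against the reads
spanning the region.  Because membership of a read in a multi-kilobase
deletion cluster is decided by its whole alignment, not one base, these
class counts use a small fixed misassignment probability (`delErr`,
default $10^{-3}$) instead of base qualities; using base-derived $e$ here
would "correct" frequencies for errors that cannot occur and visibly bias
high-frequency deletions.  After detection, sites inside a region are
re-estimated without the carrier reads; if all reads carry the deletion
the interior has no post-exclusion depth and is left uncalled.

Short indel haplotypes are merged over left-anchored windows: an anchor
site without deletion candidates followed by sites with them.  Candidate
merged alleles are the product of the per-site retained alleles, counted
from reads spanning the window (multibase quality = lowest component
quality), refitted, and pruned at zero frequency as the window extends
(capped at `maxWindow` = 50 bp).  We deliberately keep the per-position
pileup strictly per-base and form multibase alleles only in this windowed
step; that preserves the invariant that per-site allele depths sum to the
number of covering reads.

## Filters

Calls are flagged, not removed: `strand_bias` (two-sided Fisher exact test
of allele × strand against the dominant other allele, $p < 10^{-3}$),
`base_qual_bias` (one-sided Mann–Whitney of minor- vs major-allele base
qualities, $p < 10^{-3}$, applied when the called allele is the minor
one), `low_qual` (phred LRT quality < 30) and `low_freq` (VAF < 0.5%).
`PASS` means no flag.  Thresholds are conservative defaults for a method
expected to resolve heteroplasmy below 1%; all are arguments of
`callerThresholds()`.

## The view matrix and phasing

`buildViewMatrix()` renders the merged pileup as one text row per read
with exactly $l$ columns (16,569 for an rCRS-length genome): the aligned
base, `-` for deleted, `.` for skipped (uncovered) positions, and a
lower-case base marking an insertion anchor.  Glyphs are our choice; the
insertion sequence itself is not expanded into columns.  Phasing any set
of positions is then a string operation: reads covering all selected
positions are grouped by their character tuple and haplotype frequencies
are the group proportions.  This deliberately ignores intervening
sequence, so distant sites can be phased without being derailed by
errors between them.

## What the simulator emulates — and what it does not

`simulateSample()` draws, per read: a cut-site of its sample, a molecule
population (mixture fractions as configured), a strand (fair coin), a
length class (full-length, or a cut-anchored fragment for degraded-DNA
scenarios), per-base qualities from a discrete level mix (default mass on
q10–q30), substitution errors at the Phred rate of each base (uniform over
the three other bases), optional single-base deletion errors, and optional
breakpoint jitter for population deletions.  Reads are emitted as FASTQ
together with ideal PAF segments against the linear contig (split at the
reference origin) and ideal SAM against the cut-site's custom reference —
by construction, since the simulator knows the truth, which keeps the test
surface hermetic.  A molecule whose deletion spans a cut-site cannot be
cleaved there, so populations are re-weighted per cut-site (and a cut-site
with no admissible population is a configuration error); this reproduces
the diagnostic behaviour where a guide inside a deleted segment captures
only intact molecules.

Defaults are study-shaped: tolerance 100 bp, padding $d$ = 5 bp, full-length
reads starting exactly at the cut (`startOffsetMax` = 0 — non-zero start
offsets are supported, but exact ends are what makes full-length coverage
perfectly even, which we use as a check).  The simulator does **not**
model homopolymer-dependent or correlated nanopore errors, duplex reads,
adapter chimeras or NUMT contamination; passing tests show the statistics
are implemented correctly under the stated generative model, not that real
flow-cell error structure is captured.  The read-level substitution model
(uniform flip to three bases) also differs slightly from the caller's
one-vs-rest channel for sites with more than two alleles;
`simulatePileupCounts()` flips between modeled alleles and matches the
channel exactly for two-allele sites, which is why the calibration
experiments use it.

## Problem sizes and reproducibility

The bundled checks run entirely from simulation: 200 random sites against
a coarse-to-fine grid-search oracle ($10^{-5}$ resolution), 1,000 random
two-allele sites against the closed form, 100 replicates per VAF
(1–50%, depth 2,000, q20) plus 100 null replicates, a 1,000-read
full-genome (l = 16,569) two-deletion mixture (10% intact / 10% large
deletion / 80% small deletion), a 400-read 4-sample × 2-cut-site
demultiplexing run, and a 3-read view-matrix geometry check.  These sizes
keep a full run in tens of seconds on one CPU while leaving the binomial
standard errors small enough for 3-SE assertions to be meaningful.
`scripts/acceptance.R --seed N --out f.json` recomputes all of them from
scratch.  Genomes are random with the stated lengths; the rCRS sequence
itself is not bundled, as none of the properties depend on its actual
bases, only on its length.

## Known limitations

* Deletions are clustered greedily by running medians; pathological
  overlapping clusters closer than `mergeTol` in both start and length are
  reported as one allele.
* Origin-spanning deletion *regions* are joined, but a deletion allele
  crossing the origin is written as two VCF records sharing an `EVENT` id.
* The one-vs-rest likelihood is approximate for ≥3 segregating alleles at
  one site (rare in mtDNA data, where multi-allelic sites are dominated by
  one variant).
* No realignment: indel placement is taken from the aligner (or the
  simulator) as-is.
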