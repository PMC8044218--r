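---
title: "Profiling the regulatory activity of a repeat subfamily"
author: "RegulaTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the regulatory activity of a repeat subfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RegulaTE)
```

## The problem

Transposable elements, and LINE-1 subfamilies such as L1PA2 in particular,
carry regulatory sequence — a roughly 900 bp 5' UTR with a bidirectional
promoter — that is epigenetically silenced in most somatic tissue but can
re-activate in cancer. When many near-identical copies of a subfamily carry
the same transcription-factor binding sites, the subfamily acts as a vector
that disperses co-localised regulatory elements across the genome.
`RegulaTE` quantifies that activity from interval-level evidence: a
RepeatMasker-style annotation of the subfamily's copies, TF binding-site
(TFBS) interval sets, epigenetic read coverage, and a differential
transcript table. Everything operates on `GRanges` and returns S4 result
objects.

## The procedures and their assumptions

**Element-centred meta-profiles.** A fixed window (default 20 kb, 100 bp
bins) is centred on each element's midpoint. TFBS counts per bin are
normalised so every contributing element's profile sums to 1, minus-strand
windows are reversed so bin 1 is 5'-most, and profiles are averaged over
elements that harbour at least one site in their window. The per-element
denominator is the *summed bin count* of the window rather than the raw
number of sites: a site spanning k bins increments k bins, and dividing by
the summed bin counts is the choice that makes each element contribute unit
mass, which is the conservation property the averaged profile inherits and
the tests assert. Windows truncated by a chromosome edge are flagged and
excluded from averaging rather than renormalised.

**Element assignment.** A site belongs to an element when at least a
fraction `overlapFraction` (default 0.5) of the *site* overlaps that single
element — the fraction is never pooled across elements, and the rule is
`>=`, so an exactly-half overlap is assigned. Binding frequencies per TF
are reported against the number of bound elements.

**Consensus projection.** The distance from a site midpoint to the
element's 5' end (the right genomic edge for minus-strand copies), shifted
by the element's RepeatMasker consensus start, gives a 1-based position in
the subfamily consensus. For minus-strand rows of the UCSC rmsk dialect
the consensus start is taken from `repLeft`, which is where UCSC stores it
for reverse-strand alignments; the simplified TSV dialect carries explicit
`consensus_start`/`consensus_end` columns and sidesteps the convention.
Positions are clipped at 1 and histograms (5 bp bins, 0–6500 by default)
drop positions beyond the plotting bound with a logged count.

**Co-localisation statistics.** Same-TF sites are merged to most distal
coordinates first, so counts are of merged binding regions. Two sites
co-localise when their gap is *strictly* less than the window (default
500 bp) under half-open extension — a gap of exactly 500 bp does not
qualify. This boundary matters: the everyday phrase "within 500 bp" is
ambiguous, and the strict rule matches the windowing arithmetic of the
standard interval toolkit, so it is stated here prominently. Ordered-pair
proportions are asymmetric by construction (each TF's own total is the
denominator). Element-derived and non-element-derived proportions are
compared with a one-tailed *pooled* two-proportion z-test with no
continuity correction (site counts are large in intended use); the sign is
kept so depletion shows as negative z. Familywise control is Bonferroni at
`alpha / k^2`: the denominator deliberately counts the full k-by-k grid,
self-pairs included even though they are untested, because that is the
arithmetic that yields the conventional 0.05/81 ≈ 6.2e-4 threshold for
nine TFs. Star tiers are `*` below that threshold, `**` below 1e-4, `***`
below 1e-5. Cells whose TF has no merged site in a group are reported
missing rather than tested.

**Epigenetic profiles.** Reads are assigned to bins by midpoint — reads
are point-like at 100 bp resolution and single-bin assignment avoids
double-counting, in contrast to TFBS features which use overlap counting.
Bin counts convert to RPKM as `count * 1e9 / (binWidth * totalMapped)`.
Replicates are averaged *before* the input control is subtracted; the two
orders agree when controls are replicate-matched, and the
average-then-subtract order is the documented one. Normalised RPKM may be
negative. No winsorising or log transform is applied.

**TSS enrichment.** Transcripts classify as up (fold change strictly
greater than 2), down (strictly less than 0.5) or unchanged, with an
optional p-value filter for the stricter DE set. The TSS is the position
where the transcript begins, strand-aware; a TSS is inside an element iff
its single base falls in the half-open span — no fraction rule, since a
point has no length. The null for TSS-in-element overlap is a rotation
permutation: each chromosome's TSS positions are circularly shifted by an
independent uniform offset (10,000 permutations by default), which
preserves per-chromosome TSS counts and all pairwise circular distances
while randomising placement relative to the fixed elements. Rotating
elements instead is equivalent in distribution; a single-offset mode is
available as a flag. The mean overlap count over permutations divided by
the TSS count gives the expected per-TSS probability, and the observed
count is tested with an exact one-sided binomial tail in the observed
direction (enrichment and depletion are separate directional questions).
Novel transcripts associate with known ones when at least one exon of each
overlap by one base on the same strand; strand matching is the
conservative codification of an otherwise visual comparison.

**Motif scanning.** JASPAR-style count matrices become PWMs with a per-cell
pseudocount (default 0.1 — JASPAR matrices contain zero cells) and a
uniform background (default 0.25 per base; configurable). Log-odds are
base 2. Scores are discretised to 1e-3 log-odds units and the exact score
distribution of a random background word is computed by dynamic-programming
convolution across positions; the scanner scores windows with the *same*
discretised matrix, so every hit's p-value is exactly the tail probability
of its score. The discretisation error on any word score is bounded by
width × granularity/2. The hit threshold is the smallest attainable score
with tail probability at or below the target (default 1e-4); if no score
qualifies the cutoff is placed above the maximum and no hit can pass.
Only the provided strand is scanned — element sequences are expected to be
extracted strand-aware, so the scan direction is the element's own 5'→3' —
and windows containing N are skipped.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `windowWidth` | 20000 | bp | element-centred window |
| `profileBin` | 100 | bp | profile bin width |
| `overlapFraction` | 0.5 | — | site fraction for element assignment |
| `colocWindow` | 500 | bp | co-localisation distance (strict) |
| `upFc`, `downFc` | 2, 0.5 | — | strict fold-change class bounds |
| `dePCut` | 0.05 | — | optional DE p-filter (off by default) |
| `motifP` | 1e-4 | — | motif hit significance |
| `motifBin` | 5 | bp | consensus histogram bin |
| `proximityMax`, `proximityStep` | 20000, 1000 | bp | proximity ladder |
| `nPermutations` | 10000 | — | rotation permutations |
| `alpha` | 0.05 | — | familywise level; per-test `alpha / k^2` |

All of them live in one `AnalysisConfig` object so a run's constants are
auditable in a single artifact; the CLI serialises the config into every
output directory's manifest.

## What the synthetic generator emulates — and what it does not

`fixtureSpec()` defines the study conditions used throughout the tests:
three 1 Mb chromosomes, 40 non-overlapping full-length 6 kb elements with
a 900 bp 5' subregion (mirroring the ~900 bp LINE-1 5' UTR), four TFs with
homogeneous Poisson background sites at 100 sites/Mb and a ten-fold
5'-subregion density multiplier, 200 bp sites, transcripts whose
up-regulated class has 30% of TSSs planted inside elements (against ~8%
element coverage), coverage reads at 2000 reads/Mb with a twenty-fold
multiplier in bound elements' 5' subregions, and a 12 bp motif word planted
at consensus offset 201 of every element. These values are realistic
magnitudes for the biology being emulated — full-length LINE-1 geometry,
promoter-concentrated binding, and a promoter-strength TSS excess — and
were fixed once as the generator's defaults.

Pairwise coupling is planted by *relocating* existing element-internal
sites of the second TF to within 100 bp of the first TF's element-internal
sites. Relocation, rather than adding sites, preserves every TF's marginal
site density, so coupling is a pure pairwise dependence and all other TF
pairs remain exactly null — the property the familywise and recovery tests
rely on. Homogeneous Poisson backgrounds make the null distributions
analytic.

What the generator does *not* emulate: repeat sequence divergence and
phylogeny (element sequences are i.i.d. uniform bases plus the planted
word, because scanning near-identical real repeat copies is exactly the
regime where surrounding sequence similarity, not the scanner, dominates),
mappability structure, read-length and fragment-size effects, overdispersed
ChIP backgrounds, and correlated binding of more than two TFs. Passing
tests therefore demonstrate correctness of the statistics under their
stated models, not robustness to those real-data artefacts.

## Numerical choices and degenerate inputs

- Coordinates are held in `GRanges` (1-based closed) — the native
  convention of the container library — while all external formats
  (BED, rmsk dumps) are 0-based half-open and converted at the boundary;
  `grFromBed()` lets examples and tests be written in input coordinates.
- Profile mass conservation is asserted to 1e-9; strand-mirror symmetry is
  exact (no tolerance beyond floating addition order, 1e-12).
- The pooled z-statistic is defined as 0 with p = 0.5 when the pooled
  proportion is degenerate (0 or 1), logged.
- `expectedP = 0` with a positive observed count gives a binomial p of 0;
  this degenerate case is logged rather than hidden.
- Merging never joins book-ended intervals (zero overlap is not overlap);
  outputs are sorted by chromosome then start for deterministic output.
- All randomness flows through explicit integer seeds; the rotation test
  records its seed in the result object.

## Problem sizes in the test suite

The statistical suite uses sizes chosen to make its Monte-Carlo bounds
tight while keeping the default run quick: oracle equivalence on 500
random instances per operation; null calibration of the rotation-binomial
pipeline over 200 replicates at 1,000 permutations each (the binomial
interval check is on the 5% rejection rate); familywise control over 200
replicates of a four-TF Poisson null; recovery of planted coupling and
planted TSS excess over 100 seeded runs each; exact-enumeration motif
checks at widths up to 6.

## Known limitations

- Per-element binding summaries count a site once per element it overlaps;
  a site straddling two elements (rare for full-length copies) contributes
  to both.
- The rotation null conditions on element positions and chromosome
  lengths; it does not model inhomogeneous TSS density along chromosomes
  beyond what rotation preserves.
- Consensus projection uses the affine RepStart shift; internal deletions
  of individual copies are not corrected (the same approximation the
  RepStart/RepEnd fields support).
- The DP score distribution is exact only with respect to the discretised
  matrix; p-values of two words closer than the granularity in true score
  can tie.

## A minimal closed loop

```{r closedloop, eval = FALSE}
bundle <- simulateAll(fixtureSpec(rngSeed = 1))
summary <- bindingSummary(bundle$elements, bundle$sitesByTf, 0.5)
summary
profile <- tfbsMetaProfile(bundle$elements,
                           sort(Reduce(c, unname(bundle$sitesByTf))),
                           analysisConfig())
sum(profileValues(profile))   # 1: conservation
```
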