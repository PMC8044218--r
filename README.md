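# RegulaTE

Regulatory profiling of transposable-element subfamilies from
transcription-factor binding, epigenetic coverage and differential
transcription.

## What it is for

Full-length LINE-1 copies (e.g. the primate-specific L1PA2 subfamily,
~6 kb with a ~900 bp 5' UTR harbouring a bidirectional promoter) are
normally silenced, but in cancer cells many copies re-activate and supply
binding sites and transcription start sites to the host transcriptome.
Because a subfamily's copies are near-identical, this activity is best
measured at the subfamily level. `RegulaTE` is for genomicists who have
interval-level evidence — a RepeatMasker annotation, per-TF ChIP-seq
binding-site sets, read coverage of chromatin marks, and a transcript
table with fold changes — and want to quantify, with calibrated
statistics, how much regulatory activity the subfamily carries.

## The statistics at its core

- **Element-centred meta-profiles**: for each element a 20 kb window in
  100 bp bins; per-element bin counts are normalised to unit mass,
  oriented 5'→3', and averaged over elements with at least one site.
- **Element assignment** by fractional overlap: a site belongs to an
  element iff `overlap_bp >= f * site_length` against a single element
  (default f = 0.5).
- **Consensus projection**: site and motif midpoints map to the subfamily
  consensus via the distance to the element 5' end shifted by the
  RepeatMasker RepStart.
- **Co-localisation enrichment**: for ordered TF pairs (i, j), the
  proportion of TF i's merged sites with a TF j site within 500 bp
  (gap strictly < w), compared between element-derived and
  non-element-derived sites with a one-tailed pooled two-proportion
  z-test,

  z = (p̂₁ − p̂₂) / sqrt( p̂(1 − p̂)(1/n₁ + 1/n₂) ),  p̂ = (k₁ + k₂)/(n₁ + n₂),

  Bonferroni-controlled at α/k² (0.05/81 ≈ 6.2e-4 for nine TFs).
- **Epigenetic meta-profiles**: per-bin read-midpoint counts →
  RPKM = count · 1e9 / (bin · total_mapped) → replicate average → input
  subtraction → bound/unbound group averages.
- **TSS-in-element enrichment**: a circular-rotation permutation null
  (per-chromosome uniform offsets, 10,000 permutations) estimates the
  expected per-TSS overlap probability; the observed count is tested with
  an exact one-sided binomial tail, P(X ≥ obs) for enrichment or
  P(X ≤ obs) for depletion.
- **Motif scanning with exact calibration**: JASPAR counts → PWM
  (pseudocount 0.1, uniform background); the exact null score distribution
  is computed by dynamic programming at 1e-3 log-odds granularity, hits at
  p < 1e-4 on the given strand only.

A seeded synthetic-fixture generator (`fixtureSpec()` / `simulateAll()`)
produces every input format with known planted structure — 5'-enriched
sites, marginal-preserving pairwise coupling, element-derived TSS
fractions, active-mark coverage, planted motif words — so the whole
pipeline is testable closed-loop without downloads.

## Worked example

```r
library(RegulaTE)

bundle <- simulateAll(fixtureSpec(rngSeed = 1))

bs <- bindingSummary(bundle$elements, bundle$sitesByTf, 0.5)
bs
#> BindingSummary: 40 of 40 elements bound (100.0%) by 4 TFs
round(pctOfBound(bs), 1)
#>  ESR1 FOXA1   MYC  E2F1
#>  77.5  80.0  62.5  82.5

prof <- tfbsMetaProfile(bundle$elements,
                        sort(Reduce(c, unname(bundle$sitesByTf))),
                        analysisConfig())
prof
#> MetaProfile [TFBS] : 200 bins x 100 bp, averaged over 40 elements, oriented 5'->3'
sum(profileValues(prof))
#> [1] 1

tx <- bundle$transcripts
tr <- grFromBed(tx$chrom, tx$start, tx$end, tx$strand,
                foldChange = tx$fold_change, pValue = tx$p_value)
cls <- classifyTranscripts(tr)
tssEnrichmentTest(transcriptTss(tr[cls == "up"]), bundle$elements,
                  bundle$chromSizes, nPerm = 10000, seed = 1)
#> EnrichmentResult: 74 / 200 TSSs in elements; expected_p = 0.0802 (10000 permutations)
#>   enriched, binomial p = 2.54e-30
```

Every TF binds 60–85% of bound elements because the generator concentrates
sites in the 900 bp 5' subregion; the meta-profile's unit mass is the
conservation property the averaging guarantees; and 74/200 up-regulated
TSSs inside elements against an expected 8% is the planted promoter excess
the rotation-binomial test detects.

There is also a thin command-line front end over the same functions:

```sh
Rscript inst/scripts/repeat-regprof.R simulate --out fixture --seed 4
Rscript inst/scripts/repeat-regprof.R coloc --repeats fixture/repeats.tsv \
    --tfbs fixture/tfbs --out coloc_out
```

Subcommands: `simulate`, `profile`, `coloc`, `epi`, `tss-enrich`,
`motif`. Each writes TSV/JSON results plus a `manifest.json` with the
config snapshot, input digests and seed.

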