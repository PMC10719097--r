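---
title: "Trio-based haplarithmisis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based haplarithmisis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplarith)
```

## The problem

Bulk DNA from a product of conception (POC) is genotyped on a SNP array
together with both parents, in two tissues: chorionic villi (CV,
trophoblast-derived) and extra-embryonic mesoderm (EM, embryoblast-derived).
The goal is to detect chromosomal imbalances that conventional karyotyping
misses — often mosaic, often confined to one tissue — and to annotate each
with its copy state (gain, loss, copy-neutral uniparental disomy), the
parent that contributed the abnormal chromosome dose, the segregational
mechanism (meiosis I, meiosis II, or a post-zygotic mitotic error) and the
fraction of aberrant cells.

The raw observables per SNP are the genotype call, the B-allele frequency
(BAF; the share of total allele signal carried by the B allele) and the logR
ratio (log2 of observed over expected total intensity, roughly
`log2(CN/2)` for copy number CN).

## The haplarithm model

Haplarithmisis transforms the continuous BAF values of the POC tissues into
four *phased* series whose band structure encodes copy number and homolog
identity.

1. **Informative SNPs.** A SNP is informative when one parent is
   heterozygous (AB) and the other homozygous; father-AB SNPs form the
   paternal category, mother-AB SNPs the maternal category. Double
   heterozygous SNPs carry no parent-of-origin information and are
   excluded.
2. **Seed phasing.** At each informative SNP the transmitted allele of the
   heterozygous parent is deduced Mendelianly from the CV genotype and the
   homozygous parent's genotype (CV is the phasing seed; the EM sample is
   interpreted against the CV-derived phase). The deduced transmitted
   allele defines homolog H1 of that parent. SNPs whose CV call is
   impossible given the parents are flagged, excluded and counted — their
   distribution carries signal (see *Degenerate presentations*). More than
   5% genome-wide inconsistency aborts with a non-paternity/contamination
   error.
3. **Subcategories.** A paternal-category SNP goes to P1 when the
   transmitted paternal allele equals the mother's (homozygous) allele —
   the seed child is then homozygous there — and to P2 otherwise; M1/M2
   symmetrically.
4. **Mirroring.** BAF values are reflected around 0.5 where the phased
   parental genotype reads BA (transmitted allele B). After mirroring, a
   euploid conceptus shows P1 at 0 and P2 at 0.5 on every chromosome, and
   likewise M1/M2.
5. **Segmentation.** Each series is segmented by exact piecewise constant
   fitting (PCF) with penalty `gamma = 14`, giving fitted band levels and
   breakpoints (candidate crossovers and copy-number boundaries).

### Band separations

The separation between the two fitted band levels of a parental series —
`d_pat = |P1 − P2|`, `d_mat = |M1 − M2|` — combined with logR is
characteristic of each state. With aberrant-cell fraction `f`, allele-count
enumeration of the mixture gives:

| state (origin = maternal)    | d_pat           | d_mat           | logR           |
|------------------------------|-----------------|-----------------|----------------|
| disomy                       | 1/2             | 1/2             | 0              |
| trisomy (CN 3)               | (1+f)/(2+f)     | 1/(2+f)         | log2(1+f/2)    |
| tetrasomy (CN 4)             | (1+2f)/(2+2f)   | 1/(2+2f)        | log2(1+f)      |
| monosomy (maternal lost)     | (1−f)/(2−f)     | 1/(2−f)         | log2(1−f/2)    |
| isodisomic UPD               | (1+f)/2         | (1−f)/2         | 0              |

(Paternal origin swaps the two d columns.) At `f = 1` a maternal trisomy
reads (0.67, 0.33) with logR ≈ 0.58 — the textbook signature. Note the
distortion appears most strongly in the *other* parent's series: the
non-origin parent's heterozygous band is the quantity inverted for the
mosaic fraction:

* gain: `f = 4Δ/(1 − 2Δ)` (CN 4: `f = 2Δ/(1 − 2Δ)`),
* loss: `f = 4Δ/(1 + 2Δ)`,
* copy-neutral UPD: `f = 2Δ`,

with `Δ = |band − 0.5|`. These closed forms and the simulator's mixture
bands are exact inverses, which the tests verify as a round-trip identity.
The UPD band reaches `Δ = 0.5` exactly at `f = 1`; only `Δ > 0.5` is out of
domain.

### Segregational origin

Whether the two copies contributed by the origin parent are different
homologs (BPH, both parental homologs) or the same homolog (SPH) is read
off the origin parent's own series, region by region between PCF
breakpoints: SPH regions show bands at `{0, 1/(2+f)}`, BPH regions at
`{f/(2+f), (1+f)/(2+f)}`. BPH at the centromere means meiosis I; SPH at
the centromere with BPH distal to a crossover means meiosis II; SPH along
the whole chromosome means a mitotic (post-zygotic) error. Because SNP
coverage immediately around the centromere is sparse, the centromeric
composition is taken from the typed region whose supporting SNPs lie
nearest the centromere, not from strict interval containment. Monosomies,
isodisomies of a single transmitted homolog, and segmental duplications are
SPH by construction and are labelled mitotic; this matches how such events
present in POC tissues.

### Degenerate presentations

Seed phasing has a consequence the naive band algebra misses: when the CV
sample itself carries the aberration at high fraction, the seed genotypes
are distorted in a *systematic* way.

* On a fully BPH trisomic chromosome every maternal-informative SNP looks
  heterozygous in CV, so the phase routes all of them into M2 and the
  own-series separation collapses to a single band. Classification
  therefore also admits "own-series collapsed" gain templates.
* A full monosomy or isodisomy makes about half of one category's SNPs
  Mendelian-impossible; the surviving series collapse and `d` reads
  (0, 0). The state is then carried by logR (−1, 0) and the *side* of the
  Mendelian inconsistencies identifies the parent: a lost maternal homolog
  produces failures among paternal-informative SNPs, a maternal isodisomy
  among maternal-informative SNPs. A degenerate-looking call without this
  corroborating failure pattern is discarded rather than guessed.

### Copy-number parsimony

A double gain (CN 4) at fraction `f/2` occupies exactly the same band
positions and logR as a single gain at `f` — the two are mathematically
indistinguishable in bulk BAF data (which is why tetrasomies against a
triploid background are confirmed by qPCR, not by the array). CN 4 is
therefore a strictly secondary hypothesis, chosen only when no CN ≤ 3
template fits: a non-mosaic tetrasomy (d = 0.75, logR = 1) is still
recognized, while a 50% mosaic tetrasomy is reported as the equivalent full
trisomy.

## Tunable parameters

* `gamma` (default 14): PCF breakpoint penalty, applied to residuals
  standardized by a robust noise estimate (MAD of first differences /
  sqrt 2), so that the same penalty works across noise levels; the
  standardization can be disabled. The noise estimate is floored at 1e-4 so
  that noise-free series segment correctly.
* `min_snps` (default 20): minimal informative SNPs per series per
  chromosome (and per candidate region); below it the series is "not
  determined". Regions used for SPH/BPH typing need only 4 SNPs because
  such a region has already earned a dedicated PCF segment against the
  penalty.
* `tol_d` (0.08) and `tol_logr` (0.15): template acceptance tolerances,
  chosen so that noise-free classification is exact while BAF noise of
  sd 0.05 is tolerated.
* `f_min` (0.10): calls with a smaller estimated mosaic fraction are
  suppressed — the stated sensitivity floor of the method.
* Segmental calls require ≥ 100 kb span *and* ≥ 20 informative SNPs.
* Monosomy origin labelling (`monosomy_origin`): by default the named
  parent is the one whose homolog is *lost*. The opposite convention
  ("retained") exists in the literature describing the same event, so the
  labelling is configurable rather than hard-coded.

## The synthetic-data generator

The simulator emulates the full causal chain: parental haplotypes drawn
Bernoulli(population BAF) on a reduced-density scaffold (default 2,000
SNPs per chromosome over 1–22 and X; real arrays are ~14× denser),
meioses with one crossover per arm at uniform positions (the recombination
landscape is deliberately simple), controlled segregation errors (MI: the
two transmitted chromatids anchor on different homologs at the centromere;
MII: sister-derived chromatids sharing the centromere and differing distal
to at least one exchange — each crossover involving a given chromatid with
probability 1/2), post-zygotic events as duplication/loss of a transmitted
homolog, mixture rendering with per-tissue aberrant fractions, maternal
contamination as a diploid admixture, Gaussian BAF/logR noise (defaults
0.03 / 0.10), and genotype calls from the noise-free BAF with
cluster-style thresholds (AA < 0.15, BB > 0.85, AB within [0.25, 0.75]).
The wide AB band matters: array callers assign the 1/3 and 2/3 clusters of
a trisomic sample to the heterozygous cluster, and with a narrower band a
trisomic seed could not be phased at all — the pipeline would not
reproduce the 0.67/0.33 signature on its own simulator.

What the generator does **not** emulate: wave artifacts and GC bias in
logR, signal compression (real trisomy logR sits near the ideal 0.58 only
after scaling), probe-specific noise, genotyping-error rates in the
parents, cell-culture artifacts, and linkage-disequilibrium structure in
the parental haplotypes. Passing tests therefore demonstrate correctness
of the method's logic under its own generative assumptions, not
performance on any particular array product.

Triploidy is simulated as retention of a second maternal meiotic product
(MII-like), which reproduces the observed pattern that some chromosomes of
a digynic triploid present as MII and others (those without a
distinguishing exchange) as mitotic; a mitotic whole-genome doubling
variant is also available.

## Numerical and degenerate-input choices

* PCF is the exact O(n²) dynamic program, not a heuristic; ties are broken
  toward fewer segments, then toward the longest final segment. It is
  tested against exhaustive enumeration of all 2^(n−1) segmentations for
  n ≤ 12.
* Band separations are medians over breakpoint-delimited regions where
  *both* series of a pair carry SNPs, so that a series absent from a
  region (the degenerate presentations above) cannot drag the estimate.
  A pair with one genuinely depleted series reads d = 0; "depleted" is
  judged on present SNPs, not on fitted ones, so a sparse region is "not
  determined" rather than collapsed.
* Whole-chromosome aberrations can come out fragmented when logR noise
  introduces spurious breakpoints; fragments sharing state and origin that
  span ≥ 80% of the chromosome are consolidated into one chromosomal call.
* A genome-wide label (triploidy/tetrasomy signature) requires consistent
  same-origin gains on at least 20 autosomes, scaled down to "all
  autosomes present" on reduced scaffolds.
* Chromosome X: the father is hemizygous, so no paternal-informative SNPs
  exist; X calls rest on the maternal series, logR and the
  Mendelian-failure side, and a copy-neutral claim on X without positive
  failure evidence is not made.

## Contamination screening

Maternal-cell contamination is estimated *before* phasing-dependent steps,
from the BAF of parental-informative SNPs only: at contamination `c` the
maternal-informative clusters sit at `{c/2, 0.5}` and the
paternal-informative clusters at `{0, (1−c)/2}` (oriented so the
homozygous parent's allele is A). Because the two clusters are occupied
about equally under Mendelian transmission, the lower quartile of the
maternal-informative BAF tracks `c/2` and the upper quartile of the
paternal-informative BAF tracks `(1−c)/2`; a step-0.01 grid search matches
both, per chromosome, combined by the median. The estimator is
deliberately independent of the seed phase: a completely contaminated
sample phases "successfully" (the seed is the mother), and any
phase-dependent expectation would then fit c = 0. A sample with ĉ > 0.95
whose genotype calls match the mother's is flagged as complete maternal
contamination and excluded from calling. The quantile estimator's bias is
a small fraction of the BAF noise sd, so the 0.95 threshold is reliable at
the default noise level; at several-fold higher noise the flag would rest
increasingly on the genotype-concordance condition.

## Problem sizes used by the tests

The test suite and acceptance checks run the generator at desk scale: the
noise-free recovery grid (200 quartets across every constructible
type × parent × segregation combination) uses 6 chromosomes × 800 SNPs per
quartet — at least 6 chromosomes so that the localized Mendelian failures
of a full monosomy/UPD stay under the 5% genome-wide non-paternity
threshold — while mosaic-fraction recovery, detection-rate and
contamination checks use 2,000 SNPs per chromosome on 3 chromosomes, the
density at which the recovery tolerances are stated. The PCF oracle
comparison runs 10,000 random series with n ≤ 12 against exhaustive
enumeration.

## Known limitations

* Heterodisomic UPD (two *different* homologs of one parent, copy-neutral)
  is outside the aberration taxonomy; only isodisomy is simulated and
  called.
* Mosaic monosomies above f ≈ 0.8 enter the degenerate regime gradually
  (the heterozygous band drifts into the no-call genotype window), and
  classification between the clean mosaic template and the full
  presentation can return "not determined" in between.
* The MI/MII discrimination requires informative crossovers; a meiotic
  error on a chromosome whose transmitted chromatids happen to share all
  exchanged segments is indistinguishable from mitotic, and is labelled
  accordingly.
* Cohort-level biological findings (tissue-specific mosaicism rates,
  chromosome spectra) depend on real cohorts and are not reproduced by the
  simulator; the package reproduces the *methods* (statistics, power and
  fold-change arithmetic) that such analyses use.
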