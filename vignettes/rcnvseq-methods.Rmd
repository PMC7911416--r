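---
title: "rcnvseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rcnvseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnvseq)
```

## The measurement model

Low-pass whole-genome sequencing estimates copy number from read
dosage. A few million uniquely mapped short reads are scattered across
the genome; when uniquely mapped, non-duplicate reads are counted in
fixed 20-kb bins, the count in bin $i$ is well approximated by

$$c_i \sim \mathrm{Poisson}\!\left(d \cdot \frac{\mathrm{CN}_i}{2}
\cdot b(\mathrm{gc}_i)\right),$$

where $d$ is the expected count per disomic bin, $\mathrm{CN}_i$ the
local copy number and $b(\cdot)$ a mild GC-dependent efficiency. The
pipeline inverts this: estimate and divide out $b$, scale so that the
autosomal disomic state sits at $\mathrm{CN} = 2$, and classify
deviations. A mosaic aberration carried by a cell fraction $f$ with
$c$ copies has expectation $\mathrm{CN} = 2(1-f) + c f$, which is also
how the caller inverts a mosaic segment's mean CN into a fraction
estimate.

At the reference conditions used throughout the package's tests —
30 reads per 20-kb bin — the per-bin CN noise is
$\sigma = 2/\sqrt{30} \approx 0.37$ at disomy, which sets every
downstream design constraint: single bins are far too noisy to
classify, but a 5-bin (0.1 Mb) heterozygous deletion already deviates
from disomy by about six standard errors of its mean.

## What the simulator emulates — and what it does not

The count tier draws the Poisson model above directly and is used by
most tests: it is fast, bit-reproducible for a seed, and carries an
exact truth record (per-bin expected CN, CNV coordinates, mosaic and
contamination fractions). The read tier additionally exercises the
sequencing-QC surface: raw 45-bp reads carrying a 36-bp genomic insert
and a 9-bp adapter, per-base qualities from a two-state high/low model
(94% high-quality by default, so Q30 is a meaningful statistic),
unique mapping with probability 0.62 (unique-mapping ratios of this
library type are stable around 60–65%), the remainder split between
multi-mapped and unmapped, and duplicates that re-emit an earlier
read's mapped position — which is exactly the event the redundancy
ratio counts downstream. Maternal cell contamination is emulated at
the count tier by binomial thinning,
$\mathrm{Bin}(c^{fet}_i, 1-f) + \mathrm{Bin}(c^{mat}_i, f)$, whose
expectation is the $f$-mixture while counts stay integers.

Deliberately **not** modelled: base-call substitution errors, insert
fragmentation chemistry, mappability structure derived from real
sequence (exclusion lists are inputs), and reference-genome sequence
itself — read sequences are drawn base-wise from the source bin's GC
fraction. Passing tests therefore demonstrate the statistical
behaviour of the pipeline under its own measurement model, not
robustness to alignment artefacts of a real genome.

The GC-bias multiplier is a quadratic normalised to 1 at GC 0.40,
$b(g) = 1 + a_1(g-0.4) + a_2(g-0.4)^2$, with coefficients 0 by
default: GC effects on real libraries are qualitative and
protocol-dependent, so the simulator exposes a shape rather than
asserting one.

## Binning and masking

Each chromosome is tiled with `floor(L/20000)` full bins; the trailing
partial bin is dropped rather than truncated, because variable-width
bins would bias both the coverage CV and the CN estimate. Reads are
assigned by their 5' coordinate (1-based input, 0-based half-open bins
internally; 36-bp reads against 20-kb bins make the midpoint/start
choice immaterial, but it must be fixed). Every input read is
accounted for: assigned + off-grid + partial-bin + filtered equals the
table length, and a brute-force per-read interval search is the oracle
test for the vectorised counting.

Bins overlapping any excluded interval (by a single base) are masked,
as are bins with GC outside [0.28, 0.60]; masked bins receive counts
in simulation — excluding them is the pipeline's job — but carry no CN
and never enter any statistic. Toy genomes always include a centromere
and at least one excluded region per chromosome so the masking path is
always exercised.

## Normalization

GC correction divides each count by its stratum factor,
`median(counts in GC stratum)/median(all counts)`, with strata of
width 0.01 and a minimum of 10 bins per stratum (smaller strata borrow
the nearest populated stratum's factor). The stratified-median design
is robust to CNVs occupying part of a stratum and reduces to the
identity for a flat GC landscape.

The CN scale is set within-sample: $m$ is first the median corrected
count over unmasked autosomal bins, then refined by an iterated
trimmed mean over bins within 2.5 robust SDs of $m$ (the robust SD
comes from successive differences, so the trimmed set is exactly
invariant to count rescaling and insensitive to the level shifts real
CNVs introduce). The refinement matters: with integer counts the
median can sit a whole count off the Poisson mean — about 3% at 30
reads/bin — which is enough to push disomic bins visibly off CN 2;
the trimmed mean is continuous and, at 2.5 SDs, excludes single-copy
changes while keeping trimming bias below half a percent. A
whole-chromosome trisomy among ~20 autosomes moves the final baseline
by well under 2% (this is a tested property). A panel-of-normals hook
was considered and left out: the package's scope is single-sample
analysis, and the within-sample baseline is what the simulation model
justifies.

Sex chromosomes never enter the baseline. Sex is inferred from dosage
before any X call is made: Y CN below 0.2 reads as absence of Y, X and
Y CN within 0.3 of an integer pattern give the composition (XX, XY,
XO, XXY, XXX, XYY, ...), otherwise the sex is flagged undetermined.

## Segmentation and classification

Classification is a total, piecewise-constant function with the
clinical breakpoints: deletion below 1.2, mosaic monosomy to 1.8,
disomy to 2.2, mosaic trisomy to 2.8, duplication above. The published
bands are open intervals, which leaves values exactly at a threshold
undefined; `rcnvseq` assigns them to the adjacent mosaic band (the
conservative reading for a value that cannot be distinguished from
either side) and flags them `boundary`.

Segmentation works in four steps, all tunable via
`pipeline_config()`:

1. **Detection.** A running median (window 5 bins, odd by
   construction) stabilises the profile; maximal runs of consecutive
   unmasked bins whose smoothed CN lies outside the disomy band on one
   side are collected, bridging up to `gap_bins = 2` masked or in-band
   bins.
2. **Boundary refinement.** Each run edge is re-estimated on the *raw*
   CN by a local two-level change-point fit (segment level inside,
   disomy outside). The running median erodes true boundaries by up to
   half a window; the fit recovers them to about one bin at 30
   reads/bin. For established runs (≥ 15 bins) the outside misfit is
   weighted 3×, moving the per-bin inclusion threshold from the
   midpoint toward the disomy-band edge: the loss is asymmetric —
   clipping a true interval costs concordance with an orthogonal
   truth assay, while a slightly generous edge does not — and
   clinical low-pass CNV intervals characteristically run a little
   wide of array-defined coordinates. Short runs keep the symmetric
   fit so noise excursions are not inflated.
3. **Merging.** Same-side runs merge across fully masked gaps up to
   `merge_gap = 10` bins (a centromere inside a chromosome-scale
   event) and across short noise splits no longer than half of the
   shorter flanking run — long events keep their tails, short noise
   runs cannot chain.
4. **Screening.** A segment is kept only if it has at least
   `min_seg_bins = 5` member bins (0.1 Mb, the resolution floor of
   low-pass CNV sequencing) and its mean deviates from disomy by at
   least `min_seg_z = 5` standard errors, with the per-bin noise
   estimated robustly from successive differences. The z-screen is
   sized for a genome-wide scan: pure band thresholding of Poisson
   noise otherwise produces frequent spurious few-bin runs, while a
   true 0.1-Mb deletion at 30 reads/bin still scores z ≈ 6. Segment
   mean CN is computed from raw (unsmoothed) member bins, so smoothing
   affects detection, never quantification; segments whose mean falls
   back inside the disomy band are dropped.

Mosaic events at intermediate CN sit closer to the band edge and may
legitimately fragment into several same-state segments; concordance
scoring uses the union of same-side calls, and the mosaic fraction of
the dominant piece recovers the simulated fraction.

A chromosome with more than 90% of its unmasked bins outside the band
on one side is reported as a whole-chromosome gain or loss.
Sex-chromosome segments are judged against the *inferred* ploidy
(dosage rescaled by 2/ploidy): a male X at CN 1 or an absent Y is
normal dosage, while a real deletion on a single X is still called.

The karyotype string follows the clinical reporting dialect exactly as
it appears in diagnostic result tables, including its inconsistency:
euploid samples print `"46,XN"` (fetal sex masked unless
`report_sex = TRUE`), autosomal aneuploidies print without the comma
(`"47XN,+21"`), and abnormal sex compositions are spelled out
(`"45,XO"`, `"47,XXY"`). ISCN-style segment names take the cytoband of
each endpoint (`"5p15.33-p13.3(del, 31.90 Mb)"`, single-band events
print the band once) with a coordinate fallback when no cytoband table
covers the segment; sizes are megabases to two decimals.

## Concordance and the MCC gate

For each truth interval the primary score is
$100 \times |{\rm union\ of\ same\text{-}side\ calls} \cap
{\rm truth}| / |{\rm truth}|$: the truth (array-defined) interval is
the denominator because the benchmark asks how much of the known event
the sequencing assay recovered, and fragmentation that preserves
covered bases should not be penalised. Because that formula is a
reconstruction — published comparisons describe the scheme only
pictorially — the reciprocal overlap of the best single call is
reported alongside, with separate exact-state and integer-CN agreement
flags. Same-*side* credit (deletion and mosaic monosomy both count
toward a loss truth) reflects that del-vs-dup identity, not mosaic
degree, is what the orthogonal assay confirms. A brute-force per-base
membership count is the oracle test.

Maternal cell contamination is estimated from semi-quantitative STR
peak heights: at an informative locus (a maternal allele absent from
the fetal genotype) the maternal-specific peak carries half of the
maternal contribution's dosage — the specific allele is heterozygous
in the mother, since the fetus inherits her other allele — so the
contamination fraction is $2 h_{\rm specific}/\sum h$ and the reported
MCC is 100 × the median over informative loci. The clinical gate is
strict: below 5% passes, exactly 5% fails. With no informative locus
the estimate is undefined and the gate's verdict is configurable
(default: pass with a warning, since an uninformative assay is not
evidence of contamination).

## Problem sizes and numerical choices

The test and validation studies run on toy genomes of 46–86 Mb
(2,300–4,300 bins) at 30 reads per bin with 10–50 seeded replicates
per claim — sizes chosen so that every statistical property under test
(baseline accuracy to ~1%, chromosome-level CN to ±0.15, boundary
recovery to ±3 bins, truth coverage ≥ 93%) is resolvable against
Poisson noise, while a full simulated sample runs in well under a
second. The reproducibility panel places one CNV per sample on a 44-Mb
submetacentric host chromosome (long p arm, so the largest 31.8-Mb
deletion does not cross the centromere, matching the geometry of the
classical 5p deletion syndromes) over ten 4-Mb support autosomes that
anchor the baseline; the panel genome uses a flat GC landscape because
the panel is defined with GC bias off. Population (not sample) SD is
used in the coverage CV; with thousands of bins the difference is
negligible but the convention must be fixed for exact tests.
Count-tier simulation, calling and serialisation are deterministic
given a seed; the CLI's `simulate` writes byte-identical files for
identical arguments.

## Known limitations

* Read-depth only: no allele-frequency (SNP) evidence, so balanced
  events and low-fraction mosaics below the dosage resolution are
  invisible.
* The statistical guarantees are stated at ≥ 30 reads/bin; at
  substantially lower depth the z-screen will (correctly) withhold
  small calls, and the QC verdict flags median depth below 10.
* Sex-chromosome ploidy adjustment keys on the inferred whole-
  chromosome pattern; a structurally abnormal X in an otherwise
  XO-looking sample would be folded into the ploidy call rather than
  reported separately.
* The simulator's truth model is the pipeline's own measurement model;
  agreement demonstrates internal consistency and statistical
  correctness, not robustness to real-genome alignment artefacts.
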