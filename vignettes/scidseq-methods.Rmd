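---
title: "scID-seq data processing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scID-seq data processing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scidseq)
```

## The assay and its data model

Single-cell Immuno-Detection by sequencing (scID-seq) quantifies dozens of
proteins and phospho-proteins per cell by staining cells with
antibody-DNA conjugates, FACS-sorting single cells into the wells of a
96-well plate, and sequencing the antibody tags. Each read carries three
informative segments: a **well barcode** identifying the plate well (hence
the cell), a **10-nt antibody barcode** identifying the epitope, and a
**15-nt unique molecular identifier (UMI)** distinguishing molecules so
that PCR duplicates collapse to a single count. The quantity of interest
is therefore the number of *distinct UMIs* per (well, antibody) pair.

Segment positions are configurable through a read layout (0-based,
half-open coordinates) because the library architecture — in particular
whether the well barcode sits in-line or arrives on an indexing primer —
varies between implementations of the protocol. The default layout is a
single in-line read: well barcode at 0–8, antibody barcode at 8–18, UMI at
18–33. The 8-nt well-barcode length is likewise a free parameter of both
the parser and the simulator.

## Barcode demultiplexing

Antibody and well barcodes are matched against their whitelists with
Hamming-tolerant lookup. For a tolerance of $m$ mismatches we enumerate
the full radius-$m$ substitution neighborhood of every whitelist entry
once and resolve each observed string by hash lookup; a string claimed by
two entries at the same minimal distance is *ambiguous* and rejected, not
assigned to either. This is exact: a read matches within $m$ mismatches
if and only if its barcode lies in some entry's neighborhood.

Unambiguous correction of up to $m$ errors requires the whitelist's
minimum pairwise Hamming distance to be at least $2m + 1$; the
demultiplexer verifies this before touching any read and refuses
error-tolerant matching on panels that violate it. Barcode panels are
designed as discrete, well-separated code words, so ambiguity beyond the
design tolerance signals an error that should be dropped rather than
guessed — the package never assigns a read by plurality or abundance.
Defaults: 1 mismatch for antibody and well barcodes; UMIs are never
corrected in the default mode.

Every read lands in exactly one tally of the demux report (too short /
well unassigned / antibody unassigned / assigned), so the tallies always
sum to the number of input reads — a conservation property the tests
enforce on every simulated dataset.

### UMI collapse

The default collapse is **exact identity**: the count is the cardinality
of the UMI set per (well, antibody). This is the conservative choice and
is directly checkable against a brute-force set-size oracle. An optional
**directional** mode additionally absorbs a UMI into a single-mismatch
neighbor when the neighbor's read count is at least $2c - 1$ (greedy, in
descending count order), which guards against UMI sequencing errors at
the cost of slight undercounting. With 15-nt UMIs and tens to hundreds of
molecules per (well, antibody), UMI collisions are negligible
($4^{15} \approx 10^9$ sequences).

## Background, filtering, and normalization

Wells that received no sorted cell ("empty wells") measure technical
background: ambient antibody, carry-over, and index hopping. The QC
report summarizes per-well UMI totals with **medians** (robust to the
occasional outlier well): fold separation = median cell total / median
empty total, background fraction its reciprocal. A healthy plate shows
roughly 100-fold separation, i.e. ~1% background.

The default cell filter keeps cell wells whose total is at least **10×
the median empty-well total, with a floor of 500 UMIs**. The published
protocol defers its exact QC rule to supplementary material not
reproduced here, so this policy is a stated stand-in motivated by the
100-fold separation (a 10× guard band above background), not the original
rule; the threshold actually applied is always recorded in the QC report.

Sequencing-depth normalization is **rarefaction**: an equal number of
UMIs is drawn *without replacement* from each cell's observed UMI
multiset — a multivariate hypergeometric draw per cell. Without
replacement matches the physics (UMIs are discrete molecules; a
subsample is a subset of them), makes row totals exactly equal, and
bounds every subsampled entry by its original value. The default depth is
the minimum retained cell total, which discards no cells. Draws are
seeded and bit-reproducible.

After subsampling, each antibody is **min-max scaled to [0, 1] across
cells** so that abundant epitopes do not dominate PCA and testing; this
scaling is idempotent and zero-variance columns are set to zero with a
warning. For phospho epitopes with a measured total-protein partner, the
per-cell **phospho/total ratio** $(p + 1)/(t + 1)$ (pseudocount 1,
configurable) corrects phosphorylation signal for protein abundance; it
is computed on subsampled integer counts, before scaling.

The pipeline order is fixed: filter → subsample → {scale | ratio}.

## Pseudo-time ordering

Cells are ordered by PCA on six anchor markers with established
directional dynamics during epidermal differentiation: ITGB1, ITGA6 and
TP63 fall; NICD, KLF4 and TGM1 rise. Design choices here were genuinely
open and are resolved as follows:

* **Covariance PCA on the scaled values, mean-centered only.** The 0–1
  scaling is the equalization step; re-standardizing to unit variance
  would amplify markers whose variation is mostly noise. Whether the
  original analysis standardized is unstated; this is our choice and it
  is documented as such.
* **Orientation.** A principal component's sign is arbitrary. We fix it
  biologically: the sign of PC1 is chosen so that pseudo-time correlates
  positively with TGM1 (late differentiation); an exactly-zero
  correlation falls back to negative correlation with ITGB1, and if both
  anchors are uninformative the orientation is kept and flagged
  ambiguous. The oriented scores are min-max scaled to [0, 1].
* **Binning.** Cells are sorted by pseudo-time and grouped into
  consecutive 10-cell bins (rank-based, hence invariant to input order;
  ties broken by input position). A trailing remainder smaller than half
  a bin merges into the previous bin — an invented policy, since 220
  cells divide evenly by 10.
* **Trend fits.** Per-epitope bin means are fitted with unweighted
  ordinary least squares cubics against per-bin mean pseudo-time
  (coefficients in ascending degree order, $R^2$ clipped at 0). Fitting
  bin means, not single cells, matches what the binned dynamics plots
  display. A constant profile returns $(\bar y, 0, 0, 0)$ with $R^2 = 0$.

## Differential epitope testing

Each epitope is compared between the two FACS gate populations (ITGB1+
vs ITGB1low) with the two-sample Kolmogorov–Smirnov test. $D$ is computed
by evaluating both empirical CDFs at the pooled sorted values, which
handles ties exactly. The two-sided p-value uses the asymptotic
Kolmogorov distribution with the standard effective-sample-size
correction $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$,
$n_e = n_a n_b/(n_a+n_b)$; at the study's group sizes (163 vs 57) this is
comfortably in the asymptotic regime and empirically calibrated (the test
suite verifies a type-I error of 0.04–0.06 at $\alpha = 0.05$ under the
null). Selection uses the raw $p < 0.001$ rule with **no multiple-testing
correction**, for fidelity to the published selection; Benjamini–Hochberg
q-values are reported alongside as an informational column. Tests run on
the scaled matrix by default (the state shown in the published
distribution plots); whether the original analysis tested scaled or
subsampled values is unstated, and a different state can be passed
explicitly. A pathway is reported *concordant* when at least two of its
antibodies are significant and their fitted trend directions (sign of the
cubic at $t=1$ minus $t=0$) agree.

## The synthetic-data generator

Because the raw sequencing data are not available, the package ships a
ground-truthed simulator that emulates the study design and makes every
stage testable end to end:

* **Plate**: 84 cell wells + 48 empty wells (the published plate
  geometry), well barcodes drawn at pairwise Hamming distance ≥ 3.
* **Panel**: 69 antibody-DNA conjugates — the six anchor markers plus 11
  phospho/total pairs, 23 further phospho epitopes (34 phospho in total)
  and other targets, with pathway-group labels; barcodes at distance ≥ 3
  so 1-mismatch correction is sound.
* **Trajectory**: latent time uniform on [0, 1]; marker means follow
  logistic curves in their known directions with staggered midpoints
  (0.35–0.65), giving the distinct kinetics the assay resolves; 30% of
  non-marker antibodies get mild (2-fold) random dynamics, the rest are
  static. FACS gates derive from latent time with a cut at 0.7,
  reproducing the roughly 3:1 ITGB1+/ITGB1low imbalance of the sorted
  dataset.
* **Counts**: negative-binomial around the trajectory-modulated means
  (dispersion 10 by default; overdispersion is the norm for molecular
  counts, and the Poisson limit is available), with log-normal per-cell
  depth (sd 0.15) around a mean of 3000 UMIs per cell. Empty wells are
  Poisson with expected total = 1% of the cell expectation.
* **Reads**: every molecule gets a distinct random 15-nt UMI (distinct
  within its (well, antibody) group), is amplified into
  $1 + \mathrm{Poisson}(2)$ reads, per-base substitutions are applied at
  rate $10^{-3}$, and reads are shuffled. An optional mode injects
  exactly one substitution into every antibody barcode to exercise error
  correction.

No distributional statement exists for the real counts, so the
generator's families and defaults are package choices, chosen once as
realistic for plate-based antibody counting at moderate depth, and
exposed in the configuration. Under the defaults the full pipeline
recovers the latent ordering with Spearman $|\rho| \gtrsim 0.94$ and the
configured background within a few percent relative error — properties
the acceptance tests assert at fixed seeds.

What the simulator does **not** emulate: quality-score profiles and
adapter read-through, doublets, batch effects across plates, antibody
cross-reactivity, and ambient-contamination structure beyond a flat
Poisson background. Passing tests therefore demonstrate algorithmic
correctness and calibration on a faithful but idealized generative
model, not robustness to every artifact of real libraries.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere; ranks are 1-based (the R
  convention) and always a permutation of $1..n$.
* Subsampling, simulation and the pipeline derive all randomness from
  explicit integer seeds and restore the caller's RNG state.
* Degenerate inputs prefer flags and warnings over silent coercion:
  too-short reads are flagged, constant columns scale to zero with a
  warning, plates without empty wells yield an NA background with a
  warning, an all-filtered plate is an error naming the threshold.
* Ambiguity (barcode ties, zero orientation correlations) is surfaced,
  never resolved by guessing.

## Problem sizes in the test suite

The shipped tests run the complete read-level pipeline at the full study
geometry (84 + 48 wells × 69 antibodies, ≈ 7.5 × 10^5 reads), pseudo-time
recovery at 220 cells, K-S calibration with 2000 null replicates at
n = 163 vs 57, and a 5 × 9 replicate-barcode design at high depth; unit
tests use smaller plates (tens of wells, hundreds of UMIs per cell) with
the same code paths. These sizes were chosen to exercise the study
design faithfully while keeping the suite fast enough to run routinely.

## Known limitations

* The cell-filter policy is a documented stand-in for an unpublished QC
  rule; on real data it should be revisited against the observed
  empty-well distribution.
* Pseudo-time is a single linear component of six markers: adequate for
  one dominant differentiation axis, but not for branching trajectories
  or subpopulation structure (several epitopes are visibly multimodal;
  no mixture model is applied).
* The directional UMI collapse is a greedy approximation of
  network-based deduplication, appropriate at scID-seq depths but not
  validated for very deep libraries.
* Asymptotic K-S p-values are slightly conservative at small group
  sizes; an exact permutation computation is available behind a flag for
  `n_a * n_b <= 10000` but is not the default.
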