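# scidseq

Processing and analysis of **single-cell Immuno-Detection by sequencing
(scID-seq)** experiments: highly multiplexed protein and phospho-protein
quantification in FACS-sorted single cells via DNA-barcoded antibodies.
The package takes an experiment from raw single-end reads to per-cell
protein count matrices, and from there to a pseudo-time ordering of
differentiation with per-epitope dynamics and differential statistics.
It is written for groups running plate-based antibody-barcoding assays
(scID-seq and close relatives) who need a tested, reproducible,
end-to-end pipeline — and, because raw data for the original study are
not public, it ships a ground-truthed simulator so every stage is
verifiable without external data.

## What it computes

Each read carries a well barcode (default 8 nt), a 10-nt antibody
barcode, and a 15-nt unique molecular identifier (UMI). The pipeline:

1. **Demultiplexes** both barcodes with Hamming-tolerant,
   ambiguity-rejecting whitelist matching (correcting up to *m*
   mismatches requires whitelist min distance ≥ 2*m* + 1, which is
   checked), and **counts distinct UMIs** per (well, antibody):
   count(w, a) = |{UMI : reads assigned to (w, a)}|.
2. **Estimates technical background** from empty wells (median empty
   total / median cell total) and filters low-coverage cells.
3. **Normalizes depth by rarefaction** — an equal number of UMIs drawn
   without replacement per cell (multivariate hypergeometric) — then
   **min-max scales** each antibody to [0, 1] across cells, and forms
   **phospho/total ratios** (p + 1)/(t + 1) for paired epitopes.
4. **Orders cells** by PCA on six anchor markers (ITGB1, ITGA6, TP63
   down; NICD, KLF4, TGM1 up): pseudo-time is the oriented, min-max
   scaled PC1 score; cells are smoothed in 10-cell bins and every
   epitope's bin-mean profile is fitted with a third-order OLS
   polynomial.
5. **Tests each epitope** between the sorted ITGB1+ and ITGB1low
   populations with the two-sample Kolmogorov–Smirnov statistic
   D = sup_x |F̂_a(x) − F̂_b(x)| (pooled-point evaluation, asymptotic
   p-values with the effective-n correction), selecting dynamic epitopes
   at p < 0.001 and reporting pathway-level concordance.

The simulator generates the complete study design — 84 cell + 48 empty
wells, 69-antibody panels, ~1% background, PCR duplication, sequencing
errors, and a latent differentiation trajectory — as FASTQ plus ground
truth, fully determined by one seed.

## Worked example

Simulate a full experiment and run every stage (this is the in-package
pipeline; a thin CLI with the same stages is installed at
`system.file("scripts", "scidseq", package = "scidseq")`):

```r
library(scidseq)
res <- run_pipeline(list(seed = 7, simulate = list()), out_dir = "run1")
res$demux_report
#> scid demux report:
#>   n_reads_total        741224
#>   n_too_short          0
#>   n_well_unassigned    21
#>   n_ab_unassigned      29
#>   n_assigned           741174
#>   n_ab_corrected       7298
#>   n_well_corrected     5960
res$qc
#> scid QC report:
#>   cell wells: 84 (median total 2960)
#>   empty wells: 48 (median total 31)
#>   fold separation: 95.5   background fraction: 0.0105
#>   filter: threshold 500, retained 84, dropped 0
res$pseudotime
#> scid_pseudotime: 84 cells, 8 bins
#>   PC1 variance explained: 73.0% (sign flipped)
sum(res$ks$significant)
#> [1] 7
```

Reading the numbers: of 741,224 simulated reads, 99.99% were assigned,
with 7,298 antibody barcodes rescued by 1-mismatch correction; empty
wells carried 1.05% of the cell-well signal (95.5-fold separation),
consistent with the 1% background configured in the simulation; the
first principal component of the six anchor markers carries 73% of their
variance and orders the cells (its sign was flipped so pseudo-time rises
with TGM1); and 7 of 69 epitopes differ between the ITGB1+ and ITGB1low
gates at the K-S p < 0.001 threshold. `run1/` contains every table
(counts at each processing state, pseudo-time, trend coefficients, K-S
results) plus a provenance record; rerunning with the same config and
seed reproduces the tables byte for byte.

The methods, default parameters, and the design decisions behind them
are documented in `vignettes/scidseq-methods.Rmd`.

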