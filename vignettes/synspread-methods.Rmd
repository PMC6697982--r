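---
title: "Quantifying microglial involvement in alpha-synuclein transfer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial involvement in alpha-synuclein transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synspread)
```

# The scientific problem

In graft models of Parkinson's disease, naive embryonic dopaminergic neurons
are transplanted into a striatum overexpressing human alpha-synuclein
(huα-syn). Detection of huα-syn puncta inside grafted TH-positive neurons and
host Iba-1-positive microglia is the readout for cell-to-cell transfer of the
protein. Quantifying that readout, and the state of the surrounding microglia,
requires several bespoke measurements:

* a **microglial activation index** from bright-field DAB images: the
  area:perimeter ratio ("hydraulic radius") of segmented cells. Activated
  microglia are amoeboid (large area, small perimeter, high index); resting
  microglia are ramified (low index);
* an **unbiased per-cell classification** of huα-syn content from confocal
  z-stacks, summarized as the percentage of marker-positive cells containing
  transferred protein;
* **Iba-1 cell density** inside a region of interest, in cells/mm²;
* **optical-fractionator stereology** for total neuron counts with a
  predicted coefficient of error;
* a **count-matrix differential-expression workflow** (CPM filtering, TMM
  normalization, precision-weighted moderated tests, BH adjustment, and the
  derived views: reference-group z-scores, FPKM, MDS, signature overlaps,
  hypergeometric enrichment) used to characterize the LPS (pro-inflammatory)
  versus IL-4 (anti-inflammatory) striatal environment.

`synspread` implements each stage as tested, reusable functions, together
with synthetic generators that produce inputs with known ground truth, so the
whole pipeline is verifiable without any external data.

# Synthetic data: what it emulates and what it does not

Three generators define the study conditions used throughout the tests.

**Confocal stacks** (`make_confocal_stack()`): 4 channels (DAPI, green =
Iba-1, red = TH, syn), 12-bit, default 1024 × 1024 frames with 0.2 µm z-steps
over ~15 µm (75 slices). Somata are rendered as spheres, positive cells carry
bright intracellular puncta, and the clean render is degraded in the order
blur → scaled Poisson noise → additive Gaussian noise → clip/quantize. The
point-spread function is an isotropic lateral Gaussian whose axial sigma is
scaled by `pixel_size / z_step` — the simplest model to which the mask-based
operators are sensitive. The number of positive cells is exactly
`floor(n_cells * frac_positive + 0.5)`, assigned by seeded sampling without
replacement, so every stack has exact ground truth. The published
acquisition scale ("0.07 pixel/µm") is ambiguous in its units, so the
simulator exposes `pixel_size` explicitly; the default of 0.4 µm/pixel makes
the default 31-pixel averaging filter of the transfer stage span about one
soma diameter (~12 µm). Tests and the acceptance script use smaller frames
(448 × 448 × 16 z) to keep a hundred-cell benchmark affordable; the geometry
per cell is unchanged.

Not emulated: stitching, bleaching, spectral crosstalk, non-spherical somata,
or out-of-focus haze beyond the Gaussian PSF. Passing the recovery benchmarks
therefore demonstrates the correctness of the mask logic under controlled
noise, not performance on real tissue.

**Stained sections** (`make_section_image()`): ramified cells (soma disc plus
thick-line branches with secondary branchlets) and amoeboid cells (compact
discs) in DAB brown — default RGB (120, 80, 40), chosen for the low blue
intensity and high saturation the segmentation exploits — on a light
background (235, 230, 225), with additive Gaussian noise. Per-cell truth
(area, perimeter, hydraulic radius) is measured on the noise-free binary
render of each cell. Amoeboid truth indices exceed ramified ones by
construction, which is what makes the index a usable activation score.

**Count matrices** (`make_count_matrix()`): negative-binomial counts for the
study design of 4 PBS, 5 LPS and 8 IL-4 samples. Baseline abundances are
drawn on the log2 CPM scale (normal, mean 1, sd 2 — a realistic bulk RNA-seq
spread), library sizes 15–25 million, dispersion 0.1 (typical for striatal
bulk tissue), and a planted fraction of genes shifted by ±`de_log2fc`/2 in
the LPS and IL-4 means so the LPS−IL-4 contrast equals the planted effect.
Because counts are compositional, the planted fold change is recovered on
the CPM scale up to a whole-library offset; tests account for this.

# Morphometry

## Dynamic FWHM thresholds

`dynamic_threshold()` fits a single Gaussian to the 256-bin intensity
histogram by nonlinear least squares and returns the band
`[peak − FWHM/2, peak + FWHM/2]` (FWHM = 2.3548 σ). When the fit fails it
falls back to the half-maximum crossings of the smoothed histogram. A
constant image raises an explicit degenerate-histogram error.

A design choice worth spelling out: on a full section histogram the dominant
mode is the *background*, and a single-Gaussian fit will lock onto it — a
within-band mask would then select background rather than stain. The body
segmentation therefore fits the band to the **stain side of an Otsu split**
of each channel (dark side of the blue channel, bright side of saturation).
This keeps the published rule — a FWHM band per channel, OR-combined — while
making it select the stain mode it was evidently intended to select.

## Body and process segmentation

`segment_cell_bodies()` combines the blue-intensity and saturation band
masks with a logical OR, fills enclosed holes (an FWHM band admits only
~76% of a Gaussian mode, so band masks of noisy stain are sieves), labels
4-connected components, removes components under `area_min_px` (default
2000 px, tied to 60× acquisition) and components touching the image border,
and erodes the survivors (disc of radius 2 px by default) so regions conform
to cell bodies. Erosion severs thin stained processes; fragments below a
quarter of `area_min_px` are discarded as non-bodies.

`segment_processes()` recovers thin processes from the saturation channel
alone: Gaussian blur, squaring, convolution with a 3×3 Laplacian (negated so
bright ridges respond positively), retention of responses within 20% of the
maximum, the same small/border filtering, outlining, subtraction of body
pixels, dilation, and union with the body mask. The literal maximum of the
response is dominated by isolated curvature spikes at branch junctions, so
the default reference is a robust maximum (the 0.99 response quantile),
configurable back to the strict maximum.

## The hydraulic radius and its perimeter estimator

The index is area divided by perimeter. Digital perimeters are biased in
estimator-specific ways, and the bias propagates directly into the index, so
the estimator is a configuration flag with three options:

* `"contour"` (default) — the length of the half-level marching-squares
  boundary polygon. On rasterized oracles it is within ~5% simultaneously
  for a disc (A/P → r/2), an axis-aligned square (→ s/4) and a one-pixel
  strip (→ w/2, both sides counted).
* `"crofton"` — the 4-direction Crofton approximation. Accurate on discs
  and strips but ~6% high on axis-aligned squares (it shortens staircase-free
  straight edges), which is why it is not the default.
* `"pixel"` — naive exposed-edge counting; overestimates disc perimeters by
  ~27% (index ~21% low), included for comparability with legacy
  boundary-counting scripts.

Group summaries average per animal first, then report mean ± SEM across
animals; a single-animal group reports a missing SEM rather than zero.

# Transfer classification

Per stack and marker: the soma interior is flooded with a large averaging
filter and thresholded (`soma_mask()`); marker and syn channels are
thresholded per channel (`channel_mask()`); the composite positivity mask is
the AND of body, marker and syn masks (`composite_positive()`). A cell is
called positive when, in at least one z-slice, a 4-connected composite
component inside the cell reaches `min_punctum_px` pixels (default 4 —
single-pixel positives would be noise-dominated). Processing is per-slice
with a cross-slice OR, matching orthogonal-view inspection of stacks.

Two numerical guards matter in practice. First, automatic thresholds are
Otsu's method with a noise floor of `median + 6 × MAD`: Otsu always splits a
histogram, so on a stack containing *no* puncta it would threshold inside
the noise and flood the composite; the floor keeps specificity high at
`frac_positive = 0`. Second, somata merged by the wide averaging filter are
split by a distance-map watershed before per-cell scoring.

`percent_positive()` reports `100 · n_positive / n_cells` per animal and
mean ± SEM per group, mirroring the study's per-mouse sampling of at least
10 cells.

# Transcriptomics

The workflow operates on a genes × samples integer count matrix with group
labels PBS/LPS/IL4. The order of operations is: CPM filter (more than
0.1 CPM in at least 3 samples) → TMM normalization factors → group-mean
filter (mean log2 CPM > 0 in LPS or IL-4) → moderated test on the LPS−IL-4
contrast (PBS is carried through normalization but excluded from the test)
→ FDR 0.05 with a secondary |log2FC| > 1 filter.

TMM (`tmm_norm_factors()`) follows the published estimator exactly: the
reference sample is the one whose upper-quartile CPM is closest to the mean
upper quartile; per sample, M-values against the reference are doubly
trimmed (30% on M, 5% on average intensity) and averaged with inverse
approximate-variance weights; factors are rescaled to geometric mean 1.
The test suite checks exact agreement with the established implementation
and recovery of a planted composition bias within 2% at 10% asymmetric DE —
comfortably inside the estimator's ≤30% design assumption, although the
trimming bias grows toward that limit.

`de_test()` implements the precision-weighted moderated pipeline: log2 CPM
response with 0.5-count offset, per-gene OLS, a lowess trend (span 0.5) of
sqrt-standard-deviation against average log2 count, inverse fourth-power
weights interpolated at each observation's fitted log2 count, per-gene
weighted least squares, empirical-Bayes shrinkage of residual variances
toward a scaled-F prior fitted by moments (with a Newton trigamma inverse),
and two-sided moderated t statistics. On simulated data it matches the
established voom/eBayes chain to numerical precision in fold changes and to
~1e-5 in p-values (the only divergence is the pooled-variance convention
when the prior degrees of freedom are infinite).

`bh_adjust()` is the step-up definition, exhaustively checked against a
brute-force oracle. Derived views: `zscore_vs_reference()` (IL-4 mean/sd;
zero-sd genes flagged missing, never infinite), `fpkm()` (CPM over
kilobases), `mds_coordinates()` (pairwise root-mean-square of the top-500
absolute log fold changes, classically scaled to 2-D),
`signature_overlap_ratio()` (overlap of top-50 cell-type signatures with the
DE set inside the analysis universe), `hcluster()` (Euclidean/average
linkage, delegated to `stats::hclust`), and `enrich_hypergeometric()`
(one-sided tail against a fixed background with BH across categories; gene
sets are user-supplied GMT files — there are no live database queries).

Two reference figures from the deposited data of the original study are
worth noting as context for defaults (24,227 genes pass the CPM filter;
15,938 the group-mean filter); reproducing them requires downloading the
deposited counts, so the package's tests exercise the same rules on
synthetic and toy data instead.

# Stereology

`fractionator_estimate()` is `ΣQ⁻ / (ssf · asf · tsf)`. Both sampling
designs of the study ship as presets: `graft_design()` (frame 70 × 70 µm,
grid 150 × 150 µm, every 6th of 30-µm sections, 12 µm dissector, 2 µm
guards) and `nigral_design()` (frame 100 × 100, grid 200 × 200, interval 8).
The thickness fraction uses nominal cut thickness since measured mounted
thickness is rarely available; it is a parameter. `gundersen_ce()` computes
the predicted error coefficient from the counting noise `ΣQ` and the
lag-0/1/2 systematic-sampling variance term, with both smoothness classes
(`m = 0` and the default `m = 1`) available because published reports rarely
state which was used; the variance term is truncated at zero, which yields
the noise-dominated `sqrt(ΣQ)/ΣQ` limit for flat count profiles.
`simulate_point_population()` and `sample_fractionator_counts()` implement a
random-phase systematic sample from a uniform 3-D point population; over
repeated draws the estimator is unbiased (each point is counted with
probability `ssf · asf · tsf` exactly).

# Pipeline, configuration, determinism

`run_stage()` orchestrates the five stages (simulate, morph, transfer,
rnaseq, stereology) from YAML or list configs, rejects unknown keys, and
writes CSV outputs plus a JSON provenance sidecar (stage, config hash, seed,
package version). `run_demo()` generates small fixtures for all three
treatment groups, runs every stage and writes a markdown report; rerunning
with the same seed reproduces every result table byte for byte. All
randomness flows from the single seed: the generators are pure functions of
their configs. A thin command-line wrapper (`exec/synspread`) exposes the
same stages from a shell.

# Problem sizes and numerical choices

The test-suite and acceptance benchmarks use: 448 × 448 × 16 stacks with 100
cells (4 transfer-rate levels × 5 seeds = 2000 cells per benchmark);
700–900 px sections with 4–16 cells; 800-gene null matrices over 20
replicates plus a 4000-gene recovery matrix at the 5-vs-8 design; 5000-gene
TMM recovery pairs; 4000-point populations with 500 fractionator
resamplings. These sizes were chosen so a full verification runs in minutes
on a laptop while every statistical check retains enough resolution for its
tolerance (for example, 16,000 null p-values bound the type-I-error estimate
to ±0.3% at the 5% level).

Degenerate inputs are handled explicitly rather than silently: constant
images (no threshold exists), all-zero channels (empty masks, not errors),
empty segmentations (valid empty outputs), zero-sd reference genes (missing
z-scores), zero-area ROIs, zero total dissector counts, and singular designs
all have defined behavior documented on each function.

# Known limitations

* The imaging stages are validated on simulated microscopy; real DAB
  sections have stain gradients, overlapping cells and focus variation that
  the generators deliberately omit. The published erosion amount and
  histogram-fit family are unstated in the original description, so both are
  exposed as parameters with documented defaults.
* The hydraulic radius is a single scalar; it does not capture branch
  counts or Sholl-type ramification structure, and the package intentionally
  provides no such metrics.
* Statistical inference on percent-positive outcomes (negative-binomial
  mixed models) is out of scope; the package stops at per-animal and
  per-group summaries.
* The transcriptomics stage starts at the count matrix; alignment and
  exon counting are external.
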