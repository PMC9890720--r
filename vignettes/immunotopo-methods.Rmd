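---
title: "Methods: tumour-immune topography from IHC TMA cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-immune topography from IHC TMA cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(immunotopo)
```

`immunotopo` quantifies where marker-positive immune cells sit in
tumour tissue — inside tumour cell nests (intratumoural, iTILs) or in
the intervening stroma (sTILs) — from brightfield IHC images of tissue
microarray cores, and classifies each case into a hot / cold / excluded
tumour-immune phenotype. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Stain model

Brightfield IHC signal is multiplicative in transmitted light and
additive in optical density: a pixel's OD vector is (approximately) a
non-negative combination of one unit vector per stain
(Beer–Lambert). We convert intensities with
`OD_c = -log10((I_c + eps) / I0_c)` with `eps = 1e-3`, clamped at zero;
the matching inverse makes the transform exactly invertible, which the
tests exploit as a round-trip oracle. Deconvolution solves the 3×3
system per pixel and clamps negative coefficients (pixels slightly
outside the stain simplex, from noise) to zero.

Default stain vectors are the widely used published H-DAB pair
(haematoxylin (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.778)), with the
third basis vector completed as their cross product. They can be
re-estimated per image (`estimate_stain_vectors()`): pixels above an OD
floor of 0.15 are projected onto the principal plane of the OD cloud and
the stain directions taken at the 1%/99% percentiles of the angular
distribution — the robust-extreme heuristic standard in stain-separation
practice. With too few stained pixels (a blank or fragmented core) the
published defaults are returned with a warning rather than a noisy
estimate. Estimation is per image by default; a cohort can supply one
shared vector set through the pipeline configuration. Accuracy degrades
for weakly stained pixels (angular noise scales as noise/OD), which is
why the floor matters more than the percentile choice.

## Cell detection

The detection channel is the *sum* of haematoxylin and DAB OD, so
strongly DAB-positive cells with weak counterstain are not missed. The
pipeline is: Gaussian smoothing (`smoothing_sigma`, default 1.5 µm),
rolling-ball background subtraction implemented as grey-scale opening
with a disc of `background_radius` (8 µm), a fixed OD threshold (0.1),
connected components, an optional split of touching nuclei, and an area
filter (10–400 µm²). Cells touching the border are kept if their
centroid is inside; compartment assignment uses the centroid only.

For the split we use a seeded watershed: local maxima (3×3) of the
background-subtracted channel seed an intensity-guided propagation
(`EBImage::propagate`) restricted to the thresholded mask. We initially
used the classical watershed on the distance transform; on synthetic
cores at realistic densities it under-segmented pairs of touching nuclei
whose fused blob is nearly convex (centroid-matching F1 0.87), whereas
intensity maxima still resolve them (F1 0.94, positive-count error
< 10%). Positivity is `mean DAB OD > dab_positive_threshold` (0.2);
raising the threshold can only shrink the positive set, which is tested
as a monotonicity property. All thresholds are per-staining-type
configuration, since real assays differ in DAB intensity.

## Tumour/stroma pixel classification

A random forest (100 trees, depth ≤ 16, √p feature subsampling — the
standard defaults for a forest whose architecture is not otherwise
constrained) classifies every tissue pixel as tumour or stroma from a
36-dimensional feature stack: for each deconvolved channel and each scale
in {1, 2, 4, 8} px, the Gaussian-smoothed value, its gradient magnitude,
and the local standard deviation under the same window. Borders are
handled by symmetric reflection. Training pixels are sampled
(stratified, capped at 5000/class) from user-drawn polygons stored as
JSON; a 20% holdout reports accuracy. One classifier is trained per
marker-stain type and applied to all cores of a cohort.

Post-processing applies a circular majority filter and reassigns
connected regions below 500 µm² — speckle at nest boundaries — to the
surrounding class. Two numerical details guarantee bit-reproducibility:
FFT-based smoothing is quantized to 1e-8 (FFTW results vary in the last
bits between runs, which would otherwise flip vote ties and tree
splits), and the forest's prediction tie-breaks are seeded.

## Topography

Densities are counts of positive cells over compartment area in mm²;
patients with two cores have their densities averaged before
thresholding. The cutoff per marker is, by default, the cohort median of
the per-case *overall* density (counts over both compartments divided by
total area); the pooled tumour+stroma compartment median is available as
an alternative derivation because both conventions are defensible and
the choice shifts cutoffs only slightly. Even-sized cohorts use the mean
of the middle pair.

Phenotype calls follow a fixed decision order: **hot** if the
intratumoural density is at or above the cutoff, otherwise **excluded**
if the stromal density is, otherwise **cold**. Tie handling is
config-locked: `>=` counts as high within a compartment, while the
low/high dichotomization of overall density uses strict `>` (the
boundary case is "low", matching "≤ cutoff" row labels in standard
reporting). Combined phenotypes (e.g. CD3/CD8 T cells) use an AND rule
by default — a compartment is high only if every constituent marker is
high there — because lineage marker pairs are strongly co-expressed
(generator default ρ = 0.9), so the rule choice perturbs distributions
only mildly; OR and mean-of-normalized-densities rules are available.
CPS is `min(100, 100 × PD-L1-positive cells (tumour cells, lymphocytes,
macrophages) / viable tumour cells)`, high at ≥ 10; semiquantitative
TILs scores map density to 0/+/++/+++ through three fixed bin edges,
with density 0 always scoring "0".

## Statistical battery

Association tests are Pearson chi-square **without continuity
correction** and Fisher's exact test (the r×c Freeman–Halton extension
for phenotype tables), two-sided, α = 0.05. The no-correction convention
is deliberate: it is the one under which the published sq-BLCA
contingency tables' p-values reproduce exactly (verified to the printed
precision in the test suite). Expected counts below 5 raise a warning
but do not abort, mirroring how such tables are analysed in practice.
Spearman correlation uses midranks with the t approximation on n − 2 df.
Mann–Whitney uses exact enumeration for small tie-free samples and the
tie-corrected normal approximation otherwise; Kruskal–Wallis and Dunn's
post hoc (Holm-adjusted by default, unadjusted available) work on pooled
midranks. Survival uses the Kaplan–Meier product-limit estimator,
log-rank tests, and "mean OS" implemented as the restricted mean (area
under the KM curve to a configurable truncation time, default the
largest observed time) with its standard error — the estimator standard
statistics suites print as mean survival.

A note on oracle agreement: the asymptotic chi-square p-value agrees
with a fixed-margin enumeration oracle to better than 0.01 in mid-p
convention when expected counts are ≥ 10, but can differ substantially
(e.g. 0.039 vs 0.076) on tables with expected counts below 5. The
package reports the asymptotic value throughout because that is the
convention of the tables it reproduces; the tests document both regimes.

## Synthetic data: what it emulates

`generate_core()` renders one RGB image per marker of the *same* core
geometry, matching serial-section TMA practice. Geometry: a circular
tissue disk; tumour nests are the threshold superlevel set of a sum of
`nest_count` random Gaussian bumps, thresholded at the quantile that
yields exactly the requested tumour area fraction — irregular interfaces
the pixel classifier must actually learn, not ellipses. Cells are
anti-aliased discs (radius ~ N(3.5, 0.5) µm) placed uniformly per
compartment with Poisson counts at the planned densities; overlap is
allowed, and the ground truth is the point set, so detection is
evaluated by centroid matching within one cell radius. Rendering adds a
diffuse haematoxylin background (0.18 tumour / 0.06 stroma — the texture
contrast carries the compartment signal, together with nuclear density),
stamps haematoxylin discs for all nuclei and DAB discs for positive
cells, mixes through the stain matrix, and adds Gaussian OD noise
(0.02). Identical (spec, seed) pairs are bit-identical.

`generate_cohort()` draws per case: a phenotype class from the mix
(default uniform); per-marker densities log-normal (sdlog 0.25 — right
skewed and strictly positive, like observed densities) around
class-conditional medians, with multipliers hot (4, 1.2), cold
(0.25, 0.3), excluded (0.2, 4) × the marker's reference median for
(tumour, stroma); reference medians default to typical sq-BLCA values
(CD3 582.3, CD8 291.6, CD79A 85.9, perforin 9.0 cells/mm²). CD3 and CD8
share a Gaussian copula at ρ = 0.9. PD-L1 CPS positivity is logistic
with baseline 0.05 and odds ratio 8 for hot cases; FGFR3 mutations
(prevalence 0.15) multiply CD8/perforin/CD79A densities by 0.35;
survival is exponential (baseline hazard 0.03/month) with hazard ratio
0.35 for perforin-high cases, censored uniformly over a 120-month
follow-up for a configurable fraction of cases — the simplest model
satisfying proportional hazards. All per-case seeds derive from the one
cohort seed.

Because the log-normal spread and FGFR3 attenuation can move a case
across the cohort-median cutoff, the generator reports both the sampled
class label and the class implied by the true pre-sampling densities
(`true_class`); the latter is the recoverable ground truth and is what
recovery rates are measured against.

Three detail levels trade fidelity for speed: `"counts"` (planned
densities plus Poisson counts on nominal areas — sufficient for
everything downstream of the density table), `"cells"` (adds masks and
coordinates), `"images"` (adds rendered cores). Statistical validation
(phenotype recovery, effect directions over 50 cohorts) runs at the
counts level; the image stages are validated on rendered cores of 800 µm
at 2 µm/px, sizes chosen so the full suite exercises every stage in
seconds per core.

**What passing tests do not show:** the generator has no chromatic
aberration, uneven illumination, necrosis, folds or out-of-focus
regions; nuclei are discs, not textured ellipsoids; stroma differs from
tumour by density and background level, not by genuine fibrous texture.
Detection F1 ≈ 0.94 and segmentation accuracy ≈ 0.98 on this material
are upper bounds on real-slide performance, not estimates of it. The
statistics, by contrast, are exact-arithmetic reproductions and transfer
directly.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → stain separation → tissue detection
→ cell detection → pixel classification → topography → statistics; the
classifier is trained once per cohort from annotations (in the synthetic
flow, derived automatically from the ground-truth mask of the first
cores, mirroring a user annotating representative areas). Every output
CSV carries a header comment with a content hash of the configuration
and the seed; reruns with identical configuration are byte-identical.
Unknown configuration keys are rejected before any stage runs.
Coordinates are 0-based pixels (x right, y down), physical units µm from
the image origin; masks are 8-bit label PNGs (0 background, 1 tumour,
2 stroma).

## Known limitations

- One marker per stained image; no multiplexing or membrane-level
  scoring (TPS beyond the count ratio is out of scope).
- Two tissue classes only — no necrosis/artefact class; unusable cores
  are flagged, not rescued.
- Compartment assignment by centroid can misassign cells straddling a
  boundary; the synthetic tests bound this at ≤ 5% of matched cells.
- The Freeman–Halton test enumerates r×c tables via the network
  algorithm and is guarded by a grand-total limit (default 1000); larger
  tables should use chi-square.
- Survival analysis is univariate (KM/log-rank); no Cox regression, and
  no multiplicity control across the association battery.
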