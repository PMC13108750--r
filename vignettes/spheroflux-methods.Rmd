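---
title: "Methods: spheroid morphometry and flux normalization in spheroflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid morphometry and flux normalization in spheroflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroflux)
```

spheroflux implements the analysis side of a metabolic assay on 3D tumor
spheroids: time-lapse morphometry of spheroid formation, Mito Stress Test
parameterization of oxygen consumption rate (OCR) traces, and a quantitative
comparison of normalization strategies. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Segmentation: Chan-Vese level set

Spheroids in brightfield well images are segmented by minimizing the
two-phase piecewise-constant (Chan-Vese) energy

$$E(\phi, c_1, c_2) = \mu\,\mathrm{Length}(\phi = 0)
 + \lambda_1 \sum_{\phi \ge 0} (I - c_1)^2
 + \lambda_2 \sum_{\phi < 0} (I - c_2)^2,$$

evolved by explicit gradient descent on the level-set function $\phi$ with
the region constants $c_1, c_2$ re-estimated as the region means at every
iteration. The image is first rescaled to $[0, 1]$ so that the defaults
transfer across acquisition settings. Which side of the contour is
"foreground" is decided afterwards: the region whose mean differs more from
the frame-border mean, so bright-on-dark and dark-on-bright objects are
handled symmetrically.

Numerical choices, all of which were genuinely open:

* **Initialization.** The classical checkerboard (`sin`-product) start is
  kept, but scaled to the image's intensity spread and centered on the Otsu
  split of the image. A pure checkerboard has a structural failure mode on
  images whose objects cover a small fraction of the frame: the two
  half-phases then have nearly equal means, the data force vanishes, and the
  evolution stalls at a saddle. Centering the initial function on the
  intensity split removes the stall without changing the energy being
  minimized.
* **Pre-smoothing** (`smooth_sigma = 1` px). The level set evolves on a
  lightly Gaussian-smoothed copy of the image. Smoothing is symmetric, so
  object boundaries are not displaced, but it prevents pixel-level noise
  from seeding spurious contour fragments.
* **Curvature clamping.** The curvature term is clamped to $\pm 1$/px;
  larger curvatures are not resolvable on the pixel grid, and unclamped
  values (which occur where $|\nabla\phi| \to 0$) destabilize the explicit
  scheme.
* **Length penalty** `mu = 2`, scaled internally by the variance of the
  normalized image. The scale-invariant form keeps one default usable across
  contrasts; the value suppresses noise-driven fragments while leaving
  object boundaries within a fraction of a pixel of their noise-free
  position.
* **No-object guard** (`min_separation = 1.5`). Range normalization
  stretches even a pure-noise frame over $[0,1]$, so a segmentation always
  *exists*. After evolution the foreground/background mean separation is
  compared with the pooled within-region standard deviation **on the raw
  image**: pure-noise frames score well below 1, frames with a genuine
  object (contrast at a few multiples of the noise) score above 2. Below the
  threshold the frame is declared objectless. Empty wells on a plate are
  thereby reported as empty rather than as a large low-contrast artifact.
* **Convergence** when the fraction of sign changes of $\phi$ drops below
  `tol = 1e-4` (after a minimum of 20 iterations), with a hard cap of 500
  iterations; non-convergence is reported in the result, never hidden.
* A constant (uniform) frame returns an empty mask directly.

Post-processing follows the standard order dilation → hole filling →
erosion with a disk structuring element (default radius 3 px; the radius is
a free parameter since the original description names the operations but not
the element size). EBImage supplies these operations and the connected-
component labeling.

## Shape metrics

Per object: area $A$ = pixel count × pixel-size², perimeter $U$ from a
4-direction Crofton intercept estimator, circularity $c = 4\pi A / U^2$,
pixel centroid, and equivalent diameter $2\sqrt{A/\pi}$. The Crofton
estimator counts foreground/background transitions along rows, columns and
both diagonals; naive boundary-pixel counting overestimates the perimeter of
a rasterized disk enough to bias $c$ by ~20%, while the Crofton form keeps
rasterized disks of radius 30–100 px within $[0.95, 1.02]$ (verified in the
test suite). Physical coordinates place pixel $i$ at $(i - 0.5)\cdot$
pixel-size from the frame origin (top-left).

**Yield** is the fraction of wells containing exactly one object whose
circularity reaches `c_round`; wells with two or more objects stay in the
denominator and are reported separately, because multiple aggregates per
well compromise the size-controlled design. The threshold defaults to
`c_round = 0.8`: the source protocol never quantifies "roundish", so the
value is this package's choice, is exposed as an argument, and is echoed in
the result object.

**Centering.** A spheroid is centered when its equivalent-diameter disk
touches or lies inside the closed acceptance disk of radius `r_center` about
the well center (touching counts — the rule is closed). `r_center` is the
caller's choice; a quarter of the well radius mirrors the drawn acceptance
region of the original assay.

**Aggregation trajectories** apply segmentation → cleanup → shapes per
frame; size is the total foreground area and circularity that of the largest
object (ties broken by the lower label). Failed frames are recorded as
missing, never interpolated. The equilibrium is the earliest window of
configurable length over which the least-squares slope of size, relative to
the window mean, stays below `slope_tol` (default 1%/h over a 10 h window;
spheroids in this assay plateau within roughly 20–40 h of a 70 h recording).

## Mito Stress parameterization

Traces are labeled by injection phase in protocol order baseline →
oligomycin → FCCP → rotenone/antimycin A; the default protocol is
(5, 8, 5, 8) cycles. Per-phase summaries default to the vendor-report
convention — last baseline cycle, minimum after oligomycin, maximum after
FCCP, minimum after rotenone/antimycin A — because the parameter names are
standard but no summary formulas are printed in the source protocol. The
rules are configurable (`mean`, `median`, ...) and recorded in the output,
since the min/max rules are biased upward/downward by construction on noisy
traces (the test suite quantifies this against a Monte-Carlo oracle);
recovery-oriented analyses should prefer the `mean` rule.

Derived parameters, with `non_mito` = rotenone/antimycin A floor:
basal = baseline − non_mito, ATP-linked = baseline − oligomycin,
proton leak = oligomycin − non_mito, maximal = FCCP − non_mito,
spare = maximal − basal, coupling efficiency = ATP-linked / basal. The
identity ATP-linked + proton leak = basal holds exactly. Pathological values
(negative ATP-linked or spare, non-positive basal) are **flagged, never
clipped or dropped** — clipping would silently distort the downstream
normalization evaluation.

The clustering feature matrix contains exactly nine read-outs per spheroid
(spare, maximal, ATP-linked, basal, proton leak, OCR FCCP, OCR baseline, OCR
oligomycin, OCR rotenone/antimycin A), in that fixed order. Whether the
features are standardized before embedding is an explicit flag recorded on
the matrix; both modes are supported and no claim is made about which
convention any particular study used. The t-SNE embedding is delegated to
Rtsne under a fixed seed. ECAR is carried as an optional pass-through column
and summarized only as a trend indicator: without buffer-capacity correction
and CO₂ partitioning, extracellular acidification cannot quantify glycolytic
ATP production, so no proton-efflux computation is offered.

## Normalization strategies and their evaluation

Four strategies are compared on basal and maximal respiration:

1. **raw** — no transformation;
2. **median** — within each experiment × cell line, the median of maximal
   respiration is computed per seeded cell number, the factor $F$ is the
   arithmetic mean of those medians, and all metabolic endpoint columns are
   divided by $F$. With $K$ distinct cell numbers there are $K$ medians
   (the design generalizes beyond three); the sample median of an even
   group is the usual lower–upper average. Because $F$ is multiplicative,
   whole-experiment batch factors cancel exactly and the operation is
   idempotent. A non-positive factor leaves its group unnormalized with a
   warning. Scale-free ratios (coupling efficiency, spare %) are untouched.
3. **median+area** — median, then value × (10⁵ µm² / projected area);
4. **median+cellnumber** — median, then value × (10⁴ cells / seeded N).

Evaluation pools all experiments and cell numbers per cell line and
computes (i) the Pearson correlation of the (normalized) value with the
seeded cell number — for 2D reference data, with the measured count — and
(ii) the relative standard deviation (sample SD over mean). Zero variance
makes $r$ **undefined**, reported as a distinct sentinel rather than 0: a
constant column is not "perfectly de-correlated", and variance at
floating-point rounding level (relative SD below 10⁻¹²) counts as zero.
Near-floor basal values can be flagged via a configurable detection floor
(they are more error-prone), but are never excluded by default.

Group comparisons (ANOVA + Bonferroni-adjusted pairwise t-tests, two-sided
t-test for two groups, significance at p < 0.05) are thin wrappers over base
R, provided only for convenience.

## What the synthetic generators emulate

Every generator is a pure function of its arguments including the seed, so
downstream stages always have exact ground truth.

* `make_spheroid_frame` — one disk with Gaussian edge blur and additive
  noise; truth is the analytic disk area.
* `make_aggregation_timelapse` — cell-sized disks drifting with overdamped
  exponential kinetics from scattered positions toward a deterministic
  close-packed equilibrium of configurable radius; frames 0.5 h apart.
  Projected size shrinks monotonically in expectation and circularity rises
  toward ~1, reproducing the qualitative aggregation phenomenology. It is
  *not* an agent-based aggregation model: there is no cell-cell adhesion
  force, no compaction physics, and no realistic optics.
* `make_plate_truth` — wells independently empty / single / multi-object,
  single objects round (disk) or irregular (elongated ellipse whose
  rasterized circularity falls below common "round" thresholds), with a
  countable truth table.
* `make_ocr_trace` — four plateaus with multiplicative Gaussian cycle noise
  (`level × (1 + ε)`); multiplicative because OCR levels are positive and
  their spread grows with the mean. Instantaneous transitions at injections;
  the fully-functional ordering rotaa ≤ oligomycin ≤ baseline ≤ FCCP is
  enforced unless pathological wells are explicitly requested.
* `make_experiment_set` — the normalization-evaluation design: per well,
  every phase level is `g_e · k_line(phase) · (N/25000)^alpha · (1 + ε)`
  with a log-normal per-experiment × cell-line batch factor `g_e` (median
  normalization removes exactly multiplicative effects, hence the log-normal
  choice), well noise ε, projected area ∝ N^(2/3) (volume ∝ N under
  near-spherical geometry), and a measured count with relative counting
  error. Defaults: cell numbers 20,000/25,000/30,000 (the metabolic-assay
  seeding densities), 16 replicate wells, 3 experiments, `alpha = 1`,
  10% well noise, 10% counting error. The batch factor SD (0.2) and the 2D
  generator's count range (15,000–35,000) and 10% OCR noise are not printed
  anywhere in the source study; they were calibrated once so that the
  synthetic data reproduce the *printed* summary statistics — raw 3D
  per-cell-line correlations spanning roughly 0.4–0.8, raw 3D relative SD
  roughly 0.2–0.48, 2D raw correlation ≥ 0.75 and 2D relative SD falling
  from ≈ 0.25–0.3 to ≈ 0.1–0.2 under count normalization — and were not
  revisited afterwards.
* `make_2d_reference` — monolayer wells with OCR linear in the true count
  and a Hoechst-style measured count with configurable relative error.

Passing tests on these generators demonstrate that the pipeline recovers
known structure under the stated noise model; they cannot demonstrate
robustness to real-image pathologies the generators omit (debris, uneven
illumination, out-of-focus frames, wells with touching spheroids) or to
metabolic phenotypes outside the multiplicative-noise family.

## Problem sizes

The shipped tests and the acceptance script use 128–192 px frames (2.5
µm/px), disks of radius 30–100 px, 20-seed segmentation ensembles, 100-seed
trace ensembles, 20-seed experiment-set ensembles of 4 cell lines × 3 cell
numbers × 16 replicates × 3 experiments, and a 288-well (three-plate) 2D
reference. These sizes were chosen so the full suite exercises every claim
at desk scale; all of them are arguments, not constants.

## Interface conventions

The package is function-first: generators, pipeline stages and evaluators
are exported functions over plain data frames and small S3 record classes
(`label_mask`, `spheroid_shapes`, `yield_result`, `aggregation_trajectory`,
`mito_stress_params`, `normalization_report`), and file exchange uses
delimited text, TIFF and a validated YAML run configuration
(`read_trace_table()`, `read_image_stack()`, `write_report()`,
`read_run_config()`). A shell CLI would add nothing for the intended R
audience, so none is shipped; `scripts/acceptance.R` shows the end-to-end
reproduction path.

## Known limitations

* The piecewise-constant model biases boundaries outward by a fraction of a
  pixel on strongly defocused edges (a few percent of area at blur σ ≥ 2 px
  for a 40 px disk); a piecewise-smooth or local-means variant would reduce
  this at substantially higher cost.
* Circularity of small objects (equivalent diameter ≲ 15 px) is
  discretization-limited; the calibration band is only claimed for radii
  ≥ 30 px.
* The equilibrium detector assumes a monotone approach to a plateau; it
  reports the *first* qualifying window and will fire early on transient
  stalls if `slope_tol` is set loosely.
* Strategy ranking is a statement about the generator's noise family
  (multiplicative batch × power-law size scaling). If real batch effects
  are additive, median normalization is not guaranteed to dominate raw.
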