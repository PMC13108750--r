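# spheroflux

Analysis toolkit for metabolic measurements in 3D tumor spheroids. It covers
the two measurement arms of a spheroid-based extracellular flux assay and the
statistics used to make such assays reproducible:

* **Spheroid morphometry from brightfield time-lapse images** — Chan-Vese
  level-set segmentation, morphological cleanup, per-object area/perimeter/
  circularity (`c = 4πA/U²`, 1 for a perfect circle), plate *yield* (fraction
  of wells with exactly one round spheroid; wells with multiple spheroids are
  excluded), aggregation kinetics with equilibrium-size detection, and
  well-centering QC for transfer into measurement plates.
* **Mito Stress Test parameterization of OCR traces** — phase assignment for
  the oligomycin / FCCP / rotenone+antimycin A injection sequence (default
  protocol 5, 8, 5, 8 measurement cycles), derived respiration parameters
  (basal, ATP-linked, proton leak, maximal, spare, coupling efficiency, with
  non-mitochondrial respiration subtracted and the exact identity
  `ATP-linked + proton leak = basal`), the nine-feature matrix for metabolic
  phenotyping with a seeded t-SNE embedding, and baseline/post-FCCP
  energy-state tables.
* **Normalization evaluation** — the four strategies *raw*, *median*
  (divide each experiment × cell line by the mean of per-cell-number medians
  of maximal respiration), *median+area* and *median+cellnumber*, ranked by
  per-cell-line Pearson correlation with the seeded cell number and relative
  standard deviation, with a 2D monolayer reference for the best-case
  comparison.

Because public spheroid-flux datasets with ground truth are scarce, the
package ships seeded synthetic generators (`make_spheroid_frame()`,
`make_aggregation_timelapse()`, `make_plate_truth()`, `make_ocr_trace()`,
`make_experiment_set()`, `make_2d_reference()`) that emulate the assay's
statistical structure — aggregating spheroids, plates with 0/1/many objects
per well, four-phase OCR traces with multiplicative noise, log-normal
experiment batch factors, and cell-count measurement error — so every
pipeline stage is tested against known truth.

Intended users: labs running plate-based 3D metabolic assays who want a
scripted, auditable alternative to spreadsheet + vendor-report workflows,
and methods developers who need a segmentation/normalization testbed with
exact ground truth.

## Worked example

Segment a synthetic 24-well plate, compute its yield, parameterize a noisy
OCR trace, and rank the normalization strategies:

```r
library(spheroflux)

pl <- make_plate_truth(24, p_zero = 0.1, p_multi = 0.2, p_irregular = 0.15,
                       seed = 5)
shapes <- lapply(pl$frames, function(f)
  extract_shapes(morphological_cleanup(chan_vese_segment(f), radius = 3),
                 min_area_px = 30))
compute_yield(shapes, c_round = 0.8)
#> <yield_result> 11/24 wells with exactly one round spheroid (c >= 0.80): yield 0.458
#>   wells excluded for multiple spheroids: 5

tr <- make_ocr_trace(mito_stress_truth(100, 40, 150, 10, noise_sd = 0.05),
                     seed = 1)
derive_mito_stress(summarize_phases(tr, rules = "mean"))
#> <mito_stress_params> (pmol O2/min)
#>       basal  atp_linked proton_leak     maximal       spare    non_mito
#>      90.536      60.157      30.379     139.579      49.043      10.110
#> coupling efficiency: 0.664  qc: ok

set <- make_experiment_set(seed = 11)
head(attr(compare_normalizations(set), "ranking"), 4)
#>   endpoint          strategy mean_rel_sd rank
#> 1    basal median+cellnumber   0.1018645    1
#> 2    basal       median+area   0.1307591    2
#> 3    basal            median   0.1954706    3
#> 4    basal               raw   0.2397185    4
```

Reading the output: the plate's yield is the fraction of wells usable for a
size-controlled assay (here 11 of 24; 5 wells were excluded for containing
multiple spheroids). The Mito Stress parameters recover the generating
plateaus (true basal 90, maximal 140 pmol O₂/min) from a 5%-noise trace.
The ranking table shows the relative standard deviation of basal respiration
per strategy, averaged over cell lines: normalizing by the experiment median
and then the seeded cell number roughly halves the well-to-well variability
of the raw data and ranks first.

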