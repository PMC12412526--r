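# vesselquant

Label-free vascular phenotyping of the zebrafish trunk from phase-difference
OCT angiography (OCTA) and GFP fluorescence en-face maps.

Tumor angiogenesis in larval zebrafish cancer models produces a
characteristic trunk phenotype: extra "hyperbranch" vessels bridging
adjacent intersegmental vessels (ISVs), increased vessel tortuosity, a bent
dorsal aorta / caudal artery (DA/CA) axis — and, crucially, many of the new
vessels carry no blood flow. Fluorescence imaging of endothelial GFP shows
vessel *structure*; OCTA shows vessel *function* (flow). Comparing the two
channels, and quantifying each with topological descriptors, separates
healthy (RAS−) from oncogene-expressing (RAS+) larvae and scores drug
response.

`vesselquant` implements that full analysis as a reusable, tested pipeline,
exercised end-to-end on synthetic vasculature with exact geometric ground
truth:

* **Synthetic trunk vasculature** (`phenotype_params()`,
  `generate_network()`, `rasterize_network()`): parametric DA/CA axis, DLAV
  and evenly spaced ISVs with controllable wiggle, axis bend, hyperbranch
  count and perfused fraction; analytic per-vessel arc/chord lengths and
  junction coordinates (`ground_truth_metrics()`).
* **BM-scan OCT simulation** (`flow_phantom()`, `simulate_bm_series()`,
  `simulate_network_volume()`): complex-valued repeated B-scans whose
  per-repeat Doppler phase advance is the closed form
  `φ = 4π n v Δt / λ` (λ = 800 nm, n = 1.33), plus bulk-motion offsets,
  phase noise and diffusive (Brownian) jitter.
* **Angiogram reconstruction** (`phase_difference()`,
  `unwrap_and_debulk()`, `aggregate_contrast()`, `denoise_and_project()`,
  `reconstruct_enface()`, `select_interscan()`): inter-B-scan phase
  differences wrapped to (−π, π], per-A-scan intensity-weighted circular
  bulk removal, intensity masking, mean-|Δφ| (or variance) contrast,
  3-px-radius en-face median filtering and axial maximum projection.
  Effective interscan times of ~30/160/330 ms are realized by the
  B-scan pair separation.
* **Fusion and SSIM** (`coregister()`, `merge_red_green()`, `ssim()`):
  similarity-transform co-registration by normalized cross-correlation,
  red(flow)–green(structure) merge, and the standard structural similarity
  index (Gaussian 11×11 window, σ = 1.5, k₁ = 0.01, k₂ = 0.03).
* **Topology metrics** (`binarize_auto()`, `skeleton_graph()`,
  `vessel_metrics()`): Hessian ridge filtering + CLAHE + Otsu (with
  hysteresis) binarization, 1-px skeletonization with junction merging and
  spur pruning, and the five descriptors — tortuosity (20-px overlapping
  windows, path/chord), DA–CA orientation sigma (Gaussian fit to the
  tangent-angle histogram), vessel density, mean vessel diameter
  (area/length), bifurcations per ROI-normalized vessel length.
* **Group statistics and orchestration** (`normality_check()`,
  `compare_groups()`, `run_study()`, `compare_study()`,
  `study_summary_table()`, `run_pipeline()`): Shapiro–Wilk screen, plain
  two-sample t-tests with the `ns/*/**/***` convention, n = 20 per group by
  default, tidy tibble outputs, `autoplot()` box plots.

Everything is tidyverse-shaped: tabular results are tibbles, fitted/derived
objects have `tidy()`/`glance()` methods, result types have `autoplot()`.

## Worked example

Simulate one RAS+ larva, reconstruct its angiogram, and compare flow
against structure:

```r
library(vesselquant)

params <- ras_plus_params(rng_seed = 42)
net <- generate_network(params)
net
#> <vessel_network>
#>   16 vessels (axis_da:1 axis_dlav:1 bridge:6 isv:8), 28 junctions, image 120 x 354 px
#>   total centerline length 1651.2 px; 15/16 vessels perfused

vol <- simulate_network_volume(net, n_repeats = 3, dt_s = 0.160,
                               seed = 42, bulk_sd_rad = 0.5)
octa_map <- reconstruct_enface(vol, threshold = 0.15)

gfp_map <- rasterize_network(net, "all")
ssim(octa_map, en_face_map(gfp_map$pixels, channel = "GFP-structure"))
#> <ssim_result> global = 0.8581 (window 11, sigma 1.50)

vessel_metrics(octa_map)[, 1:5]
#>   tortuosity orientation_sigma_deg vessel_density mean_vessel_diameter_um bifurcations_per_length
#> 1      1.012                  11.6         0.2253                   8.813                   726.5
```

The measured metrics sit close to the generator's analytic flow-channel
truth for the same larva (tortuosity 1.013, orientation sigma 10.3°,
bifurcation density 689.8), and the SSIM of 0.86 against this larva's own
structure map drops further once the non-perfused hyperbranch is
structurally present but dark in the flow channel — the same
flow-vs-structure dissociation the descriptors are designed to detect. A
full two-group study (n = 20 per group) runs with:

```r
study <- run_study(study_config(seed = 1))
compare_study(study, channels = "OCTA")
autoplot(study)
```

which reproduces the discriminative pattern: tortuosity, orientation sigma,
vessel density and bifurcations per length significantly higher in RAS+,
mean vessel diameter indistinguishable (the radius-matched control), and a
strictly lower flow-vs-structure SSIM in RAS+.

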