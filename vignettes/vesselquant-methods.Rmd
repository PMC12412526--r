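---
title: "Quantifying zebrafish trunk vasculature from phase-difference OCT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish trunk vasculature from phase-difference OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

# The problem

Oncogene-driven angiogenesis in larval zebrafish remodels the highly
regular trunk vasculature — a ventral dorsal aorta / caudal artery (DA/CA)
axis, a dorsal longitudinal anastomotic vessel (DLAV), and evenly spaced
intersegmental vessels (ISVs) — into a tortuous, hyperbranched network in
which many newly formed vessels carry no blood flow. Two imaging channels
see two different things: endothelial GFP fluorescence reports vessel
*structure*, while OCT angiography (OCTA) reports vessel *function*,
contrasting moving red blood cells against static tissue. This package
implements the complete analysis chain between raw repeated OCT B-scans
and group-level statistics, together with a synthetic-data layer that makes
every stage verifiable against closed forms or exact geometric truth.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not demonstrate about real data.

# The synthetic vasculature generator

`generate_network()` draws a parametric 2-D trunk network with exact
sub-pixel centerlines. The healthy (RAS−) and tumor-bearing (RAS+)
presets differ in four knobs:

| knob | RAS− | RAS+ | meaning |
|---|---|---|---|
| `axis_bend_sigma_deg` | 2.5 | 8 | sd of the DA/CA and DLAV tangent angle |
| `wiggle_amplitude_px` | 1 | 3 | sinusoidal ISV centerline perturbation |
| `n_hyperbranches` | 0 | 6 | bridges between adjacent ISVs |
| `perfused_fraction` | 1 | 0.3 | probability a bridge carries flow |

The preset magnitudes were fixed once so the synthetic groups land in the
neighborhood of published healthy/tumor trunk measurements (orientation
sigma of a few degrees vs. roughly 7–8 degrees, tortuosity near 1.005 vs
1.015 at these window settings) while remaining desk-verifiable.
Remaining geometry defaults (8 ISVs, 42 px spacing, 80 px ISV length,
1.4 µm pixels, radii 2–3 px) approximate a 120 hpf larval trunk at the
lateral sampling of the imaging configuration the package emulates.

Numerical design worth knowing:

* **Axis bend.** Tangent angles are drawn at 60-px control points,
  spline-interpolated, and rescaled so the realized dense tangent-angle sd
  equals the requested sigma exactly; integrating `tan(θ)` gives the
  centerline. This makes orientation-sigma recovery a well-posed
  parameter-recovery problem rather than a distributional approximation.
* **ISV wiggle.** A transverse sinusoid with per-ISV random phase, tapered
  to zero over 8 px at both ends so chain endpoints lie exactly on the
  axial centerlines (junction coordinates are therefore exact).
* **Hyperbranches.** Each occupies a (ISV pair × height band) slot; a
  bridge leaves the left ISV slightly dorsal of where the neighboring
  pair's bridge arrives, so two junctions on one ISV are always separated
  by several pixels and junction counts remain exactly recoverable from
  clean rasters. Requesting more bridges than slots is an error.
* **Radius matching and jitter.** The study presets give all vessel
  classes one radius (2.5 px) and add a per-larva radius offset
  (sd 0.15 px) shared across classes. The shared radius makes mean vessel
  diameter a designed *negative control* between phenotypes (the
  discriminative information lives in the other four metrics), and the
  jitter emulates animal-to-animal size variation — real between-animal
  diameter spreads are of order 1 µm, far larger than this.
* **Rasterization** is an exact swept disk: a pixel is vessel iff its
  center is within the class radius of the centerline polyline. No
  anti-aliasing, so pixel counts are integers reproducible by a
  brute-force distance oracle.

# The OCT simulator

`simulate_bm_series()` models repeated complex B-scans at one slow-axis
position. Repeat $r$ accumulates, per pixel,
$$\varphi_r = r\,\frac{4\pi n v \Delta t}{\lambda} + b_r + \varepsilon,$$
on top of a random static speckle phase, with $\lambda = 800$ nm and
$n = 1.33$ by default; amplitude is the phantom reflectivity plus Gaussian
noise. Only axial velocity is modeled — phase methods are axially
sensitive — and speckle is not modeled explicitly; per-pixel complex
Gaussian noise stands in, which keeps every reconstruction stage checkable
against the closed form. Bulk motion is a per-repeat global phase offset
$b_r$; "Brownian" tissue jitter is a per-pixel phase random walk whose sd
grows as $\sqrt{\Delta t}$, the ingredient that makes long interscan times
noisier in a physically sensible way.

One subtlety governs all velocity choices: the phase is only unambiguous
for $|\varphi| < \pi$, i.e. below about 0.94 µm/s at Δt = 160 ms. Real
trunk velocities (hundreds of µm/s) are far beyond this, so their wrapped
phases are effectively arbitrary but *fixed* values; the simulator's class
velocities (580 / 230 / 8 / 4 µm/s for DA, DLAV, ISV, bridge) were chosen
once so the wrapped magnitudes land in a detectable band (0.8–2 rad). The
interscan-selection demonstration instead uses sub-wrap velocities
(0.3–0.75 µm/s), where the closed-form story — contrast linear in
$v\,\Delta t_{\mathrm{eff}}$ until wrapping, background growing as
$\sqrt{\Delta t_{\mathrm{eff}}}$ — is exact, and the contrast-to-background
ratio peaks at the intermediate of the three ~30/160/330 ms presets.

The RNG always consumes the bulk-offset draws even when bulk motion is
disabled, so switching bulk on/off compares identical noise realizations —
that is what makes the bulk-invariance check exact rather than
statistical.

# Reconstruction

`reconstruct_enface()` chains four stages:

1. **Phase differences** between B-scans `j` repeats apart,
   `Arg(z_{k+j} conj(z_k))`, wrapped to (−π, π]. Effective interscan time
   is `j·Δt`; no spatial unwrapping is attempted because only differences
   are processed.
2. **Bulk removal**: per frame and per A-scan, the intensity-weighted
   circular mean of the wrapped differences over above-threshold pixels is
   subtracted and the result re-wrapped. For a common-mode offset this is
   exact (circular-mean equivariance); fully sub-threshold A-scans get
   offset 0. Pixels below the intensity threshold (default half the mean
   intensity) are masked to zero contrast.
3. **Aggregation**: default contrast is the mean absolute corrected phase
   difference — stable for the few repeats typically acquired; the
   variance across frames is available (`method = "variance"`) but is zero
   for perfectly constant Doppler shifts, which is why it is not the
   default. A single frame falls back to |Δφ|.
4. **Filtering and projection**: the volume is normalized, optionally
   smoothed along the locally dominant vessel orientation
   (structure-tensor direction, 5-px line kernels — off by default, since
   the method's verification is cleaner without it), median-filtered with
   a 3-px radius on each en-face plane, thresholded, maximum-projected
   along depth, and rescaled to [0, 1]. Thresholding accepts either an
   explicit value or the 95th percentile of a declared background region:
   a reproducible rule standing in for interactive thresholding.

# Fusion and SSIM

`coregister()` estimates a similarity transform (translation, rotation,
isotropic scale) by maximizing normalized cross-correlation: per candidate
rotation/scale the best integer shift comes from an FFT cross-correlation,
followed by Nelder–Mead refinement; ties break toward the smaller
transform, and a correlation below the floor (default 0.1) falls back to
the identity with a warning. Registration accuracy on known-shift/rotation
phantoms is about 0.1 px and 0.1°.

`ssim()` is the standard three-component (luminance, contrast, structure)
index with a Gaussian 11×11 window, σ = 1.5, k₁ = 0.01, k₂ = 0.03 and the
dynamic range taken from the data — the conventional defaults of common
built-in implementations. The global score is the mean of the local map
over the ROI; `plot_ssim_map()` renders the inverted-hot display
convention in which black is a local score of 1. Self-similarity is exactly
1 by construction of the formula, which the acceptance machinery uses as a
calibration point.

On synthetic pairs the flow-vs-structure SSIM is high for RAS− larvae
(every structural vessel is perfused) and strictly lower for RAS+ larvae
(hyperbranches present but mostly non-perfused). The *ordering* is the
validated claim; the absolute synthetic scores (≈0.51 vs ≈0.49 under the
bundled study's noise settings) are far closer together than published
animal values, because the synthetic phenotype perturbs a small fraction
of the image area while real tumor vasculature reorganizes the whole
field. Passing the ordering test therefore says the metric and plumbing
are correct, not that synthetic effect sizes match biology.

# Topology metrics

`binarize_auto()` implements curvilinear-ridge filtering (multiscale
Hessian, scale-normalized most-negative eigenvalue, scales 1–3 px matched
to the vessel half-widths), CLAHE, and a global Otsu threshold extended by
hysteresis: components above 0.45× the Otsu value are kept if they touch
an above-threshold pixel. Hysteresis is the package's resolution of the
otherwise under-specified manual-segmentation step: a single global cut
drops faint slow-flow vessels whose wrapped Doppler phase is small, which
would silently delete exactly the biology of interest (partially perfused
hyperbranches). The three binarization requirements used to fix the
defaults were mask overlap with truth (Dice ≥ 0.85 on mildly degraded
rasters), connectivity of faint vessels (flow-channel junction recovery),
and symmetry of mask widths between phenotypes (an unbiased diameter
control).

`skeleton_graph()` thins the mask (Zhang–Suen), removes redundant
staircase pixels (non-endpoint pixels whose set neighbors form a single
8-connected component — without this, oblique runs masquerade as spurious
branch pixels), classifies endpoints (1 neighbor) and branch pixels
(≥3 neighbors), merges branch-pixel blobs within 2 px into single junction
nodes, traces pixel chains (never cutting a corner past a junction), and
prunes spur branches shorter than 3 px. Chain path lengths count diagonal
steps as √2 and are measured after a 5-px moving-average smoothing of the
chain coordinates: raw 8-connected chains overestimate the length of
oblique straight runs by up to ~8%, which would otherwise corrupt the
tortuosity contract; smoothing removes that digitization bias while
preserving genuine curvature at the 20-px window scale.

The five descriptors:

* **Tortuosity** — 20-px path-length windows sliding 1 px at a time along
  every edge; per-window path/chord ratio; unweighted mean over all
  windows. Edges shorter than the window contribute one whole-edge ratio
  (configurable to drop instead) so hyperbranch-rich networks remain
  represented. A straight vessel scores exactly 1.0; a semicircular window
  scores π/2.
* **Orientation sigma** — tangent angles (central difference over ±4 px)
  for every chain position, folded to [−90°, 90°), histogrammed at 1°, and
  a Gaussian fitted around the dominant (axial) mode within ±45°. Two
  numerical choices matter on digitized chains: orientation uses a longer
  chain smoothing (15 px) than length measurement, because gently sloped
  digitized vessels otherwise collapse onto exact-0° runs between
  staircase jogs and bias the fitted sigma low; and the histogram is
  lightly smoothed before fitting while degeneracy (near-delta spikes) is
  detected on the raw histogram, falling back to the moment estimate.
* **Vessel density** — vessel pixels over ROI pixels.
* **Mean vessel diameter** — vessel pixel count over skeleton length
  (the area/length identity), in µm.
* **Bifurcations per vessel length** — junction nodes over
  ROI-area-normalized skeleton length. The normalization convention is
  recorded with the result; magnitudes are comparable only within one
  convention, so only ratios and directions between groups are
  interpreted.

ROIs are 1-based inclusive `c(r0, r1, c0, c1)` throughout (see `R/io.R`).

# Statistics and the bundled study

`compare_groups()` is an equal-variance two-sample t-test by default (a
Welch switch is provided), with significance labels at 0.05 / 0.01 /
0.001. `normality_check()` runs Shapiro–Wilk and warns — rather than
fails — on rejection, matching the screen-then-t-test workflow the
descriptors are used in. No multiple-testing correction is applied across
the five metrics; the report footer states this.

`run_study()` processes `n = 20` synthetic larvae per group by default:
generate → rasterize GFP → simulate the BM-scan volume (3 repeats,
Δt = 160 ms, phase noise 0.08 rad, bulk sd 0.5 rad) → reconstruct →
SSIM(flow, structure) → five metrics on both channels plus the analytic
truth. A counter-based seed derivation gives every larva an independent
stream, so changing one group's size never reshuffles another group's
larvae. At these sizes the full study runs in a few minutes on one core;
test-suite smoke studies use 4-ISV larvae and 2 repeats.

# What the validation shows — and what it does not

The test suite establishes, on synthetic data: exact Doppler closed-form
agreement (to 1e−6 rad) across the velocity/interscan grid; exact
bulk-motion invariance of the final en-face maps; exact junction-count
recovery and ≤2% tortuosity error against the analytic windowed arc/chord
oracle over 20 seeds per phenotype; orientation-sigma recovery within 1°
on average; the full RAS−/RAS+ directional pattern (four metrics up,
diameter flat, SSIM down); and calibrated type-I error of the t-test
machinery.

The generator does not emulate speckle statistics, transverse flow
decorrelation, depth-dependent signal roll-off, vessel diameter taper,
non-trunk anatomy, or segmentation ambiguity from overlapping structures
in projection. Consequently, passing these tests validates the
*correctness of the computations and the recoverability of the designed
effects*, not the pipeline's robustness to every artifact of live-animal
imaging; absolute synthetic effect sizes (notably SSIM differences) are
intentionally conservative relative to published animal data.

# Known limitations

* Analysis is 2-D on maximum-intensity projections; bifurcation counts of
  overlapping 3-D structures are overestimated by construction.
* The bulk model is a per-A-scan common phase; real sample motion with
  intra-A-scan gradients would need registration, which is out of scope.
* The orientation fit assumes a single dominant axial mode; vasculature
  with two comparably long orientation populations inside the ±45° fit
  window would need a mixture fit instead.
* `binarize_auto()` is tuned for bright vessels 2–4 px in half-width at
  this pixel pitch; other magnifications should revisit `scales`.
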