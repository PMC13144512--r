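---
title: "Quantifying microtubule end shapes and tip fluorescence with mtflare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule end shapes and tip fluorescence with mtflare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtflare)
```

## Scope and data model

mtflare quantifies two kinds of data from in-vitro reconstitutions of
microtubule end-binding couplers:

* **3D protofilament traces** — ordered polylines (nm), one per
  protofilament, traced minus→plus at a microtubule plus-end in an
  electron tomogram. Manual traces are exchanged as CSV
  (`read_traces()` / `write_traces()`).
* **Kymographs** — position × time intensity arrays from TIRF movies
  (32-bit TIFF plus a JSON sidecar carrying pixel size and frame
  interval), rows = time, columns = position, seed at low columns.

Coordinates are right-handed with the microtubule axis along +z and the
plus-end at larger z. All geometry is done per end against a fitted
axis, never against raw image axes.

## End geometry

### Axis and lattice fit

`fit_axis()` fits a cylinder (axis line + radius) to all trace points by
iteratively re-weighted least squares with Tukey bisquare weights
(c = 4.685 on a MAD scale, 8 reweighting rounds). Two details matter:

* the initial direction and centre come from the minus-end 60% of each
  trace — traces run minus→plus, so these points are mostly intact
  lattice, while flares concentrated at the plus end would tilt a naive
  first fit, and
* the first optimisation round already uses robust weights computed
  from the initial residuals, so flare points never dominate any
  iteration.

On noiseless synthetic ends the fitted direction is within much less
than 0.1° and the radius within 0.05 nm of truth; rigid motions of the
input move the fitted axis equivariantly (both are tested).

### Trace smoothing

Manual or synthetic traces carry point noise. On a densely sampled
polyline, independent noise *inflates arclength* — every 1 nm step gains
length from the jitter (about 30% at σ = 0.5 nm) — which would corrupt
every arclength-based quantity. `smooth_trace()` therefore fits one
smoothing spline per coordinate against the raw arclength parameter and
re-evaluates the curve on a fine grid. The spline flexibility is fixed
deterministically at one degree of freedom per 8 nm of trace (minimum
6): protofilament shapes are gentle arcs (radius of curvature
≥ ~15 nm), so this follows the geometry while suppressing noise.
Cross-validated smoothness selection was rejected because it
occasionally chases noise on individual traces, inflating their
arclength by several percent and misaligning paired measurements.

### Bend segmentation

The bend criterion is **radial excess** over the fitted lattice
cylinder: a protofilament is bent from the first arclength where
distance-to-axis minus fitted radius exceeds ε = 1.5 nm for at least
k = 3 consecutive 1 nm samples. Because a flare departs tangentially,
radial excess grows only quadratically, so the ε-crossing lags the true
onset by √(2ε/κ) ≈ 7–9 nm at typical curvatures. The onset is therefore
refined by extrapolating √excess — linear in arclength for a tangential
circular arc — back to zero over the samples below the crossing. On
noiseless synthetic flares the refined onset is within 0.7 nm (one
resample step) of truth; noiseless straight ends yield zero false bends,
and at σ = 0.3 nm noise the 5σ margin of ε keeps the false-bend rate
far below 1%.

Bent length is the arclength from onset to the plus terminus.
Protofilaments whose flares never build ~1.5 nm of radial excess
(arclengths below roughly √(2ε/κ) ≈ 9 nm) are below the detection limit
of this criterion and are reported unbent; the validation protocol uses
flare lengths of 40 ± 10 nm (lognormal), where detection is well-posed.

### End summaries and raggedness

`end_summary()` reports the fraction of unbent protofilaments, the bent
lengths, and **raggedness**: the population standard deviation (divisor
n) of the axial bend-onset coordinates, with unbent protofilaments
contributing their plus-terminus coordinate. The population form keeps
the arithmetic anchor exact (onsets {0, 0, 8.2, 8.2} nm give 4.1 nm);
consequently the estimator is biased low for small n like any SD — for
13 normal draws its expectation is 0.941σ — and the simulation test
asserts against that analytic expectation rather than against σ.

### Lattice spacing and seed exclusion

`estimate_lattice_spacing()` autocorrelates a detrended axial intensity
profile, corrects the n-divisor taper of the sample ACF (whose linear
decay otherwise drags peaks toward zero lag by ~0.01 nm), finds the
dominant peak in the 3.5–5 nm window, and refines it by spline
interpolation. Profiles without a local-maximum peak above correlation
0.1 are flagged unresolved (white noise is). Mean recovery over noisy
replicates is well within 0.5%, and a 4.10 vs 4.22 nm difference is
ordered correctly in ≥95% of replicate pairs at 20% noise; individual
noisy replicates scatter by a few percent, so spacing comparisons should
always pool replicates.

`filter_seed_like()` excludes plus ends that are probably the ends of
stable GMPCPP seeds rather than dynamic GDP lattice: shorter than 3 µm
**and** spacing above 4.16 nm (both exposed in
`seed_filter_config()`; the cutoffs are defaults, not measured
constants). Short ends with unresolved spacing are kept with a warning.

### Decoration, trains, oligomer position

`decoration_thickness()` measures how far decoration extends radially
beyond the wall: outermost radius with intensity above background + 3
background SDs (3-sample persistence against noise spikes), minus the
wall's outer half-maximum radius. Thicknesses at or below the 18 nm
extent of a single decorating dimer are classed `within_single_dimer`
(boundary inclusive), larger ones `multi_layer`. The half-maximum edge
assumes the wall is ≥ ~2× brighter than the decoration, which axial
tomogram projections satisfy comfortably.

`train_copy_number()` converts a decorating train length to copies by
fencepost counting at the 4.1 nm monomer repeat: floor(L/4.1) + 1.
`classify_oligomer_position()` calls an oligomer `at_end` when the axial
gap between its plus-most point and the minus-most flare onset is at
most 50 nm (inclusive), the distance over which direct contact with the
bent protofilaments is possible.

## Lateral clustering

`pair_overlap()` scores two neighbouring bent protofilaments by

$$\Omega = \frac{\sum_i w_i\,[\,|d_i - d_{ref}|/d_{ref} < \delta\,]}{\sum_i w_i}
  \times \frac{\text{shared bent arclength}}{\text{shorter bent length}}$$

with δ = 0.2 and d_ref = 2R sin(π/n_pf) from the fitted cylinder.
Matched points share the same *global* arclength coordinate inside the
interval where both protofilaments are bent. Two readings of "matched"
were considered: aligning at the two bend onsets, or matching at common
global arclength. The global reading was adopted because (i) it is
robust to the few-nm uncertainty of estimated onsets — a sheet whose
members' onsets are estimated 5 nm apart still scores Ω ≈ 0.9, whereas
onset-aligned matching shifts the correspondence and can drive Ω to 0 —
and (ii) it makes the overlap factor (shared bent arclength / shorter
bent length) the natural consequence of the matching rather than a bolt-on.
With full overlap and at least 50% of the weighted distances within 20%,
Ω ≥ 0.5, so the default link threshold θ = 0.1 is lenient by
construction.

Only angular-neighbour pairs are scored; edges are Ω ≥ θ (ties link);
clusters are connected components (union–find, verified exhaustively
against a depth-first-search oracle on all graphs up to 5 nodes and on
10³ random graphs up to 13 nodes, and cross-checked against igraph).
Distributions are reported as protofilament counts in categories
{1, 2, ≥3} pooled per condition, compared across conditions by
chi-squared, and `threshold_sweep()` repeats everything over
θ ∈ {0.03, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5}; the clustered fraction is
non-increasing in θ by construction, which the suite asserts on every
dataset.

A property worth knowing: two *solitary* flares whose onsets happen to
coincide genuinely stay near d_ref over their first ~10 nm and can link
at θ = 0.1 (the worked example in the README shows one such pair). This
is a feature of the lenient threshold, not an implementation artefact —
hence the sweep.

## Fluorescence quantification

* **Envelope boundary** (`detect_envelope_boundary()`): single
  change-point, two-level least-squares fit on the time-median spatial
  profile; a boundary is called only when the step height exceeds 3× the
  residual SD. At a step SNR of 5 the boundary localises within 2 px in
  ≥95% of replicates, and estimates across disjoint time windows of a
  stationary-boundary movie scatter with SD < 2 px.
* **Envelope ratio** (`envelope_ratio()`): (I_env − I_BG)/(I_lat − I_BG)
  over user-supplied disjoint boxes (or boxes derived automatically from
  the detected boundary, with the background box in the larger
  contiguous off-microtubule block). The ratio is exactly invariant
  under affine intensity maps.
* **FRAP** (`frap_recovery()`): I_pre is the pre-bleach mean, I_post the
  first post-bleach frame, and the plateau comes from a single-
  exponential fit (Levenberg–Marquardt) — not from the last frames, so
  finite acquisitions do not bias recovery low. The recovery fraction
  (plateau − I_post)/(I_pre − I_post) is clipped to [0, 1.05] with a
  flag.
* **Dwell events** (`detect_dwell_events()`): threshold at background
  mean + 5 SDs (background from off-microtubule columns), 4-connected
  components in (time, position), duration = frames × frame interval,
  events touching the first/last frame flagged censored.
  `dwell_fractions()` splits uncensored events at 0.32 s (≤ vs >,
  recomputed at 0.2 and 0.4 s for robustness); events longer than 1 s
  are included, never truncated. Excluding censored events is unbiased
  when the movie is much longer than the mean dwell (the suite checks
  the discretised-mixture survival value at movie length ≥ 2000×).
* **Stoichiometry** (`classify_stoichiometry()`): two-Gaussian EM with
  the dimer mean constrained to twice the monomer mean and a shared SD;
  a component with weight < 0.05 collapses the fit to one class. The
  constraint reflects the physics of single vs double fluorophore loads
  and eliminates label switching.

## The synthetic generator: what it emulates, what it does not

`generate_end()` builds a 13-protofilament cylinder (radius 11 nm,
4.1 nm axial repeat), gives each protofilament a ragged lattice exit
(taper SD 15 nm by default), and attaches flares as circular arcs
departing tangentially with curvature 0.04 ± 0.01 nm⁻¹ (radius of
curvature ~25 nm) and lognormal lengths (40 ± 15 nm by default). Sheets
listed in `cluster_spec` share one onset and one arc template, so
adjacent members sit at exactly d_ref at matched arclengths — the
defining geometry of lateral association. Flare length/curvature
families are fixture conventions: the experimental literature does not
constrain them, and no conclusion drawn here depends on the family.

The generator does **not** emulate: missing-wedge anisotropy or
tracing bias of real tomograms, partially traced protofilaments,
interactions between flares and bound oligomer densities, or intensity
nonlinearities of real cameras. Passing the synthetic benchmarks
therefore demonstrates the *estimators* are correct and calibrated on
data obeying the stated model — not that real traces satisfy that
model.

Kymograph, dwell-time and radial-profile generators follow the same
pattern (two-level envelope with a stationary boundary, exponential-
mixture residence times discretised by ceiling with sub-frame events
dropped as undetectable, wall + decoration shell radial profiles); each
returns a ground-truth record sufficient to re-measure every quantity.

All generators take a mandatory seed and use a single RNG stream per
call, restoring the caller's RNG state afterwards; identical parameters
and seed give bit-identical outputs.

## Numerical and protocol choices

* Resampling step 1 nm; smoothing spline df = length/8 nm; IRLS rounds 8;
  ACF peak refined by natural spline + golden-section maximisation
  (tolerance 1e-10 nm).
* Validation problem sizes: 200 ends for partition recovery (sheets of
  2–4, σ = 0.5 nm, θ = 0.1), 507 flares for onset accuracy, 200
  replicate pairs for spacing, 200 kymographs for boundary hit rate, 100
  FRAP traces, 2000 dwell events, 10⁴ null replicates per statistical
  test. The partition-recovery protocol generates ends whose bent
  protofilaments are the sheets; ends with additional solitary flares
  exercise the effect-direction benchmark instead, where the ≥3-cluster
  fraction must rise monotonically with the generator's sheet
  probability (Spearman ρ > 0.9 over p ∈ {0, 0.2, …, 1}).
* Null calibration of the exact two-sample KS test uses n = 24 vs 25:
  the exact statistic is discrete, and equal small samples make the
  attainable levels too coarse to sit inside [0.04, 0.06]; slightly
  unequal sizes refine the lattice while staying in the exact regime.
* Multiple-testing adjustment is off by default (pairwise p-values are
  reported unadjusted, as is conventional for these comparisons);
  `compare_conditions(adjust = "holm")` enables Holm adjustment.
* Two-way ANOVA is additive (no interaction) with type-II sums of
  squares, so unbalanced layouts are handled; with repeated experiments
  the user chooses whether rows are replicates or repeat means — both
  are legitimate and give different denominators.

## Known limitations

* The bend criterion cannot see flares shorter than ~√(2ε/κ); lowering ε
  trades this against false bends under noise.
* Raggedness mixes onset coordinates (bent) with terminus coordinates
  (unbent); ends dominated by unbent protofilaments measure terminus
  scatter, not taper.
* The overlap score treats the fitted d_ref as the sole reference; local
  lattice deformations shift all deviations of a pair coherently.
* Envelope boundary detection assumes one dominant step; two-step
  profiles (e.g. double envelopes) return the stronger step only.
* The stoichiometry mixture assumes a common SD for both brightness
  classes; strongly heteroscedastic data would need a free-SD variant.
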