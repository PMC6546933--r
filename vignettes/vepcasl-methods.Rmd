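---
title: "Methods: vessel-encoded multi-delay ASL analysis in vepcasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vessel-encoded multi-delay ASL analysis in vepcasl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the signal and
kinetic models, the decoding and fitting algorithms, what the digital
phantom does and does not emulate, the numerical choices, and the design
decisions that were genuinely open. It states no empirical results beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## Acquisition model

The default protocol (`default_protocol()`) is a pseudo-continuous labeling
train of duration τ = 1.4 s, cycled through eight vessel-encodings (two
non-selective — label and control — plus left–right, anterior–posterior and
diagonal selective pairs), two repetitions per encoding at each of six
nominal post-labeling delays (0.25–1.5 s in 0.25 s steps), TR 4.1 s, for
8 × 2 × 6 = 96 volumes. The 2D echo-planar readout acquires 24 ascending
slices in 1085 ms, so slice *k* of PLD *p* is effectively read at
`nominal + k·(readout/24)`; the brain-average effective PLDs are the
nominal values plus half the readout, 0.79–2.04 s. All synthesis and
fitting uses the slice-specific times; the rounded averages are reporting
conveniences.

The encoding weight of artery *a* in selective cycle *e* follows the
standard sinusoidal labeling-efficiency model
`w = −cos(π (p_a·d_e − o_e)/L_e)`, with the offset and half-period chosen
so the cycle's two target arteries sit exactly at −1 (labeled) and +1
(control). The default labeling-plane geometry — RICA (−30, 0),
LICA (+30, 0), RVA (−8, −20), LVA (+8, −20) mm — is a plausible neck
configuration, purely a phantom default and overridable; with it, the
encoding matrix augmented by a static column has full column rank (5), so
the decoding problem is identifiable. The diagonal pair's orientation is a
sequence-design choice with no single convention; it defaults to the
(1, 1)/√2 axis targeting RICA vs LVA and is configurable
(`default_encoding_scheme()`). Decoding carries the matrix with the data,
so results are invariant to the phase convention. An idealized ±1/0 matrix
(`ideal_encoding_matrix()`) exists for exactly identifiable test cases.

## Decoding: MAP selection over sparse artery supports

Per voxel, the eight encoding values at each PLD follow
`y = S·1 + Σ_a w[·,a]·ΔM_a + ε`, `ε ~ N(0, σ²I)`. The decoder considers
the empty class, all singletons and all pairs (11 classes for four
arteries): voxels fed by three or more major arteries are physiologically
rare and poorly determined from eight encodings, so larger supports are
excluded by default (configurable).

Classes are scored by the Gaussian *marginal* likelihood: zero-mean
Gaussian priors on the per-artery amplitudes, and a flat prior on the
static term, which is marginalized analytically by projecting data and
design onto the orthogonal complement of the constant vector. A plain
maximized likelihood would always favor the largest class; marginalization
supplies the Occam penalty that makes class comparison meaningful. Class
selection is *joint across PLDs* (log-evidences summed before
maximization): a voxel's feeding arteries do not change with delay, so one
vascular assignment per voxel is both physiologically right and
statistically stronger. The class prior is flat by default.

Point estimates within the chosen class are ordinary least squares
(the flat-amplitude-prior limit), with negative amplitudes clipped to zero
afterwards — simpler and more testable than constrained solving, and at
worst conservative. The amplitude prior scale is set globally to 10× the
99th percentile of the non-selective difference signal; the noise variance
is estimated per voxel from paired-repetition differences
(`Var(r₁ − r₂) = 2σ²`), floored at the global median so single aberrant
voxels cannot claim zero noise. The tests verify the implementation's
eigen-decomposition evidence against an independent Woodbury-identity
route in a different (Helmert) basis, exhaustively over every voxel of a
small phantom.

## Kinetic model and fitting

Each artery's decoded signal across PLDs is fitted with the general ASL
kinetic model for continuous labeling without dispersion (`delta_m()`),
with flow converted from ml/100 g/min by 1/6000. Constants default to
conventional 3 T values — T1 blood 1.65 s, apparent tissue T1′ 1.6 s,
inversion efficiency α 0.85, T2 CSF/blood 0.75/0.15 s, blood–water density
ratio 0.87, TE 14 ms — all exposed in `kinetic_constants()`. Whether
post-arrival decay is better described by a blood or tissue constant is
genuinely ambiguous; T1′ is therefore a parameter, not a constant of the
package. `M0` of blood comes from the ventricular-CSF signal (10%
two-sided trimmed mean against mask-edge partial volume) via
`M0b = S_csf · exp(TE(1/T2csf − 1/T2blood)) · ratio`.

The model is linear in `f·M0b`, so the fit profiles flow out in closed
form and reduces to a 1D search over the transit time: a deterministic
grid (0–3 s, 5 ms steps) followed by parabolic refinement through the
three bracketing points, then re-solving the flow at the refined ATT. The
posterior adds a weak Gaussian ATT prior (mean 1.3 s, sd 1.0 s) and a flat
positive prior on flow. This is the MAP point of the same posterior a
variational scheme would approximate; at phantom scale the point estimates
are what matters and the grid search is exactly reproducible. Voxels whose
peak signal is below 2× the noise sd are flagged low-signal and reported
with zero flow at the prior-mean ATT — with a very prolonged arrival delay
the label has decayed too far to quantify flow, and pretending otherwise
produces noise-fit artifacts.

One identifiability caveat the tests respect: with the default schedule
the earliest effective sampling time is τ + 0.79 s, so a bolus arriving
before ≈ 0.79 s is entirely in its decay phase at every sample and flow
and arrival trade off exactly; only the ATT prior breaks the tie. True
transit times in the phantom (1.2–1.6 s) sit well inside the identifiable
range.

## The digital phantom

`phantom_spec()`/`generate_truth()` emulate the *structure* of a stroke
VEPCASL dataset, not anatomy: an ellipsoidal head with a ventricle region
and a cortical gray-matter shell (GM partial volume ≈ 0.9 superficially,
0.2 deep); four vascular territories split left/right at the midline and
anterior/posterior at y = −33 mm with 4 mm linear blending bands (so both
single-artery and genuinely mixed voxels exist); and a spherical
right-MCA-like lesion. Defaults: 64 × 64 × 24 voxels of 3.4 × 3.4 × 5 mm;
GM/WM CBF 50/20 ml/100 g/min; carotid/vertebral baseline ATT 1.2/1.3 s.

Scenarios mirror the collateral patterns of interest: `no-collateral`
(direct flow reduced ×0.2 inside the lesion, nothing replaces it),
`inter-hemispheric` (contralateral-ICA collateral), `ica-occlusion`
(the whole carotid territory taken over by the contralateral ICA, with
vertebral collateral in the lesion). Collateral flow ramps from 0 at the
core edge to 75 ml/100 g/min at the lesion edge — the core is precisely
the tissue collaterals fail to reach — which also makes the survival
analysis span the full 0–80 ml/100 g/min Indirect-CBF range in
10-unit bins. A +0.3 s transit delay applies within 20 mm of the lesion
boundary, emulating peri-lesional delayed arrival. The ADC map is
800×10⁻⁶ mm²/s with 500×10⁻⁶ inside the core (threshold 620×10⁻⁶); the
final infarct is drawn voxelwise in the at-risk region (lesion + 10 mm)
with survival probability `plogis(0.15·(totalCBF − 20))`, the core always
infarcting — so survival rises smoothly with total flow, the property the
peri-core analysis is designed to detect. The left hemisphere is built
mirror-symmetric so mirrored-ROI code is exactly testable. The static
tissue signal is a constant (default 100× the peak difference signal):
decoding removes it, so only its dynamic range matters.

The noise model is additive white Gaussian, with the level either given
or derived from a target temporal SNR (default 5) on the non-selective
difference. What the phantom deliberately does *not* contain: realistic
anatomy and partial-volume structure, motion, distortion, coil
non-uniformity, bolus dispersion, or registration error between
timepoints (volumes are generated aligned). Passing tests therefore
demonstrate the correctness of the estimators under the stated model, and
the qualitative direction of the collateral/survival effects — not
robustness to the full messiness of patient data, where preprocessing
(motion correction, registration, segmentation) is assumed done upstream.

## ROIs and statistics

The ischemic core is the largest 6-connected component under the ADC
threshold — a deterministic stand-in for semi-automated delineation, with
an optional editing mask where a manual step would intervene. Shell ROIs
dilate with a spherical kernel in *physical* millimetres on the
anisotropic grid (center-to-center distance ≤ radius, inclusive): 10 mm
around the final infarct (surviving tissue), 20 mm around the core
(peri-core). Contralateral equivalents mirror the core/infarct masks
across the sagittal midline (nearest-voxel rounding) *before*
gray-matter restriction — mirroring a geometric mask is well-defined,
mirroring a GM-restricted one would entangle the two hemispheres'
segmentations. Hemisphere clipping (with logged counts) replaces a manual
check that no opposite-hemisphere voxels slip in.

The collateral fraction of an ROI is the sum ratio
`Σ indirect / Σ total` — robust to near-zero-flow voxels, unlike the mean
of voxelwise ratios (available via `method = "voxel_mean"`). The survival
table bins peri-core voxels by Indirect CBF in 10 ml/100 g/min bins
(open-ended ≥ 80 bin; fractions reported only for bins with ≥ 10 voxels),
after excluding voxels with *strictly more than* 25 ml/100 g/min of
Direct CBF (ties retained — the exclusion wording is "more than"); a
variant bins all peri-core voxels on either axis. Significance uses a
pooled two-proportion z-test above/below 25 ml/100 g/min (bins pooled by
lower edge). Patient-level comparisons use a two-way ANOVA (ROI ×
timepoint, Type-II sums of squares — appropriate when missed follow-ups
unbalance the design) with unpaired per-timepoint Welch t-tests gated on a
significant ROI effect; unpaired because dropouts make pairing impossible
for some cells. Voxels pool across subjects with equal weight.

## Numerical choices and limitations

* Decoding tie-breaks take the first maximal class in a fixed class
  order; everything downstream is deterministic, and pipeline reruns under
  one seed are byte-identical.
* The ATT grid (5 ms) plus parabolic refinement makes noiseless
  round-trips accurate to ~10⁻⁵ s; the acceptance suite checks median
  noiseless recovery at ≤ 10⁻³ relative.
* Problem sizes: the validation suite runs the full 64 × 64 × 24 phantom
  at SNR 5 once end-to-end, plus an 8 × 8 × 2 phantom for the exhaustive
  decoder-oracle comparison and 16³ masks for the dilation oracle — sizes
  chosen so each check exercises the full code path at desk scale.
* Dispersion of the labeled bolus is not modeled, macrovascular signal is
  not separated, and partial-volume correction is out of scope; the
  per-artery model is the plain kinetic model per arterial component.
* Compensatory flow *within* one artery's territory (e.g. leptomeningeal
  rerouting of the same carotid's blood) is invisible to vessel-encoded
  decoding by construction; only inter-arterial collateral flow is
  measured.
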