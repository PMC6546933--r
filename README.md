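# vepcasl

Quantitative analysis of **vessel-encoded pseudo-continuous arterial spin
labeling (VEPCASL)** acquired at multiple post-labeling delays (PLDs), aimed
at stroke perfusion studies where the question is not just *how much* blood a
voxel receives but *which artery* it comes from. The package separates the
perfusion signal of the four main brain-feeding arteries (right/left internal
carotid, right/left vertebral), fits per-artery cerebral blood flow (CBF) and
arterial transit time (ATT), and quantifies **collateral perfusion** — flow
reaching tissue from arteries other than its own hemisphere's carotid — and
its relationship to tissue survival after ischemic stroke.

It is written for imaging scientists who want a tested, deterministic,
end-to-end reference pipeline: every stage can be driven from R, validated
against a built-in digital phantom with known ground truth, and reproduced
exactly under a fixed seed.

## The model

**Encoding.** A VEPCASL acquisition cycles through encoding patterns that
spatially modulate the labeling efficiency across the labeling plane. With
per-cycle, per-artery efficiencies `w[e, a] ∈ [−1, +1]` (−1 fully labeled,
+1 control), the acquired volume for cycle `e` is

    I_e(v) = S(v) + Σ_a w[e, a] · ΔM_a(t_v)

where `S` is the static tissue signal and `ΔM_a` the difference signal of
artery `a`. The default scheme is eight cycles: non-selective label and
control, plus left-right, anterior-posterior and diagonal selective pairs,
each cycle a sinusoidal modulation `w = −cos(π (p·d − o)/L)` placing its two
target arteries exactly at ∓1.

**Decoding.** Each voxel is assumed fed by a sparse subset of arteries
(empty, singletons, pairs: 11 classes). Classes are scored by the Gaussian
marginal likelihood of the encoding vector — zero-mean Gaussian priors on
the amplitudes, the static term marginalized with a flat prior — summed over
PLDs, and the maximum a posteriori class's amplitudes are solved by least
squares (negative amplitudes clipped to zero).

**Kinetics.** Each artery's decoded signal across PLDs is fitted with the
general ASL kinetic model for a labeling bolus of duration τ arriving at Δt:

    ΔM(t) = 2 M0b α (f/6000) T1' e^(−Δt/T1b) ·
            (1 − e^(−(t−Δt)/T1'))                for Δt ≤ t < Δt+τ
            (1 − e^(−τ/T1')) e^(−(t−Δt−τ)/T1')   for t ≥ Δt+τ

with `f` in ml/100 g/min. The model is linear in flow, so the fit profiles
flow out in closed form and searches the transit time on a fine grid with
parabolic refinement, under a weak Gaussian ATT prior. `M0b` comes from a
ventricular-CSF calibration. Slice-specific timing of the 2D readout is
honored throughout: the brain-average effective PLDs of the default protocol
are 0.79–2.04 s.

**Derived measures.** Per voxel: total CBF; CBF-weighted ATT
`Σ CBF_a·ATT_a / Σ CBF_a`; **Direct CBF** (flow from the hemisphere's own
ICA) and **Indirect CBF** (everything else — the collateral measure).
Stroke ROIs are built morphologically: ischemic core = ADC < 620×10⁻⁶ mm²/s
(largest component); *surviving tissue* = 10 mm spherical shell around the
final infarct; *peri-core* = 20 mm shell around the core; mirrored
contralateral equivalents; all restricted to gray matter (partial volume
> 0.5) and clipped to their hemisphere.

## Worked example

Simulate the default study-sized phantom (64×64×24 voxels of 3.4×3.4×5 mm,
a right-MCA lesion with inter-hemispheric collateral supply, temporal SNR 5),
then decode, fit, and analyze:

```r
library(vepcasl)

protocol <- default_protocol()
effective_plds(protocol)
#> [1] 0.79 1.04 1.29 1.54 1.79 2.04

enc   <- build_encoding_matrix()
truth <- generate_truth(phantom_spec(scenario = "inter-hemispheric", seed = 42))
series  <- synthesize_series(truth, protocol, enc,
                             noise_sd = noise_sd_for_snr(truth, protocol, snr = 5))
decoded <- decode_series(series, mask = truth$brain)
decoded
#> Decoded vessel-encoded series
#>   grid 64x64x24, arteries: RICA, LICA, RVA, LVA
#>   class counts:
#>     empty      RICA      LICA       RVA       LVA RICA+LICA  RICA+RVA  RICA+LVA
#>       225     13735     15599      5464      5474       450       295         4
#>  LICA+RVA  LICA+LVA   RVA+LVA
#>         5       333       104

m0b  <- calibrate_m0_blood(mean_csf_signal(truth$calibration, truth$ventricles))
maps <- fit_maps(decoded, m0b)
maps
#> Per-artery CBF and ATT maps
#>   RICA: CBF > 0 in 14147 voxels (median 45.2 ml/100g/min)
#>   LICA: CBF > 0 in 16125 voxels (median 45.3 ml/100g/min)
#>   RVA: CBF > 0 in 5771 voxels (median 45.7 ml/100g/min)
#>   LVA: CBF > 0 in 5785 voxels (median 45.6 ml/100g/min)
```

Most voxels decode to a single artery; mixed classes appear along territory
borders and in the collateralized lesion. Collateral perfusion and tissue
fate:

```r
derived <- direct_indirect(maps, "RICA")     # lesion is right-hemispheric
core    <- core_from_adc(truth$adc)          # ADC < 620e-6 mm^2/s
rois    <- build_roi_set(core, truth$infarct, truth$gm_pv, truth$voxel_size_mm)

indirect_fraction(derived, rois$surviving_tissue)
#> [1] 0.291
indirect_fraction(direct_indirect(maps, "LICA"), rois$surviving_tissue_contra)
#> [1] 0

tab <- survival_table(derived$direct_cbf, derived$indirect_cbf,
                      truth$infarct, rois$peri_core)
binomial_split_test(tab)
#> survival below/above 25 ml/100g/min Indirect CBF:
#> 65.0% vs 98.3% (z = 13.8, p = 2.7e-43)
```

Tissue close to the infarct that survived drew ~29% of its flow from
collateral sources, versus none contralaterally, and peri-core voxels with
more collateral flow survived far more often — the qualitative signature the
method is designed to detect. `run_pipeline(pipeline_config(...))` chains
all stages (simulate → decode → fit → maps → rois → stats) with NIfTI/CSV
outputs and provenance sidecars; `inst/cli/vepcasl` exposes the same stages
as shell subcommands.

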