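---
title: "Aortic flow quantification: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic flow quantification: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The measurement model

Two-dimensional phase-contrast cine MR encodes, for every pixel of a plane
transecting the aorta, the signed blood velocity through that plane, sampled
at 20–40 frames across one cardiac cycle. `aortaflow` takes these velocity
maps together with per-frame lumen masks (segmentation is treated as an
upstream input, typically drawn on the magnitude images and copied to the
phase images) and derives the flow markers below. Two conventions anchor
everything:

- **Coordinates.** Pixels are addressed 0-based, `x` along columns and `y`
  along rows, centers at integer coordinates. Centroids are reported in pixel
  units; all physical distances and areas use the `(row, col)` pixel spacing,
  so anisotropic pixels are handled exactly.
- **Velocity sign.** Stored velocities keep the acquisition sign. Each region
  of interest carries a `forward_sign` (+1 ascending, −1 descending by
  default): in one acquisition plane the two vessels flow in opposite
  through-plane directions, and every downstream computation works on
  `forward_sign * v`.

### Flow curves, volumes, landmarks

Within each frame, lumen pixels are split by the sign of the oriented
velocity: the forward rate integrates the forward-signed pixels, the
retrograde rate the rest, each as `velocity (cm/s) × pixel area (cm²)` summed
in mL/s. The identity `net = forward − retro` holds exactly by construction.

Volumes integrate rates with the **rectangle rule** — sample value times the
uniform frame duration `RR / n_frames` — which matches how frame-based PC
analyses conventionally report volumes under retrospective gating; a
trapezoid option exists behind an argument. Forward and backward whole-cycle
volumes are indexed to body surface area when available.

Landmarks: peak systole is the frame of maximum net rate. End systole is the
first **linearly interpolated downward zero crossing** of the net curve after
the peak ("where the descending systolic limb meets the x-axis");
`end_systole_idx` is the last frame at or before the crossing. Systole starts
at frame 1 — the acquisition is R-wave-triggered, and no separate systole
onset is defined; if an onset at the upslope foot is ever preferred, the
landmark windows are plain integer vectors and can be replaced. When the net
curve never crosses zero (e.g. a persistent diastolic baseline without a
dicrotic notch), strict mode raises an error and lenient mode falls back to
the post-peak minimum with a warning — a real analysis should look at such a
curve rather than trust a silently invented end systole.

The systolic flow-reversal ratio is `sFRR (%) = 100 × SRF / SFF` with both
volumes integrated over the systolic window. `SFF = 0` leaves sFRR missing
(not 0, not infinite), with a warning.

### Flow displacement and jet rotation

Flow displacement (FD) is the distance between the lumen geometric center
(unweighted mask centroid) and the center of velocity of the forward flow
(forward-velocity-weighted centroid), in mm, normalized per frame to the
vessel size. The vessel-size normalization is the **equivalent lumen
diameter** `D_eq = 2·sqrt(area/π)` — the dominant convention in the
flow-displacement literature; an equivalent-radius option is exposed because
conventions differ between groups (the radius variant simply doubles the
percentage).

The rotational angle (RA) of the jet is the angular position of the offset
vector: 0° at image "up" (anterior on a standard display), increasing
clockwise, range (−180°, 180°]. The zero reference and handedness are pure
convention (configurable at the level of interpretation — all derived
quantities use only angle *differences*, wrapped to the minimal arc).

Three gating rules reflect the physics:

- Frames with **no forward pixels** have undefined FD and are gated.
- The **laminar gate**: RA is not interpretable when the flow is nearly
  axisymmetric, so frames with FD ≤ 12% (default) are gated — early-systolic
  aortic flow is mainly laminar and the centroid direction is then noise.
  Gated frames are drawn at RA = 0 in plots and CSV exports but are *excluded*
  from (not zero-filled into) the rotation computations.
- Rotational speed (RS) is computed only between **consecutive ungated
  frames**, as the wrapped angle change over `360 × frame_dt`, in rev/s;
  `RSls_avg` averages the speeds whose frame pairs lie inside late systole.

The rotational angle change ΔRA runs from the post-peak **stabilization
frame** to end systole. "The point where the flow angle stabilized" is
operationalized deterministically: the first ungated frame after peak systole
where the absolute frame-to-frame RA change stays below 10°/frame for two
consecutive steps (both thresholds are arguments). If no frame qualifies, or
an endpoint is gated, ΔRA is missing with a warning.

### Pulse wave velocity

PWV is the arch centerline length (summed 3-D segment lengths, mm → m)
divided by the transit time between the ascending and descending flow
upslopes, each timed by the **half-maximum method**: the time at which the
curve first reaches 50% of its maximum, linearly interpolated between the
bracketing frames, taking the last upslope crossing before the peak (robust
to baseline blips). Two numerical details matter:

- The half level is computed on the **forward** rate by default (robust to
  small retrograde components near the upslope); `on = "net"` is available.
- The curve maximum is refined by a **three-point parabola** through the peak
  sample and its neighbours before halving. The sampled maximum undershoots
  the true peak by up to `O((dt/Ts)²)`, and — crucially — by a *different*
  amount for the two planes, which sample the same waveform at different
  phases; at 30 frames per cycle that phase-dependent undershoot alone can
  bias the transit time by ~1 ms, a 5% error on a 20 ms transit. The parabola
  removes the bias to well below the interpolation noise. `refine_peak =
  FALSE` restores the raw convention.

A non-positive transit time is rejected as non-physiological rather than
clamped.

### Cohort statistics

- **Stepwise OLS**: candidates are screened univariately (p < 0.05, matching
  the practice of entering only univariately significant terms), then forward
  selection (entry p < 0.05) alternates with backward elimination (removal
  p > 0.10). The thresholds are arguments; the tie-break (smallest p, then
  alphabetical term name) makes the procedure fully deterministic. Candidates
  that would make the design matrix rank-deficient are skipped with a
  warning. The published composite model
  `PVO2 = 20.729 + 0.443·FFi − 0.261·FDs_avg − 0.172·LVEF` is available as an
  exact evaluator (`predict_pvo2_published()`).
- **ROC**: the empirical curve over midpoint thresholds; AUC as the
  pairwise-concordance U-statistic (ties count ½), CI as `AUC ± 1.96·SE`
  with the Hanley–McNeil standard error; the operating point maximizes the
  Youden index, ties broken toward higher specificity.
- **Nested logistic LRT**: likelihood-ratio χ² (df = 1) between binomial-logit
  fits. Separation is reported as a distinct error — including the quiet
  variant where the optimizer "converges" with fitted probabilities at the
  machine boundary.
- **Agreement**: ICC for average measures under the two-way mixed model,
  consistency type — `(MS_between − MS_error)/MS_between`, i.e. ICC(3,k) with
  k = 2 — with F-distribution confidence bounds; the paired CV
  `100·sqrt(Σd²/(2n)) / (Σ(m1+m2)/(2n))`, left missing when the mean is near
  zero; Bland–Altman limits `mean ± 1.96·SD` of the differences.
- **Utilities**: METs = PVO2/3.5 (resting oxygen consumption); risk strata
  boundary-inclusive at PVO2 ≤ 14 (high) and 14 < PVO2 ≤ 20
  (low/intermediate); VE/VCO2 slope by least squares. No multiple-comparison
  adjustment is applied anywhere. Group-comparison wrappers
  (ANOVA/Kruskal–Wallis/χ²) are provided for descriptive tables only; the
  routing between parametric and non-parametric tests is the caller's choice,
  not an inference.

## The synthetic generators

The simulators provide ground truth the pipeline can be held against; their
defaults describe one realistic healthy ascending aorta rather than a
convenient test case:

| parameter | default | rationale |
|---|---|---|
| grid, spacing | 96 px, 1.25 mm | typical PC in-plane resolution; lumen ~23 px across |
| frames, RR | 30, 1000 ms | common retrospective-gated cine |
| waveform | 420 mL/s peak, 35% systole, sin² pulse | systolic forward volume ≈ 73 mL, the healthy mean |
| notch, baseline | 15 mL/s × 60 ms, 3 mL/s | dicrotic notch gives the net curve its end-systolic zero crossing; small diastolic forward flow keeps diastolic FD defined |
| lumen radius | 13 → 14.5 mm, tracking the waveform | areas ~5.3–6.6 cm², relative area change ≈ 24% |
| jet | truncated Gaussian, σ = 0.18·r | the forward centroid is then analytically the Gaussian center (projected into the lumen), so imposed FD is recoverable; plug/parabolic profiles would couple FD to truncation much more strongly |
| offset | 0.17·D_eq systole, 0.29 diastole | healthy-cohort mean FD values |
| retrograde | 4.4 mL in a crescent opposite the jet, active peak→end systole | reversal physiologically appears near the outer wall opposite the jet |
| noise | 0 (opt-in per preset) | ground-truth checks are exact; the rotating preset adds 2 cm/s |

Implementation details that make the ground truth *exact* rather than
approximate: the jet is normalized per frame so its pixel sum equals the
waveform value; the retrograde crescent is kept spatially disjoint from the
jet support, so its scale has a closed-form solution and the imposed systolic
retrograde volume is met exactly under the pipeline's own rectangle rule (no
iterative sizing needed). Jet rotation is anchored at the *sampled* peak
frame — the frame the landmark detector registers — so every post-peak frame
pair carries exactly `rotation × dt` of angle change. Every generator runs
its randomness inside an explicit seed and leaves the global RNG untouched.

The cohort generator draws FFi, FDs_avg and LVEF independently normal at the
healthy-cohort means and SDs (42.7 ± 6.5 mL/m², 17 ± 6%, 63 ± 7%), builds
PVO2 from the composite coefficients plus Gaussian noise (SD 6 mL/kg/min,
which puts the model R² in the 0.15–0.35 band and the high-risk fraction
near 7%), and adds decoys for selection tests: an age column correlated 0.5
with FDs_avg (jet eccentricity rises with age) and an independent BSA column.

**What the simulators do not emulate** — and hence what passing tests do not
establish about real data: partial-volume and segmentation errors at the
lumen border, phase-offset (eddy-current) background, velocity aliasing,
in-plane motion of the vessel, non-circular lumina, correlated (structured)
noise, and any real hemodynamics (no Navier–Stokes). Recovery of imposed
parameters shows the *estimators* are correct, not that the acquisition
chain is unbiased.

## Degenerate inputs and edge policies

- Empty mask frames, non-monotone trigger times, shape mismatches and missing
  sidecar keys are rejected at load time with distinct error classes.
- sFRR with zero systolic forward volume, ΔRA without a stabilization frame,
  RSls_avg without an ungated late-systolic pair, and CV with a near-zero
  mean are all *missing with a warning*, never silently 0.
- A flow curve starting at or above half-maximum has no upslope and is an
  error for PWV timing.
- Missing optional cohort columns stay `NA`; they are never imputed as zero.

## Problem sizes used in the checks

The test-suite and the acceptance script run entirely on simulated data:
96×96×30 cines (one 192×192 case for the area-change closed form, where the
~0.5% lattice error of a rasterized disc at r ≈ 20 px would otherwise be
amplified fivefold in RAC), 200 cohorts of n = 169 for the selection study,
2000 subjects for variance-component recovery, and ≤ 50-point ROC instances
against an exhaustive concordance oracle.

One acceptance property is knowingly not met and documented as such: with the
cohort defaults above, stepwise selection recovers *exactly* the generating
trio in ~40% of cohorts, not ≥95%. This is a power fact, not a code defect:
at n = 169, residual SD 6 and SD(LVEF) = 7, the LVEF partial t-statistic has
noncentrality ≈ 2.6 (univariate screening power ≈ 60%, partial-test power
≈ 74%), and FDs_avg ≈ 3.4. A model whose weakest term is just significant in
one cohort cannot be re-selected near-certainly in replicate cohorts of the
same size. The *coefficients* of the composite refit are recovered without
bias (the acceptance script reports their means over 200 cohorts), and the
machinery itself is verified separately on low-noise cohorts where every
partial t exceeds 5.

## Known limitations

- FD normalization, the RA zero reference, and the ΔRA stabilization rule
  follow the dominant literature conventions where the source protocol is
  not fully specified; all three are exposed as arguments, and results that
  depend on them should state the convention used.
- Half-maximum PWV timing at 30 frames/cycle carries ~0.2–0.5 ms residual
  interpolation error; transit times below ~10 ms need finer temporal
  sampling regardless of method.
- The consistency ICC ignores fixed rater offsets by definition; use the
  Bland–Altman bias alongside it.
- No eddy-current/background-phase correction, aliasing correction, or
  segmentation: these belong upstream of this package.
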