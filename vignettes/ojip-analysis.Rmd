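---
title: "Methods: OJIP transient analysis, inhibitor occupancy, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OJIP transient analysis, inhibitor occupancy, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipr)
library(dplyr)
```

## The measurement and the model behind the analysis

A dark-adapted photosynthetic sample exposed to strong continuous light
shows a polyphasic chlorophyll-*a* fluorescence rise. Fluorescence acts as
an inverse proxy for the redox state of Q_A, the first quinone acceptor of
photosystem II: open reaction centers (Q_A oxidised) quench excitation
photochemically, closed ones (Q_A⁻) do not. The rise therefore maps the
progressive reduction of the electron-transport chain: the O–J phase
(20 µs–2 ms) is dominated by primary photochemistry (single-turnover Q_A
reduction), the J–I phase (2–30 ms) by exchange with the plastoquinone
pool, and the I–P phase (30 ms–1 s) by the filling of the PSI
end-acceptor pool while ferredoxin-NADP⁺-reductase activates.

The JIP-test reads this curve through a small set of landmark values and
an energy-flux bookkeeping: absorbed excitation (ABS) is either trapped
(TR₀) or dissipated (DI₀); trapped excitation either drives electron
transport past Q_A⁻ (ET₀) or not; transported electrons either reach the
PSI end acceptors (RE₀) or stop in the intersystem chain. All yields in
the suite are built from three measured ratios — φ_Po = 1 − F_O/F_M,
ψ_Eo = 1 − V_J, δ_Ro = (1 − V_I)/(1 − V_J) — and the initial slope M₀.
These definitions make a number of identities exact by construction
(φ_Po + φ_Do = 1, φ_Eo = φ_Po ψ_Eo, φ_Ro = φ_Po(1 − V_I),
ABS/CS = TR₀/CS + DI₀/CS, PI_total = PI_ABS·δ_Ro/(1 − δ_Ro)); the test
suite asserts them to 1e−12 on randomised records, which validates the
implementation rather than any physiology.

A Q_B-site inhibitor blocks reoxidation of Q_A⁻ in the centers it
occupies, so those centers close after a single turnover and the J step
rises. The occupancy statistic

R_J = [V_J(treated) − V_J(control)] / [1 − V_J(control)]

is the fraction of variable fluorescence headroom at 2 ms that the
treatment has consumed, and under the single-turnover reading equals the
fraction of reaction centers with the inhibitor in the Q_B niche.

## Landmarks, interpolation, and numerical conventions

* **Time zero** is the onset of actinic illumination; all landmark times
  (20, 150, 270, 300 µs; 2, 30 ms) are absolute from onset. F_O is read at
  20 µs — the standard operational origin on instruments that record from
  10 µs — by interpolation, not curve fitting.
* **Interpolation** is piecewise linear in linear time (`rule =
  "linear"`). PEA-class instruments sample every 10 µs at early times, so
  the choice is numerically almost immaterial, but it must be fixed for
  reproducibility; a linear-in-log-time alternative is available
  (`rule = "log-time"`) since log-spaced late samples make it slightly
  better there. Both rules are exact at sample points, and landmark
  queries outside the sampled range are errors, not extrapolations.
* **F_M is the maximal recorded sample**, not the maximum of an
  interpolant, with ties resolved to the first occurrence; t_FM is its
  time. A peak at or before 2 ms triggers a warning (not an error): such a
  trace has no I–P structure and most derived quantities lose meaning.
* **Area** is trapezoid-integrated on the raw sample grid from onset to
  t_FM, with samples capped at F_M so that noise excursions above the
  recorded maximum cannot produce negative area contributions. No
  resampling or smoothing is applied.
* **M₀** uses the 270 µs point exactly as defined
  (4(F_270µs − F_O)/(F_M − F_O), in ms⁻¹), not the 300 µs K-step
  approximation that also circulates in the literature.
* **J-step saturation.** When an inhibitor closes essentially every
  center by 2 ms, ψ_Eo → 0 and PI_ABS, δ_Ro degenerate. Exact V_J = 1
  never occurs on sampled data in floating point, so the branch is
  operationalised: records with ψ_Eo ≤ `j_sat_tol` (default 0.05, about
  the resolution of variable fluorescence on a fast transient) are
  flagged `j_saturated`, with PI_ABS = PI_total = 0 and δ_Ro undefined.
  The tolerance is configurable; set it near zero to treat saturation
  strictly.
* **ABS/CS proxy.** The absorption flux per cross-section has no
  estimator of its own on a fluorescence trace. The classical proxy
  ABS/CS ≈ F_O is the default, ABS/CS ≈ F_M the documented alternative;
  the choice is recorded in every output row because RC/CS and the
  Q_A-reducing-fraction statistic inherit it.
* **Group statistics.** R_J and the spider-plot tables are ratios of
  group means (one headline value per treatment, matching how a
  concentration series is usually reported), not means of per-sample
  ratios; per-sample occupancies against the control mean are available
  separately (`sample_occupancy()`) for dispersion. Negative raw R_J
  (treated below control) is reported raw and clipped to 0 in the
  headline column, since occupancy is a fraction.
* **Band windows.** The L-band is summarised at the extremum of ΔW_OK
  within 100–300 µs and the K-band at the extremum of ΔW_OJ within
  200–500 µs; the windows bracket the named steps (L = 150 µs,
  K = 300 µs) and are configurable. Because the J-peak of ΔV_t is
  conventionally quoted at the 2 ms step itself, the summary reports both
  the windowed extremum (1–3 ms) and the value exactly at 2 ms.
* **W_IP half-time** is the first upward crossing of 0.5 within the
  30–530 ms analysis range, linearly interpolated between the bracketing
  samples; curves that never cross are flagged rather than extrapolated.
* **Difference kinetics** are computed on the union of the two time grids
  restricted to their overlap, with each side averaged across its samples
  first. Disjoint ranges are an error.
* **F_O′ for qP** defaults to F_O — the minimal assumption, since the
  light-adapted minimal fluorescence is rarely measured — with the
  Oxborough–Baker estimate F_O′ = F_O/(F_V/F_M + F_O/F_M′) behind a flag.
  ETR uses the conventional absorptance 0.84 and PSII fraction 0.5, both
  exposed as arguments.
* **MR 820 nm features.** MR_0 is read at 0.7 ms (the first reliable
  point of a modulated-reflection measurement), MR_min within a
  configurable fast window (default 0.7–200 ms), MR_max after t_min up to
  2 s. Since MR_min is an extremum statistic, an optional running-median
  smoother is provided for noisy traces (default off). A slow amplitude
  below 0.5 % of MR_0 is classified as "plateau" (PSI-acceptor bypass
  phenotype) or "decline" (full disconnection phenotype) from the sign of
  the signal after t_min.
* **I₅₀.** The dose–response model is a two-parameter log-logistic with
  the upper asymptote fixed at the control mean and the lower at zero,
  fitted by Levenberg–Marquardt least squares on the non-zero doses; the
  model choice is this package's own, as an I₅₀ concept does not pin down
  an estimator. A model-free linear interpolation of the 50 % crossing is
  always computed alongside, serves as the starting value and the
  fallback, and is reported so the two estimates can be compared.
  Monotone-increasing responses are flagged `no_inhibition`; series that
  never reach 50 % are fitted but flagged `no_crossing`.
* **Pathogenicity thresholds.** Lesion diameters classify as `+` below
  1 mm, `++` from 1 to 3 mm inclusive, `+++` above 3 mm; the boundary
  convention (1.0 and 3.0 both `++`) is fixed by treating the verbal
  definitions "less than 1 mm" and "more than 3 mm" as strict, and the
  bundled published gliotoxin survey (30 species × concentration rows,
  including 3.04 and 3.06 mm entries) reclassifies without disagreement
  under it.

## The synthetic generator

No public raw transients accompany the assays this package targets, so
the package carries a generator whose outputs have the statistical
structure the analysis assumes. It is deliberately minimal — the goal is
ordered, tunable O-J-I-P phenomenology, not photosynthetic realism.

Two reaction-center subpopulations are propagated on the sampling grid
(time in ms):

* a blocked fraction `B` whose Q_A reduces at the light-driven rate `k_L`
  and never reoxidises: C_b(t) = 1 − exp(−k_L t), in closed form;
* an active fraction in which Q_A⁻ reoxidises at `k_AB` while oxidised
  plastoquinone remains (pool `N_PQ`, in electron equivalents per RC).
  The pool is re-oxidised by a PSI-side drain that activates as
  1 − exp(−k_FNR t) and draws down an end-acceptor pool `S_PSI` at
  specific rate `k_red` per remaining equivalent.

Fluorescence follows the total closed fraction through the
antenna-connectivity transform F = F_O + (F_M − F_O)·C(1 − p)/(1 − pC),
both levels scaled by `1 − antenna_loss`, with multiplicative Gaussian
noise applied last. The construction gives each control a single
phenomenological knob: `B` raises the J step, `S_PSI` scales the I→P
amplitude, `k_FNR` sets the I→P timing (so the W_IP half-time decreases
as it grows), `p` shapes the sigmoidicity of the early rise, and
`antenna_loss` attenuates the whole signal without touching any
normalised ratio — the separation of antenna effects from acceptor-side
effects that the flux analysis presumes.

Defaults were chosen once for physiological plausibility of the control
condition and then frozen: `k_L = 2 /ms` (saturating red actinic light),
`k_AB = 2.5 /ms` (giving a control V_J near 0.36 with `p = 0.25`),
`N_PQ = 10`, `S_PSI = 30`, `k_FNR = 0.02 /ms`, `k_red = 0.012 /ms` per
equivalent, F levels 500–2500 instrument units. Under these conditions
the control shows V_J ≈ 0.36, V_I ≈ 0.9 and a W_IP half-time near 330 ms
on the default grid (10 µs steps to 300 µs, then 220 log-spaced samples
to 2 s).

Integration is deterministic fixed-step stepping between grid points.
Within each substep the three states are updated analytically with their
couplings frozen at substep scale: the closed fraction and the acceptor
pool relax exponentially toward their momentary equilibria, and the
plastoquinone pool is handled piecewise exactly (linear drawdown above a
soft width of 0.25 equivalents, exponential relaxation below, with the
crossing time resolved inside the substep). The scheme is
unconditionally stable on the log-spaced grid, and the suite asserts
step-halving convergence (relative change below 1e−3 when the substep
target drops from 0.5 to 0.25 ms).

The two-phase MR generator anchors its fast oxidation decay at the
0.7 ms first-reliable point — so the programmed curve equals 1 exactly
where MR_0 is read — and adds a logistic slow re-reduction
(default onset 400 ms, rate 0.02 /ms). With the default separation of
phases the feature extractor recovers both programmed amplitudes to
better than 2 % on noise-free traces; strongly overlapping phases would
bias the fast amplitude low, because MR_min is then reached before the
fast decay has finished.

**What passing tests show, and what they do not.** The generator omits
real features of instrument data: the slow fluorescence decline after the
peak (so t_FM of an unblocked scenario sits at the end of the 2 s
window), baseline drift, detector nonlinearity, the two-electron gate of
Q_B, S-state dependence of the oxygen-evolving complex, and genuine
K-band or L-band chemistry (the generator can only move these bands
indirectly). Recovery of a programmed blocked fraction by R_J within
±0.10, or of a programmed I₅₀ within 5–10 %, therefore demonstrates the
internal consistency of the estimators under the stated noise model — not
their accuracy on any particular organism or instrument.

## Problem sizes

The test suite and the acceptance script use 1000-record identity sweeps,
single transients of ~250 samples per scenario, five-point occupancy
grids, 400-point MR traces, and 6 × 5 dose series. These sizes were picked
so that every stochastic check is comfortably stable under seed changes
while the whole suite stays fast on a laptop.

## Known limitations

* The specific energy fluxes per reaction center (ABS/RC, TR₀/RC, …) are
  not emitted; the per-cross-section family plus γ_RC covers the same
  information under the chosen proxy.
* R_J presumes the control and treatment share F_O/F_M normalisation
  behaviour; strong antenna damage combined with Q_B blockage mixes the
  two effects, and the spider-plot table is the better diagnostic there.
* The I₅₀ fit fixes the lower asymptote at zero; partial inhibitors that
  plateau above zero will show a biased I₅₀ and a poor residual, visible
  in `glance()` and `autoplot()`.
* `fluor_at()` and the landmark extraction refuse to extrapolate; traces
  must actually cover 20 µs to 30 ms (and past the peak) to yield a full
  record, which is the instrument's own requirement as well.
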