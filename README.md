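# ojipr

Analysis of fast chlorophyll-*a* fluorescence rise (OJIP) transients and
related photosystem II (PSII) inhibition assays, in tidy R.

When a dark-adapted photosynthetic sample is hit with strong continuous
light, its chlorophyll fluorescence rises through the characteristic
O–J–I–P steps (origin ≈ 20 µs, J ≈ 2 ms, I ≈ 30 ms, peak P). The shape of
this polyphasic rise encodes the state of the photosynthetic electron
transport chain, and the JIP-test turns a handful of landmark values into
quantum yields and energy fluxes. `ojipr` is written for plant
physiologists, phycologists and herbicide-mode-of-action researchers who
export such transients from continuous-excitation fluorometers
(Handy-PEA-style two-column text files) and want a scripted, reproducible
version of the analysis that instrument software performs interactively —
plus the statistics used to localise and quantify the action of
Q_B-site inhibitors such as DCMU, atrazine, or the fungal toxin gliotoxin.

## What it computes

**JIP-test parameters** from the landmarks F_O (20 µs), F_K (300 µs), F_J
(2 ms), F_I (30 ms), F_M (peak), and the 270 µs point:

- V_t = (F_t − F_O)/(F_M − F_O); initial slope M₀ = 4(F_270µs − F_O)/(F_M − F_O)
- φ_Po = 1 − F_O/F_M, ψ_Eo = 1 − V_J, φ_Eo = φ_Po·ψ_Eo, φ_Do = F_O/F_M,
  δ_Ro = (1 − V_I)/(1 − V_J), φ_Ro = φ_Po·(1 − V_I)
- complementary area, S_m = Area/(F_M − F_O), S_s = V_J/M₀, and
  S_m/t_FM (average fraction of open reaction centers up to the peak)
- fluxes per cross-section (ABS/CS, TR₀/CS, ET₀/CS, DI₀/CS, RC/CS) and the
  performance indexes
  PI_ABS = [γ_RC/(1−γ_RC)]·[φ_Po/(1−φ_Po)]·[ψ_Eo/(1−ψ_Eo)] and
  PI_total = PI_ABS·δ_Ro/(1−δ_Ro)

**Inhibitor occupancy**: R_J = [V_J(treated) − V_J(control)]/[1 − V_J(control)],
the fraction of PSII reaction centers whose Q_B site is filled by the
inhibitor, with the Q_A-reducing-center fraction and spider-plot tables of
every parameter relative to the control.

**Band analysis**: double-normalised kinetics (W_OK, W_OJ, W_OI, W_IP) and
treated-minus-control difference curves with the L-band (connectivity),
K-band (oxygen-evolving complex) and J-peak extrema, plus the half-rise
time of the I→P phase (PSI end-acceptor conduction).

**MR 820 nm kinetics**: MR_0/MR_min/MR_max features and fast/slow phase
amplitudes of modulated-reflection traces (plastocyanin/P700 redox
kinetics), with plateau/decline classification of degenerate slow phases.

**Dose–response**: percent-inhibition tables and I₅₀ by a two-parameter
log-logistic fit (upper asymptote fixed at the control mean) with a
model-free interpolation cross-check; saturation-pulse quenching parameters
(F_V/F_M, Yield, qP, ETR); and a lesion-diameter pathogenicity classifier
(`+` < 1 mm, `++` 1–3 mm, `+++` > 3 mm) bundled with a published gliotoxin
phytotoxicity survey.

**Synthetic data**: a compact mechanistic generator of inhibitor-treated
transients (blocked Q_B fraction, antenna connectivity, PQ pool, PSI
acceptor pool), two-phase MR traces, dose series, and lesion tables, so the
whole pipeline is testable without instrument data.

## Worked example

Simulate a control group and a group with 40 % of Q_B sites blocked, then
run the standard analysis:

```r
library(ojipr)
library(dplyr)

trs <- bind_rows(
  purrr::map(1:3, ~simulate_ojip(ojip_scenario(B = 0,   noise_sd = 0.01),
                                 seed = 100 + .x,
                                 label = paste0("mock_", .x), group = "mock")),
  purrr::map(1:3, ~simulate_ojip(ojip_scenario(B = 0.4, noise_sd = 0.01),
                                 seed = 200 + .x,
                                 label = paste0("gt_", .x), group = "inhibitor"))
)

jip <- jip_parameters(trs)
jip |> select(label, group, v_j, phi_po, psi_eo, pi_abs, sm_over_tfm)
#> # A tibble: 6 × 7
#>   label  group       v_j phi_po psi_eo pi_abs sm_over_tfm
#>   <chr>  <chr>     <dbl>  <dbl>  <dbl>  <dbl>       <dbl>
#> 1 gt_1   inhibitor 0.579  0.78   0.421   1.08       0.044
#> 2 gt_2   inhibitor 0.554  0.781  0.446   1.16       0.067
#> 3 gt_3   inhibitor 0.565  0.781  0.435   1.13       0.033
#> 4 mock_1 mock      0.347  0.778  0.653   1.95       0.077
#> 5 mock_2 mock      0.342  0.778  0.658   1.98       0.033
#> 6 mock_3 mock      0.35   0.782  0.65    2.06       0.093

compare_groups(jip, control = "mock") |>
  select(group, v_j_treated, v_j_control, r_j)
#> # A tibble: 1 × 4
#>   group     v_j_treated v_j_control   r_j
#>   <chr>           <dbl>       <dbl> <dbl>
#> 1 inhibitor       0.566       0.347 0.336
```

The J step (V_J) rises from 0.35 to 0.57, the electron-transport
probability ψ_Eo and the performance index PI_ABS drop roughly by half,
and the occupancy statistic R_J ≈ 0.34 recovers the programmed blocked
fraction of 0.4 up to the finite J-step kinetics of the simulated control.
A dose–response fit prints its estimate alongside the interpolation
cross-check:

```r
fit_i50(simulate_dose_series(i50 = 60, hill_slope = 1.2,
                             noise_sd = 0.05, seed = 42))
#> Log-logistic dose-response fit (upper asymptote fixed at control mean)
#>   I50       : 57.77
#>   hill slope: 1.232
#>   top       : 102.2   interpolated I50: 56.27   flag: ok
```

File-based batch analysis goes through a one-line manifest interface,
`run_pipeline("manifest.tsv", control_group = "mock", out_dir = "results/")`,
which writes every table (per-sample records, comparisons, band curves,
half-times, MR features, dose summaries) as TSV; a thin command-line
wrapper with `analyze`/`simulate`/`compare`/`report` verbs is installed at
`inst/scripts/ojip-pipeline.R`.

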