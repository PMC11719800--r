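# sfrtgrowth

Analysis toolkit for preclinical **spatially fractionated radiotherapy
(SFRT)** tumor growth-delay studies — the study design in which
subcutaneous xenografts (e.g. A549 lung tumors in nude mice) are irradiated
with microbeam (MRT), minibeam (MBRT) or conventional broadbeam arrays at a
matched equivalent uniform dose, and the endpoint is the time for each
tumor to triple its volume at irradiation.

It is written for the biostatistician or radiation biologist analyzing such
an experiment: caliper measurement tables, 1-D dose profiles and qPCR Ct
tables go in; growth delays, progression-free survival and fold changes
come out. A seed-reproducible synthetic cohort generator stands in for
animal data, so the whole pipeline is testable end to end.

## The models

**Dosimetry.** A planar SFRT field is idealized as a top-hat profile: dose
`P` inside each beam of width `w` on a center-to-center grid `ctc`, and the
valley dose `P / PVDR` elsewhere. With linear-quadratic cell survival
`S(D) = exp(-αD - βD²)`, the **equivalent uniform dose** is the uniform
dose giving the same spatially averaged survival `S̄`:

```
EUD = (-α + sqrt(α² - 4 β ln S̄)) / (2 β)        (β > 0)
```

The survival average is computed in log space, so peak doses of hundreds of
Gy do not underflow. `solve_peak_for_eud()` inverts the relation to find
the peak dose delivering a prescribed EUD.

**Regrowth kinetics.** The normalized volume after irradiation is the sum
of a dying and a proliferating compartment:

```
f(t) = V(t)/V0 = A1 e^(-α1 t) + A2 e^(α2 t),   A1 + A2 = 1,  all > 0
```

`fit_regrowth()` estimates `(A1, α1, α2)` per mouse by bounded multi-start
least squares on the `V/V0` scale. The curve's global minimum
`t_min = ln(A1 α1 / (A2 α2)) / (α1 + α2)` defines the start of regrowth
(the next measurement day after `t_min`), which is the event for
progression-free survival; the tripling time (first crossing of
`f(t) = 3`) defines the growth time, and the growth delay is the
difference to the control-arm mean.

**Endpoint statistics.** Kaplan–Meier product-limit PFS curves, pairwise
Mantel–Cox log-rank tests, and pooled-variance unpaired t-tests on growth
delays with t-based 95% CIs.

**qPCR.** Relative quantification by `2^(-ΔΔCt)`: Ct values normalized to
the mean of multiple reference genes (GAPDH, B2M, ACTB by default), then to
the control group.

## Worked example

```r
library(sfrtgrowth)
report <- run_pipeline(list(simulate = list(seed = 7)))
report
#> <study_report>
#>   36 mice, 4 arm(s)
#>   growth delays vs control:
#>    arm mean_delay   sd ci95_halfwidth p_vs_control
#> 1  CRT       10.5 2.88           2.21     3.51e-06
#> 2 MBRT       21.9 1.37           1.06     8.45e-12
#> 3  MRT       33.7 2.94           2.26     2.18e-13
#>   pairwise log-rank:
#>      arm1 arm2  chi2        p
#> 1 control  CRT 17.00 3.74e-05
#> ...
```

Thirty-six simulated mice (9 per arm) are generated with the default
kinetics — control tumors tripling in 33 days, treated arms with true
model-based delays of 11.1 (broadbeam), 20.2 (minibeam) and 34.9
(microbeam) days — measured Mon/Wed/Fri with 15% multiplicative caliper
noise and euthanized at the first observed `3×V0`. The recovered mean
delays above sit within a couple of days of those truths; the log-rank
matrix shows every irradiated arm separating from control.

The dosimetry side:

```r
dose_summary(mrt_geometry(), peak_gy = 470, pvdr = 20)
#>  label beam_width_um ctc_um n_beams peak_gy valley_gy pvdr eud_gy ...
#>    MRT            50    400      25     470      23.5   20  23.65
```

— 25 microbeams across the 10 mm field, valley dose 23.5 Gy, and the EUD
of the binary idealization at that peak (23.65 Gy; a top-hat profile has no
penumbra, so this is slightly above a film-based prescription).

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

| script | does | writes |
|---|---|---|
| `01_dosimetry.R` | beam counts, valley doses, EUD, inverse peak solve | `dose_summary.csv` |
| `02_simulate_cohort.R` | 36-mouse synthetic cohort | `cohort_measurements.csv` |
| `03_fit_regrowth.R` | per-mouse bi-exponential fits | `regrowth_fits.csv` |
| `04_growth_delay.R` | growth times, delays, t-tests | `growth_delay.csv` |
| `05_pfs.R` | KM curves, pairwise log-rank | `pfs.csv`, `logrank.csv` |
| `06_qpcr.R` | synthetic Ct table, ΔΔCt folds | `qpcr_folds.csv`, ... |

Each is a thin narrative over the package functions; run them in order with
`Rscript analysis/01_dosimetry.R` etc.

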