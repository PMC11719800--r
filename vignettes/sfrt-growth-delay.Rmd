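---
title: "Growth-delay analysis for spatially fractionated radiotherapy studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-delay analysis for spatially fractionated radiotherapy studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfrtgrowth)
```

sfrtgrowth analyzes the canonical preclinical SFRT experiment: xenografted
animals are randomized to sham control, conventional broadbeam, microbeam
(tens of µm beams at sub-millimeter spacing) or minibeam (hundreds of µm
beams at millimeter spacing) irradiation at a matched equivalent uniform
dose, tumors are calipered three times a week, and the readouts are tumor
growth delay, progression-free survival, and blood qPCR of
radical-scavenging genes. This vignette documents the models, the defaults
and the design decisions, and what the synthetic-data tests do and do not
demonstrate.

## Dose model

An SFRT field is described by its collimator geometry — beam width $w$,
center-to-center spacing $c$, field width $W$ — and idealized as a binary
top-hat profile: peak dose $P$ within each beam, valley dose $P/\mathrm{PVDR}$
between. Beams sit on a symmetric grid; the field holds
$\lfloor 1000\,W/c \rfloor$ beams, which reproduces 25 microbeams
(50 µm / 400 µm) and 5 minibeams (500 µm / 2000 µm) on a 10 mm field. The
default sampling step is $\min(w/10, 25)$ µm — 5 µm for the microbeam
geometry, 25 µm for the minibeam one — guaranteeing at least ten samples
per beam; a step coarser than $w/5$ is rejected.

The equivalent uniform dose uses linear-quadratic survival
$S(D) = e^{-\alpha D - \beta D^2}$ (A549 defaults $\alpha = 0.4460$ Gy$^{-1}$,
$\beta = 0.0115$ Gy$^{-2}$). Every grid sample is weighted equally (no
lateral tissue weighting is assumed), the survival average is accumulated
in log-sum-exp form — at a 470 Gy peak, $e^{-\beta D^2}$ underflows double
precision, yet the valley-dominated average is perfectly representable —
and the quadratic is inverted in closed form, falling back to
$-\ln \bar S / \alpha$ at $\beta = 0$. The $\beta \to 0$ limit is continuous
to $10^{-4}$ Gy, and the EUD always lies between the valley and peak doses.

```{r eud}
dose_summary(mrt_geometry(), peak_gy = 470, pvdr = 20)
```

A binary profile has no penumbra, so the EUD of the idealization at the
nominal study peak doses (about 23.6 Gy for the microbeam field, 21.2 Gy
for the minibeam one) is somewhat above a 20 Gy prescription computed on
measured film profiles; film-measured penumbra moves dose from peak into
the shoulder regions and lowers the survival-averaged dose. The package
therefore treats nominal peak doses as *inputs*, offers `eud()` on any
user-supplied profile CSV, and provides `solve_peak_for_eud()` for the
inverse problem on the ideal geometry.

## Regrowth model

Post-irradiation volume, normalized to the volume $V_0$ at irradiation
(enrollment window 60–100 mm³; volumes from the caliper ellipsoid formula
$\frac{\pi}{6} L B^2$), follows a two-compartment curve

$$ f(t) = A_1 e^{-\alpha_1 t} + A_2 e^{\alpha_2 t}, \qquad
   A_1 + A_2 = 1,\; A_1 \ge 0,\; A_2, \alpha_1, \alpha_2 > 0 , $$

a dying irradiated fraction plus a regrowing surviving fraction. The
constraint $A_1 + A_2 = 1$ pins $f(0) = 1$, so no pseudo-point at the
origin is added and pre-irradiation measurements are excluded from the fit.

**Fitting.** Parameters minimize $\sum_i (f(t_i) - V_i/V_0)^2$ on the
normalized linear scale. $A_2$ is eliminated as $1 - A_1$, $A_1$ is bounded
to $[0, 1 - 10^{-6}]$ and both rates to $[10^{-4}, 1]$ d$^{-1}$. The
objective has local minima (a shallow dip can be explained either by a
weak fast-dying compartment or a strong slow one), so optimization restarts
from a deterministic $5 \times 3 \times 3$ grid of bounded L-BFGS-B
searches with an analytic gradient, keeping the lowest objective; the
analytic gradient matters because late-time residuals respond
exponentially to $\alpha_2$ and finite-difference steps are far too coarse.
Identical inputs give bit-identical fits. At least four post-irradiation
points are required (three free parameters); measurements recorded after
the euthanasia day are rejected as inconsistent.

On noise-free data sampled on the study schedule the fit recovers all
parameters to $10^{-3}$ relative error with SSE below $10^{-10}$. Under 15%
multiplicative noise the median absolute error of $\alpha_2$ is about 5–6%
of truth over 200 replicates, with a small (~3%) upward finite-sample bias
— intrinsic to least squares on the linear scale under multiplicative
noise (a log-scale fit would remove it, but the linear scale is the
procedure this package models), and small against the between-animal
variability of real cohorts.

**Landmarks.** The curve's global minimum lies at
$t_{\min} = \ln(A_1\alpha_1 / A_2\alpha_2)/(\alpha_1 + \alpha_2)$ when
$A_1 \alpha_1 > A_2 \alpha_2$ and at 0 otherwise (monotone growth).
Regrowth is deemed to start at the *next scheduled measurement day* after
$t_{\min}$ — events are only observable on measurement days, so mapping
"the day after the minimum" to $t_{\min} + 1$ would manufacture sub-schedule
resolution. The growth (tripling) time is the first crossing of $f(t) = 3$:
by default from the raw measurements via piecewise-linear interpolation
(growth time is defined from recorded volumes; the day-0 ratio of 1 anchors
a crossing before the first measurement), with a model-based bisection
alternative (tolerance $10^{-6}$ d) used for noise-free validation, where
it is exact: a pure exponential with $\alpha_2 = \ln 3 / 33$ triples at
33.000 days.

Both fit scopes are available: per mouse (the default; one animal, one
parameter set) and per arm (pooling every survivor's normalized points into
one fit). Group-level curves are smoother but hide inter-animal
heterogeneity; all growth-delay statistics here use per-mouse values.

## Endpoint statistics

Growth delay per treated animal is its growth time minus the *mean* control
growth time (arms are independent; there is no pairing). Arm summaries
report mean, SD, and the half-width of the t-based 95% CI,
$t_{0.975,\,n-1}\, s/\sqrt n$. Two p-values accompany each arm because
"compared to controls" admits two readings — a one-sample t-test of the
per-mouse delays against zero and a two-sample pooled-variance t-test of
treated vs. control growth times; they coincide in the balanced noise-free
limit. The t-test is the classic pooled (Student) flavor, with Welch behind
a flag.

PFS uses the regrowth-start day as the event, censoring at
$\min(\text{last follow-up}, 90)$ days. Kaplan–Meier estimation and the
Mantel–Cox log-rank test come from the survival package behind the module
surface; the suite cross-checks the log-rank $\chi^2$ against a hand-coded
observed-minus-expected statistic and its p-value against a
10,000-permutation label-shuffle null (agreement within $\pm 0.02$ on
small cohorts). The log-rank is unstratified by default — no
stratification factor exists in this design — and the three pairwise
p-values are reported raw, with Holm adjustment available but off, matching
the way such studies report pairwise comparisons.

## qPCR quantification

Technical replicates are collapsed to mean Ct per sample and gene, then
$\Delta Ct = Ct_\text{target} - \overline{Ct}_\text{refs}$ against the
arithmetic mean of the reference genes (equivalently the geometric mean of
their quantities; defaults GAPDH, B2M, ACTB),
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_\text{control}$ per
gene, and fold $= 2^{-\Delta\Delta Ct}$. Group summaries are mean and SD of
per-replicate folds (the fold scale, matching how such results are
reported, $n = 4$). Note the control group's mean fold is exactly 1 only
for noise-free data: averaging on the fold scale is Jensen-biased upward
by roughly $e^{(\sigma \ln 2)^2/2}$, ~3% at $\sigma = 0.42$ cycles — which
the recovery tests account for. No amplification-efficiency correction is
applied (efficiency 2 is assumed), and expression comparisons between
groups are unpaired t-tests on $\Delta Ct$ (the log-scale measure).

## Synthetic cohorts

`generate_cohort()` emulates the study design: per arm, 9 animals with
$V_0 \sim U(60, 100)$ mm³, true volume $V_0 f(t)$ under the arm's
parameters, observed on a Monday/Wednesday/Friday schedule (offsets
{0, 2, 4} mod 7; day 0 is not a follow-up point) with multiplicative
mean-one lognormal noise at CV 0.15 — no error magnitude is published for
this design, and 15% is a realistic caliper CV once per-axis reading error
compounds through $L B^2$. The series truncates at the first day the
*observed* volume reaches $3 V_0$ (mirroring caliper-triggered euthanasia,
which deliberately reproduces the first-passage selection effect: noisy
early crossings shorten observed growth times, and truncation-limited
series inflate fitted $\alpha_2$ by tens of percent — a property of the
design, not of the fitter) or censors at 90 days. Every animal draws from
its own named substream derived from the study seed, so cohorts are
bit-reproducible and stable under arm reordering.

The default kinetics place the control tripling time at 33 days
($A_1 = 0$, $\alpha_2 = 0.0332913$ d$^{-1}$) and give the treated arms
($A_1 = 0.6$, $\alpha_1 = 0.15$ d$^{-1}$) model-based delays of 11.1, 20.2
and 34.9 days ($\alpha_2 = 0.045683, 0.037873, 0.029674$ d$^{-1}$) — each
rate verified by bisection against the closed-form curve.

```{r cohort}
cohort <- generate_cohort(default_study_design(seed = 1))
gt <- vapply(cohort, tripling_time, numeric(1), method = "raw")
arms <- vapply(cohort, function(r) r$arm, character(1))
growth_delay(gt[arms == "MRT"], gt[arms == "control"], arm = "MRT")
```

**What the synthetic tests show — and what they do not.** Passing recovery
tests demonstrate that the estimators are consistent and approximately
unbiased *under the generator's assumptions*: a correctly specified
bi-exponential mean, i.i.d. multiplicative lognormal noise, no
measurement-day jitter, no tumor-take failures, no toxicity-driven
dropout, and a shared noise level across arms. Real caliper series violate
several of these (operator drift, serially correlated errors, growth-curve
misspecification), so synthetic recovery bounds are evidence of software
correctness, not of field accuracy.

## Numerical choices and degenerate inputs

* EUD: log-sum-exp survival averaging; closed-form quadratic inversion;
  `uniroot` at $10^{-9}$ tolerance for the inverse peak solve, bracketed on
  $[\mathrm{EUD}_\text{target}, 10^4]$ Gy.
* Tripling: bisection at $10^{-6}$ d; raw interpolation anchored at
  $(0, 1)$; censored series return `NA` rather than an arbitrary value.
* Zero-variance t-test inputs resolve to $p = 1$ (equal means) or $p = 0$
  markers instead of erroring mid-pipeline.
* A valley dose of zero makes the PVDR undefined and is an error, not
  `Inf`.
* Fit failures in `run_pipeline()` are recorded per mouse and the pipeline
  continues; the report lists the failed ids.

## Problem sizes used by the test suite

Property suites run on 1,000 random parameter sets (closed-form vs.
grid-scan minima, beam-count placement scans), 200-replicate Monte-Carlo
recovery for $\alpha_2$ and the arm-level delays, 500 seeds for qPCR fold
recovery, and 10,000 label permutations for the log-rank null — sizes at
which Monte-Carlo error is comfortably below the asserted bands while the
whole suite stays fast enough to run on every change.

## Known limitations

* The top-hat profile omits penumbra and scatter tails; EUD on real film
  profiles should be computed from the measured CSV, not the idealization.
* No mixed-effects pooling across animals; arms are fit independently
  per mouse (or fully pooled), with nothing in between.
* No Gompertz/logistic alternatives; tumors that never shrink are handled
  ($A_1 = 0$ boundary) but plateauing regrowth is not modeled.
* qPCR assumes perfect amplification efficiency and ignores melting-curve
  QC, which belongs upstream.
* The growth-delay t-test inherits the usual small-$n$ normality caveats;
  with $n = 9$ per arm the CIs are indicative, not exact.
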