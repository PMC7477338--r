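---
title: "Methods: temporal-frequency and contrast tuning with divisive normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-frequency and contrast tuning with divisive normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnorm)
```

This vignette documents the scientific and numerical choices behind the
package: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where a design
was genuinely open.

## The pipeline

A recording session presents drifting gratings in a full factorial of
temporal frequency (default 0.5, 1, 2, 4, 8, 16 Hz), Michelson contrast
(10–90% in steps of 20) and eight drift directions, five repeats each,
2 s stimuli separated by 1.5 s of gray. The analysis proceeds:

1. **Evoked rate** per trial: mean rate over the stimulus window minus
   the spontaneous rate, the latter measured in the last 0.5 s before
   onset. Negative evoked rates are preserved — clipping them would bias
   every downstream mean upward.
2. **Condition aggregation**: responses are averaged over directions and
   repeats into one (frequency x contrast) matrix per unit (40 trials
   per cell under the default protocol), with the standard error taken
   across the pooled trials.
3. **Inclusion**: a unit is analysed only if some cell of its matrix
   reaches 1 spike/s ("minimum response" read inclusively, so exactly
   1.0 is kept).
4. **Per-unit fits**: a difference of Gaussians over frequency at each
   contrast; a Naka-Rushton function over contrast at each frequency.
5. **Population model**: the mean surface across units is fit by the
   divisive-normalization model in static, shunting and linear variants,
   and the same machinery runs per unit for model comparison.

## Difference-of-Gaussians stage

`R(f) = R_e exp(-f²/2w_e²) - R_i exp(-f²/2w_i²)` is fit by minimizing
the summed squared error with multi-start Nelder-Mead (eight
deterministic multiplicative perturbations of a moment-based guess;
function/parameter tolerances 1e-10 relative, 2000 iterations, with
restart polishing). Widths enter squared, so the search is unconstrained
and widths are reported as absolute values. A fit is rejected when
`R_e < 1e-4`, `R_i < 1e-4` or `w_e > 160` Hz — a gain that small or a
width that broad means the two-Gaussian structure is not supported by
the data.

Characteristics are interpolated on a logarithmic search range
[0.05, 32] Hz: wide enough below the lowest tested frequency that
low-pass curves resolve their edge behaviour, and extending one octave
above the highest tested frequency so a high half-maximum beyond 16 Hz
is still reportable. A coarse 1200-point log scan brackets the optimum
and the half-maximum crossings; golden-section and bisection refinement
take them to ~1e-9 Hz, well below the 1e-3 Hz resolution at which the
test suite cross-checks them against brute-force scans. For curves whose
maximum sits at the low edge (pure low-pass), the optimum is reported at
the edge and flagged by the absent low half-maximum; this is a
convention — the edge argmax, rather than exclusion, keeps low-pass
units in the per-contrast summaries.

A unit is **band-pass** when the fitted curve at the lowest tested
frequency (0.5 Hz) is below half the interpolated maximum, using the
fitted value for consistency with the interpolated optimum (a raw-value
mode is available via `value_at_lowest`).

## Naka-Rushton stage

`R(c) = R_m cⁿ/(σⁿ + cⁿ)` is fit by SSE plus a small penalty
`w·((σ/100)² + (n-2)²)`, `w = 1e-4`. The penalty exists because exactly
linear data are fit equally well by any large-σ curve with `R_m/σ`
fixed; the penalty selects the least extreme of these without visibly
moving fits to saturating data (the test suite checks curve changes
stay under 1% when the penalty is switched off on clean sigmoids). The
σ/100 normalization makes both penalty terms order 1 for an SSE in
(spikes/s)²; both the weight and the normalization are conventions,
exposed as `penalty_weight`, because no canonical scaling exists.

C50 and the quartile contrasts are found by bisection on the fitted
curve; the 100%-contrast reference is an extrapolation beyond the 90%
protocol maximum, and quartile searches extend to 1000% contrast, past
which the quantity is reported undefined rather than extrapolated
further. A response exactly linear in contrast yields C50 = 50% and
dynamic range = 50%, the package's analytic benchmark.

## Divisive normalization stage

With drives factorizing as `D = c·d(f)^(1/n)` and pooled drive
`T(f) = Σ d(f)`, the population response is
`P(c,f) = R_m cⁿ/(σⁿ/T(f) + cⁿ)`. Three variants are fit:

* **static** — one (σ, n) for all stimuli; 7 parameters;
* **shunting** — σ replaced by σ + τf, motivated by shunting-inhibition
  implementations in which the effective saturation grows with stimulus
  frequency; 8 parameters;
* **linear** — `P = R_m c T(f)`, the no-saturation control; 5
  parameters.

The population is aggregated by the cell-wise *mean* across units
rather than the sum; the two differ by the constant unit count, which
the fit absorbs into `R_m`, and the mean keeps `R_m` in spikes/s
regardless of cohort size. `T(f)` is a difference of Gaussians with its
excitatory gain fixed at 1: the gain is exactly degenerate with
`R_m`/σ, and fixing it makes the reported σ interpretable. Optimization
runs in log-parameter space (all parameters are positive scales) by
multi-start Nelder-Mead; shunting fits include a start at the static
optimum with τ near 0, which guarantees the nested model never fits
worse.

`t_mode = "free"` replaces the d.o.G. constraint with one positive
drive value per grid frequency. In that parameterisation σ (static) or
(σ, τ) (shunting) can be absorbed into `T(f)`, so the two variants span
the same surface family and converge to the same optimum — the
reparameterisation identity the test suite asserts. The free mode pins
σ = 1 for the static variant since it is then unidentifiable.

Explained variance is `1 - SSE/SS_tot`, and the adjusted form applies
the standard small-sample correction `1-(1-EV)(N-1)/(N-p-1)` with
N = 30 grid cells and p the variant's parameter count above. Two
analytic consequences of the static model are checked numerically
rather than assumed: the argmax of `P` over frequency does not move
with contrast (dP/df is proportional to dT/df through a positive
factor), and the response at a suboptimal frequency relative to the
optimum strictly increases with contrast.

The model-implied input tuning is `T(f)^(1/n)`, peak-normalized. As a
reference to compare it against, a d.o.G. curve is matched to the dLGN
literature characteristics (optimum 3.2 Hz, half-maxima 1.5 and 6.0 Hz
— the Methods-style values; a variant report gives the low half-maximum
as 1.4 Hz, and the target triple is a configurable argument for exactly
this reason). The match is a seeded stochastic search: log-uniform
draws of the three shape parameters (the overall gain does not affect
characteristics), Nelder-Mead polish of each, stopping when the summed
squared characteristic error falls below 1e-3 Hz² or 200 restarts are
exhausted.

## The synthetic-data generator

Each synthetic unit has a d.o.G. frequency drive `d(f)` coupled to
contrast through the normalization surface
`rate = scale·cⁿd(f)/(σⁿ + cⁿd(f))`, a spontaneous rate, and Poisson
spike counts per trial (spontaneous spikes also fill the pre-stimulus
gap). Poisson counts are the minimal noise model for spike data; no
trial-noise statistics were available to calibrate anything richer, so
recovery tolerances established here (e.g. the 20% band on the median
optimum) speak to Poisson-like variability only. Direction tuning is a
cosine modulation with depth defaulting to 0, since every analysis
stage averages over directions.

Default parameter ranges were calibrated once, by dense-grid evaluation
of the drive optima over 2000 draws, so a default population has its
median drive optimum near 2.8 Hz with roughly half the units band-pass:
`w_e ~ lognormal(median 5.5 Hz, sd 0.3 log-units)`,
`w_i ~ lognormal(median 1.2 Hz, sd 0.3)` capped at `0.9 w_e`,
`g_i ~ U(0.5, 0.9)` with `g_e = 1`. The cap plus `g_i < 1` keeps every
drive strictly positive, which the static model requires. Per-unit
σ ~ U(15, 45)% and n ~ U(0.9, 1.8) give contrast curves from
near-linear to clearly saturating; response scales of 8–30 spikes/s and
spontaneous rates of 0.5–4 spikes/s are typical extracellular values.

What the generator does **not** emulate: super-saturation at high
contrast, non-Poisson dispersion, adaptation or slow drift across
blocks, direction-selective populations, and any correlation between
units. Passing recovery tests therefore validates the estimation
machinery, not those aspects of real recordings.

## Problem sizes and determinism

Cohort-level tests run a 200-unit population under the full default
protocol (240 000 trials) for parameter recovery and per-unit model
comparison, and 100-unit single-contrast populations for tuning
recovery; these sizes give stable medians while keeping a full test run
in a few minutes. All randomness — sampling, simulation, bootstrap,
stochastic search — flows from explicit integer seed arguments, and
identical seeds reproduce results bit-for-bit.

## Known limitations

* The optimum of low-pass units is reported at the search-grid edge
  (0.05 Hz), a convention that depresses cohort medians relative to a
  treatment that excludes low-pass units.
* Naka-Rushton penalty weight and σ normalization are conventions; fits
  to strongly degenerate (flat or decreasing) data depend on them.
* Normalization fits are non-convex; multi-start plus restart polishing
  makes them reproducible, but global optimality is asserted only
  against the start set, and broad parameter plateaus (large σⁿ/T with
  compensating `R_m`) are expected and documented behaviour rather than
  a defect.
* The per-unit normalization fit refits `T(f)` per unit; an
  alternative reading shares the population drive across units. Refit
  is the default because the per-unit surface is itself unit-specific;
  no mode sharing a fixed population `T` is currently provided beyond
  fixing parameters manually in `model_surface()`.
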