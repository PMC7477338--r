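# tfnorm

Tools for analysing the joint dependence of visual-cortical responses on
the **temporal frequency** and **contrast** of drifting gratings, and for
testing whether that dependence is captured by the **divisive
normalization** model.

The package is aimed at visual neurophysiologists who record spiking
responses to a factorial grating protocol (temporal frequency x contrast
x drift direction) and want a reproducible pipeline from trial-level
spike times to population-model comparison. Because such recordings are
rarely deposited, the package ships a synthetic spiking-population
generator with retained ground truth, so every stage can be validated by
parameter recovery.

## The models

Per-unit tuning is summarised by two standard descriptive fits:

* temporal-frequency tuning by a **difference of Gaussians**

  `R(f) = R_e exp(-f²/2w_e²) - R_i exp(-f²/2w_i²)`

  from which the optimal frequency, the low/high half-maximum
  frequencies and the band-pass/low-pass class are interpolated;

* contrast response by the **Naka-Rushton function**

  `R(c) = R_m cⁿ / (σⁿ + cⁿ)`

  from which C50 (contrast at half the extrapolated 100%-contrast
  response) and the dynamic range (contrast span between the 1/4 and 3/4
  quartile responses) are derived by root-finding.

The population-level question is whether a single divisive-normalization
equation explains the whole (f, c) response surface. With a drive that
factorizes as `D = c·d(f)^(1/n)` and pooled drive `T(f)`, the population
response is

  `P(c, f) = R_m cⁿ / (σⁿ / T(f) + cⁿ)`   (static variant),

with a **shunting** variant substituting `σ + τf` for `σ`, and a
**linear** control `P = R_m c T(f)`. The static model predicts a
contrast-invariant optimal frequency and a relative response at
suboptimal frequencies that grows with contrast; the package verifies
both properties against closed-form derivatives. The model-implied input
tuning `T(f)^(1/n)` can be compared against a dLGN population proxy
built by stochastic characteristic matching to literature values.

## Worked example

Simulate a 30-unit population under the default protocol (0.5–16 Hz x
10–90% contrast x 8 directions x 5 repeats), analyse it, and report:

```r
library(tfnorm)

study    <- simulate_study(30, seed = 42)
analysis <- analyze_study(study$trials)
analysis
#> study analysis: 30/30 units included
#>   population static   EV 0.995 (adjusted 0.993)
#>   population shunting EV 0.999 (adjusted 0.999)
#>   population linear   EV 0.899 (adjusted 0.878)

report <- tuning_report(analysis, seed = 43)
report$tf_by_contrast[, 1:4]
#>   contrast_pct n_fits f_opt_median f_opt_sem
#> 1           10     30         2.87     0.118
#> 2           30     30         2.88     0.238
#> 3           50     30         2.69     0.160
#> 4           70     30         3.12     0.276
#> 5           90     30         3.53     0.404
```

The per-contrast table gives the median optimal temporal frequency (Hz,
with bootstrapped standard errors) of the accepted per-unit
difference-of-Gaussians fits; here the optimum shifts upward with
contrast. `report$contrast_by_tf` tabulates median C50 and dynamic range
per frequency, `report$model_comparison` the explained variance of the
three population-model variants, and `report$lgn` the inferred drive
against the dLGN proxy:

```r
report$lgn
#>   tf_hz inferred_drive lgn_proxy difference
#> 1   0.5         0.614    0.0323      0.582
#> 2   1           0.777    0.255       0.522
#> 3   2           1        0.808       0.192
#> 4   4           0.940    1          -0.0604
#> 5   8           0.596    0.214       0.382
#> 6  16           0.0965   0.000368    0.0961
```

i.e. the normalization model has to assume far more low-frequency input
drive than the dLGN provides — the key qualitative mismatch the pipeline
is built to expose. Each fitted object also supports `tidy()`,
`glance()` and `autoplot()`.

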