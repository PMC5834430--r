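# triexpdwi

Multi-compartment signal modelling for multi-b-value diffusion-weighted
MRI (DWI), built around a **modified tri-exponential model** whose third
compartment is *strictly diffusion-limited*: its apparent diffusion
coefficient (ADC) is fixed at exactly zero, so its fraction `f0` survives
as a signal floor at arbitrarily strong diffusion weighting. The package
is for researchers who acquire ultra-high b-value DWI (up to
8,000 s/mm²) and want to ask, voxel by voxel, whether a non-decaying
water pool is present — as it is in brain white matter — and whether
adding it is justified by formal model selection rather than by eyeball.

## The models

With `S`/`S0` the signal normalized to the unweighted (b = 0) image, the
three competing models are

```
bi-exponential:          S/S0 = f_slow·exp(−ADC_slow·b) + f_fast·exp(−ADC_fast·b)
tri-exponential:         S/S0 = f_vs·exp(−ADC_vs·b) + f_slow·exp(−ADC_slow·b) + f_fast·exp(−ADC_fast·b)
modified tri-exponential: S/S0 = f0 + f_slow·exp(−ADC_slow·b) + f_fast·exp(−ADC_fast·b)
```

with all fractions non-negative and summing to one (the fast fraction is
always implied, never stored). Each model is fitted per voxel by
constrained projected-gradient least squares on the first 16 b-values of
the 17-b-value scheme; b = 8,000 s/mm² is held out. Models are then
ranked by

- **RSS** — residual sum of squares of the fit;
- **AICc** — `2k + N·ln(RSS/N) + 2k(k+1)/(N−k−1)` with `N = 16` points
  and `k` = 3 (biexp), 5 (triexp), 4 (modtriexp) free parameters;
- **PRESS** — leave-one-out predicted residual sum of squares over the
  16 fitting b-values;
- **SPE** — squared prediction error `(S_m − S_p)²` at the held-out
  b = 8,000 measurement.

A synthetic brain phantom (white/gray-matter classes, Rician magnitude
noise, the scanner's NSA and three-direction magnitude averaging) makes
the whole stack testable without scanner data, and an SNR
"difference-method" estimator reproduces the floor-versus-noise
plausibility argument.

## Worked example

Simulate one white-matter-like voxel (15% strictly diffusion-limited
fraction, per-average SNR 25) and rank the three models:

```r
library(triexpdwi)
scheme <- default_bvalue_scheme()   # 0 ... 8000 s/mm^2, 17 b-values
wm <- modtriexp_params(f0 = 0.15, f_slow = 0.58,
                       adc_slow = 816e-6, adc_fast = 4525e-6)
set.seed(7)
raw <- acquire_voxel(tissue_class("WM", wm, s0_mean = 560), scheme,
                     sigma = 560 / 25)
compare_models(normalize_signal(raw, scheme))
```

```
model comparison (held-out b = 8000, measured S/S0 = 0.1415)
     model k n_points      rss    aicc    press       spe s_predicted
     biexp 3       16 0.021744  -97.62 0.034757 0.0117102     0.03325
    triexp 5       16 0.005680 -111.09 0.009598 0.0005761     0.11747
 modtriexp 4       16 0.004694 -118.51 0.008815 0.0006932     0.16779
```

The bi-exponential model, lacking a zero-ADC pool, predicts only 3.3%
remaining signal at b = 8,000 where 14.2% was measured — an SPE an order
of magnitude above the tri-exponential variants — and has the worst
(highest) AICc. The modified tri-exponential model wins the
fit/complexity trade-off with one parameter fewer than the conventional
tri-exponential model.

On a noise-free curve the fit recovers the generating parameters
exactly, independent of the starting point:

```r
fit_voxel("modtriexp", predict_curve(wm, scheme))
```

```
modtriexp fit: rss = 9.726e-24 over 16 points (k = 4, converged in 8481 iter)
modtriexp parameters
  f0                 15.000 %
  f_slow             58.000 %
  adc_slow          816.000 x1e-6 mm^2/s
  adc_fast         4525.000 x1e-6 mm^2/s
  f_fast             27.000 % (implied)
```

Volume-level work uses `make_phantom()` / `fit_volume()` /
`run_full_analysis()`, which write NIfTI parameter and score maps plus
CSV report tables (medians and quartiles per ROI, paired Wilcoxon
signed-rank comparisons between models). The same operations are
available from a shell through the thin CLI in `exec/triexpdwi`
(`simulate`, `fit`, `compare`, `report`).

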