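# nh3wt

Hybrid wavelet-transform + machine-learning prediction of ammonia (NH₃)
concentration in poultry houses.

Ammonia is the dominant gaseous pollutant in broiler housing; elevated
levels (above roughly 25 ppm) depress weight gain, feed conversion and bird
viability, so operators want NH₃ predicted from variables that are cheap to
monitor: litter moisture content (LMC, %), litter pH (LPH), litter surface
temperature (LT, °C), air temperature (T, °C), relative humidity (RH, %) and
air velocity (V, m s⁻¹). Raw sensor series are noisy and non-stationary,
which limits plain regression models. This package is aimed at
agricultural/environmental engineers and modellers who want that hybrid
pipeline as tested, reusable code.

## The method

Each predictor series \(x(t)\) is decomposed by a periodized orthogonal
discrete wavelet transform (default `db4`, \(L = 10\) levels) into
full-length detail sub-series and an approximation satisfying the additive
multiresolution identity

    x(t) = D1(t) + D2(t) + ... + DL(t) + AL(t)

Levels whose Pearson correlation with the NH₃ series is weak
(|r| < 0.08) or sign-inconsistent with the raw predictor's overall
correlation are discarded; the sum of the retained details is the denoised
feature. Features then feed one of four regression families behind a common
fit/predict contract:

* **ELM** — extreme learning machine: hidden weights drawn once from a
  seeded Uniform(−1, 1) and frozen, activations `af(XW + b)`, output
  weights solved in closed form from `(H'H + rp I) β = H'y`;
* **KNN** — mean of the k nearest training targets under Minkowski-p
  distance;
* **RF** — seeded bootstrap regression forests with depth/size constraints
  (ranger backend);
* **LR** — ordinary least squares baseline.

Hyperparameters are tuned by grid search scored on mean validation MAE over
ten Monte-Carlo 90/10 partitions of the 80 % training pool (min-max scaling
refit inside every partition; the 20 % test set never touches the scaler or
the tuning). Models are compared by MAE (ppm) and Pearson R.

Because the underlying field data are not public, the package includes a
first-class synthetic generator that reproduces the structure the analysis
assumes — marginal locations/scales/bounds and skewness signs, a configured
signed correlation of every predictor with NH₃, and band-limited noise
injected into chosen decomposition levels so that wavelet denoising
demonstrably helps. See the vignette (`vignettes/hybrid-wavelet-ml.Rmd`)
for the generator's design and its limits.

## Worked example

```r
library(nh3wt)

dataset <- generate_dataset(generator_config(seed = 1))
stats <- summarize_dataset(dataset)
stats[-1] <- round(stats[-1], 2)
print(stats, row.names = FALSE)
#>  variable   min   max  mean   sd skewness kurtosis
#>       lmc 15.02 42.88 30.69 6.43    -0.30    -0.18
#>       lph  6.02  8.28  7.50 0.51    -0.93     0.60
#>        lt 20.00 33.40 27.87 2.47    -0.28     0.00
#>         t 19.10 32.44 24.78 3.17     0.17    -0.54
#>        rh 50.35 79.81 64.63 6.19     0.13    -0.25
#>         v  0.11  2.10  0.62 0.45     0.82     0.11
#>       nh3 13.00 26.70 19.35 2.89     0.29    -0.07
```

1600 ordered records with broiler-house-like marginals (right-skewed air
velocity, left-skewed litter pH; NH₃ mean ≈ 19.4 ppm). Now compare the
linear baseline and a random forest on the air-side inputs (T, RH, V),
with and without wavelet denoising, using the fast two-point grid:

```r
cfg <- experiment_config(families = c("lr", "rf"), combinations = "vi",
                         arms = c("raw", "wt"), grid_size = "smoke", seed = 1)
report <- run_experiment(dataset, cfg)
#>  family arm         hyperparameters train_mae train_r test_mae test_r
#>      lr raw                             1.486   0.776    1.559  0.741
#>      rf raw nt=25, d=10, ss=2, sl=3     1.066   0.895    1.517  0.743
#>      lr  wt                             1.448   0.791    1.482  0.766
#>      rf  wt nt=50, d=10, ss=2, sl=3     0.964   0.916    1.403  0.785
```

Both families improve on the denoised arm — the forest's test MAE drops
from 1.517 to 1.403 ppm (a 7.5 % reduction, `relative_improvement(1.517,
1.403)`) and its test R rises from 0.743 to 0.785 — because selection
discarded the fine-scale levels that carry injected noise rather than
signal. The per-variable decisions are attached to the report:

```r
print(attr(report, "selections")$v)
#> Component selection for 'v' (auto rule, |r| >= 0.08): overall r = -0.206
#>   selected levels: D4 + D5 + D6 + D7
```

The same pipeline is scriptable from a shell via `inst/cli/nh3wt`
(subcommands `generate`, `decompose`, `run`).

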