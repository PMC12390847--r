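# soilregimes

Functional regimes of soil microbiome nitrate metabolism under pH
perturbation.

Soil bacteria reduce nitrate during anaerobic respiration, and the rate at
which a soil community does so changes qualitatively when its pH is
perturbed. In slurry microcosms amended with 2 mM nitrate, paired
incubations with and without chloramphenicol (which arrests growth while
leaving existing enzymes active) separate the activity of pre-existing
biomass from growth. This package is for microbial ecologists and
biogeochemists analysing such experiments: it fits a minimal
consumer-resource model to the paired nitrate curves, classifies each
(soil, perturbed pH) condition into one of three functional regimes, and
carries out the companion sequencing analyses — spike-in absolute
abundance, growth and survival folds, differential enrichment with an
empirical replicate noise model, NMF growth modes, and native-pH
prediction from resurgent-growth taxa. A synthetic microcosm generator
makes every stage testable without sequencing data.

## The model

Nitrate `A`, a rescaled limiting nutrient `C̃`, and biomass activity `x̃`
(mM nitrate/day) follow

    dA/dt  = − x̃ · A/(A + K_A)
    dC̃/dt = − x̃ · C̃/(C̃ + K̃_C)
    dx̃/dt =   γ x̃ · A/(A + K_A) · C̃/(C̃ + K̃_C)

Fits hold γ = 4.8/day and K_A = K̃_C = 0.01 mM fixed (fit quality is
insensitive over wide ranges; see `sensitivity_scan()`) and estimate the
two parameters that carry the biology:

* **x̃(0)** — indigenous biomass activity (initial nitrate-reduction
  capacity), and
* **γC̃(0)** — available growth-limiting nutrient, expressed as the extra
  reduction capacity it can support.

Their position in the (x̃(0), γC̃(0)) plane defines the regimes:
**I, acidic death** (both low), **II, nutrient limiting** (high x̃(0):
linear nitrate decline), **III, resurgent growth** (low x̃(0), high
γC̃(0): near-zero initial rate, then exponential speed-up). Default
thresholds are 0.05 and 1.5 mM/day.

## Worked example

Simulate one resurgent-growth condition and fit it:

```r
library(soilregimes)
truth <- crm_params(x0_tilde = 0.02, C0_tilde = 0.9, A0 = 2, A0c = 2,
                    gamma = 4.8)
pair <- synth_nitrate_pair(truth, noise_sd = 0.02, seed = 42,
                           soil_id = "soil07", perturbed_pH = 8.5)$pair
fit <- fit_crm(pair, seed = 7)
summary(fit)
#> Consumer-resource model fit
#>   x0_tilde = 0.02054 mM/day   gamma*C0_tilde = 4.299 mM/day
#>   A0 = 2.02 mM, A0c = 1.99 mM (gamma = 4.8 /day fixed)
#>   RMSE = 2.23% of 2 mM (loss 0.002 mM^2)
#>   Functional regime: III
#>   Per-point |error| / norm quartiles:
#>     0%    25%    50%    75%   100%
#> 0.0000 0.0003 0.0035 0.0259 0.0486
```

The fit recovers the planted truth (x̃(0) = 0.02 mM/day,
γC̃(0) = 4.8 × 0.9 = 4.32 mM/day) to within the 2% measurement noise, the
per-point errors stay well below 10% of the nitrate input, and the low
initial activity combined with a large nutrient pool classifies the
condition as Regime III (resurgent growth). `plot(fit)` overlays the data
and both fitted arms; `predict()`, `residuals()` and `simulate()` behave
as for other R model objects.

Panels of replicate pairs go through `fit_crm_panel()` (median parameters
per condition) and `classify_regime()`; count tables go through
`spikein_normalize()`, `growth_folds()`, `enrichment_analysis()`,
`nmf_decompose()` and the `build_presence_matrix()`/`fit_lasso_cv()`
regression. `run_regime_pipeline()` wires all stages end to end, and
`synth_soil_gradient()`/`synth_count_table()` generate full synthetic
panels with known truth.

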