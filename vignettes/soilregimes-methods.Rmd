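---
title: "Methods: functional regimes of soil nitrate metabolism"
author: "soilregimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional regimes of soil nitrate metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilregimes)
```

# The problem

Soil microbiomes reduce nitrate during anaerobic respiration, and how fast
they do so changes dramatically when soil pH is perturbed. In microcosm
experiments, soil slurries amended with 2 mM nitrate are adjusted to a grid
of pH values and incubated anaerobically for four days, with nitrate
measured ten times (0 to 91 h). Each condition is run with and without
chloramphenicol: the drug arrests protein synthesis, so the treated arm
(chl+) reports the activity of pre-existing enzymes only, while the
untreated arm (chl-) includes growth. This package implements the full
analysis around that design: a two-parameter consumer-resource model fitted
to the paired curves, classification of conditions into three functional
regimes, spike-in-based absolute abundance from 16S amplicon counts, an
empirical replicate noise model for differential enrichment, a rank-2
non-negative matrix factorization (NMF) of phylum growth folds, and a LASSO
that predicts a soil's native pH from the taxa that grow after basic
perturbations.

# The consumer-resource model

The community is summarized by one functional biomass $x$ that reduces
nitrate $A$ while consuming a single growth-limiting nutrient $\tilde C$
(carbon, in rescaled units). After rescaling $\tilde x = r_A x$,
$\tilde C = C\, r_A / r_C$, $\tilde K_C = K_C\, r_A / r_C$, the dynamics
are

$$
\dot A = -\tilde x \frac{A}{A + K_A}, \qquad
\dot{\tilde C} = -\tilde x \frac{\tilde C}{\tilde C + \tilde K_C}, \qquad
\dot{\tilde x} = \gamma\, \tilde x \frac{A}{A + K_A}
                 \frac{\tilde C}{\tilde C + \tilde K_C}.
$$

Only two parameters carry the biology of interest:

* $\tilde x(0)$ — the *indigenous biomass activity*, in mM nitrate per day:
  the initial community-level nitrate reduction capacity.
* $\gamma \tilde C(0)$ — the *available limiting nutrient*, also expressed
  in mM nitrate per day: how much extra reduction capacity can be built by
  growing on the nutrient pool.

The chloramphenicol arm is the same system with $\gamma = 0$ and its own
initial nitrate $A_0^c$ (decision recorded in `simulate_crm`): growth is
arrested, existing enzymes keep working, and nitrate falls at the constant
rate $\tilde x(0)$ while $A \gg K_A$.

Because the affinities are small ($K_A \approx \tilde K_C \approx$ 0.01
mM), biomass grows essentially exponentially until the first
non-substitutable resource runs out, at

$$
t^* = \frac{1}{\gamma}\log\!\left(
  \frac{\min(A_0, \tilde C(0))\,\gamma}{\tilde x(0)} + 1\right),
$$

and `closed_form_crm()` gives the corresponding piecewise solution:
exponential consumption before $t^*$ and, when the nutrient is exhausted
first, a linear decline with slope $\gamma \tilde C(0) + \tilde x(0)$.

## How close is the closed form to the ODE?

The approximation ignores the Monod factors. The package's tests measure
the sup-norm gap between `closed_form_crm()` and `simulate_crm()` on a
dense four-day grid for the three regime-anchor scenarios at
$K = K_A = \tilde K_C = 0.01$ mM: roughly 0.012, 0.023 and 0.19 mM. The
large third value occurs at the resurgent-growth exhaustion corner, where
nitrate is being consumed at ~8 mM/day and the ODE's Monod-smoothed corner
lags the sharp closed-form kink; a small time offset there produces a large
vertical gap. The gap shrinks by roughly a factor of ten per decade of $K$
(to below 0.003 mM at $K = 10^{-4}$), which is the sense in which the
closed form is the small-affinity limit of the model. Statements that the
agreement is uniformly better than 0.02 mM at $K = 0.01$ are not supported
by the integration; our acceptance suite records this honestly as a failed
bound together with the passing monotone-convergence check.

Relatedly, the natural numerical surrogate for $t^*$ — the first time the
ODE's $\tilde C$ falls below $\tilde K_C$ — matches the formula only in the
small-affinity limit (0.8% relative at $K = 10^{-4}$); at $K = 0.01$ the
Monod tail delays the crossing by ~18%. The $t^*$ oracle test therefore
runs at $K = 10^{-4}$.

# Fitting

`fit_crm()` minimizes the mean-squared error over both arms,

$$
L = \frac{1}{N_- + N_+}\left[
 \sum_k \big(A(t_k^-) - a_k^-\big)^2 +
 \sum_k \big(A^c(t_k^+) - a_k^+\big)^2\right],
$$

over the free parameters $\{\tilde x(0), \tilde C(0), A_0, A_0^c\}$, with
$\gamma = 4.8$/day and $K_A = \tilde K_C = 0.01$ mM held fixed. Each arm's
sum runs over its own time points, so plates with dropped wells are
handled; the reported `rmse_norm` is $\sqrt{L}$ divided by the 2 mM nitrate
input.

Numerical choices:

* Optimizer: `stats::nlminb` (bounded PORT quasi-Newton), the base-R
  analogue of an interior-point bounded solver. $\tilde x(0)$ and
  $\tilde C(0)$ are searched on a log10 scale over $[10^{-4}, 10]$;
  $A_0, A_0^c \in [0.5, 4]$ mM.
* Multistart: one data-driven start (the chl+ slope estimates
  $\tilde x(0)$; the endpoint gap between arms estimates the nutrient pool)
  plus log-uniform random restarts, eight starts by default. The
  resurgent-growth regime has genuine local minima (a late exponential can
  be traded against a larger initial activity), and the data-driven start
  alone occasionally lands in them.
* Integration: compiled right-hand side under `deSolve::lsoda`
  (`rtol = 1e-8`, `atol = 1e-9`), with state floored at zero inside the
  rate law. When $\min(K_A, \tilde K_C) < 5\times10^{-3}$ the implicit
  Radau stepper is used instead (and as a fallback on any lsoda failure):
  the exhaustion corner becomes near-discontinuous at very small
  affinities and lsoda's interpolation fails there.
* Replicates are fitted separately and summarized by the median per
  (soil, perturbed pH) condition (`fit_crm_panel`).

Fixing $\gamma$ and the affinities is justified by `sensitivity_scan()`:
refitting the three regime-anchor simulations with $\gamma$ mis-specified
anywhere in 2-6/day changes the normalized RMSE by at most ~5%, and
mis-specifying both affinities anywhere below 0.1 mM changes it by less
than 1%. `scripts/acceptance.R` recomputes exactly these two numbers.

For literature data that report only an early-time denitrification rate
(DEA) and a long-term rate (DP), `infer_from_rates()` maps
$\tilde x(0) = \mathrm{DEA}$ and
$\gamma\tilde C(0) = \mathrm{DP} - \mathrm{DEA}$, clipped at zero with a
flag when measurement noise inverts the ordering. Carbon-amendment series
are fitted by `fit_amendment_ratio()` with a single free stoichiometry
ratio $r_A/r_C$ converting added carbon into rescaled nutrient.

# Functional regimes

`classify_regime()` places each condition in the
$(\tilde x(0), \gamma\tilde C(0))$ plane:

* **Regime I, acidic death**: both parameters low — little activity, and
  survival folds indicate cell death.
* **Regime II, nutrient limiting**: high $\tilde x(0)$, low
  $\gamma\tilde C(0)$ — linear nitrate decline set by existing biomass.
* **Regime III, resurgent growth**: low $\tilde x(0)$, high
  $\gamma\tilde C(0)$ — near-zero initial rate, then exponential speed-up
  by rare taxa.

Default thresholds are 0.05 mM/day on $\tilde x(0)$ (the valley of its
bimodal distribution) and 1.5 mM/day on $\gamma\tilde C(0)$ (the tail of
its near-zero mode); both live in `regime_thresholds()`, not in code. The
both-high quadrant carries no named regime; it is labelled II with
`ambiguous_quadrant = TRUE` so the ambiguity is surfaced rather than
hidden. `threshold_from_distribution()` re-derives thresholds from fitted
panels: the valley rule finds the KDE minimum between the two largest
modes of $\log_{10}(x + 0.01)$ (with a prominence check — the valley must
dip below 80% of the smaller mode — so unimodal wiggles are rejected), and
the tail rule returns a quantile (default 0.9) of the dominant near-zero
mode, a package choice since no closed rule accompanies the published
threshold. Thresholding operates on raw parameter values; the log
transform is visualization-only.

# Absolute abundance and folds

Known quantities of two foreign genomic DNAs are spiked into every sample
before extraction. `spikein_normalize()` merges the two spike ASVs into a
per-sample reference, removes them, and divides all counts by the spike
total; the result is absolute abundance in multiples of the spike-in DNA
quantity, insensitive to sequencing depth. QC reports the correlation of
the two spike ASVs across samples (they share every sample-level factor,
so high correlation validates the method) and the spike fraction of reads.

Growth folds isolate growth-mediated change by using the chloramphenicol
arm — not the initial community — as the reference:
$g = \log(\mathrm{Abs}^- + 10^{-3}) - \log(\mathrm{Abs}^+ + 10^{-3})$
(natural log), computed per replicate pair, summarized by the median, and
clipped below at zero. Survival folds compare the chl+ endpoint with the
initial (T0) community with the same pseudocount but are *not* clipped:
declines are the death signal. The pseudocount applies on the
absolute-abundance scale, so a taxon absent from both samples has a fold
of exactly zero.

# Differential enrichment with an empirical noise model

What change in counts is significant cannot be derived from first
principles; it is estimated from the replicate structure. Replicate
measurements of an ASV with mean $n$ counts are modelled as Gaussian with

$$\sigma(n) = \sqrt{(c_{\mathrm{frac}}\, n)^2 + c_0^2},$$

fitted per (soil, perturbed pH) because those samples are processed in
separate runs. $c_{\mathrm{frac}}$ comes from moderate-abundance ASVs
(pair mean > 50 counts) as the median absolute pairwise relative
difference scaled to a Gaussian sd ($\times 1.4826$) and divided by
$\sqrt 2$ (a replicate-replicate difference carries both measurements'
noise); $c_0$ is then the smallest value for which 67% of replicate-pair
deviations from the 1:1 line (perpendicular distance,
$|n_1 - n_2|/\sqrt2$) fall within $\pm\sigma$, found by bisection. In the
package's enrichment driver the model is fitted on spike-normalized counts
mapped back to the count scale — the same quantity the z-scores compare —
so spike-in measurement noise is part of the empirical null.

Enrichment z-scores compare arms per replicate pair (rep1-rep1, ...):
the chl- count is mapped to the chl+ arm's count scale through the spike
ratio, and

$$z = \frac{c^-\, s^+/s^- - c^+}{\sigma(\bar n + 0.5)}, \qquad
\bar n = \tfrac12\,(c^-\, s^+/s^- + c^+),$$

with the median over replicate pairs assigned to each ASV. Two details
matter and are deliberate:

* The pseudocount (0.5 counts) is applied on the common count scale, so it
  cancels exactly in the difference: an ASV absent from both arms scores
  $z = 0$ regardless of the depth ratio.
* $\sigma$ is evaluated at the *null-hypothesis mean* $\bar n$, not at the
  chl+ count alone. Evaluating it at the reference count makes $z$
  asymmetric: whenever the chl+ draw fluctuates low (to zero, say),
  $\sigma \approx c_0$ while the chl- side still carries $\sigma(n)$
  noise, and low-to-moderate-count ASVs generate systematic false
  positives. The symmetric evaluation point removes that inflation; the
  planted-signal recovery tests pass exactly under it.

ASVs are called enriched when their median $z$ exceeds the two-tailed
Bonferroni critical value $z_{\mathrm{crit}} = \Phi^{-1}(1 -
\alpha/2n_{\mathrm{ASV}})$ with $\alpha = 0.05$ and $n_{\mathrm{ASV}}$ the
non-zero ASVs of the sample pair (4.2 at 2,000 ASVs; 4.3 at 2,500).
Per regime, calls are unions over that regime's conditions, minus the
*no-nitrate responders*: ASVs enriched in the chl-/chl+ contrast of
no-nitrate controls at unperturbed pH, which respond to the incubation
itself rather than to nitrate. Note that a replicate-pair difference has
variance $2\sigma^2$ while the threshold is stated in units of one
$\sigma$; the Bonferroni margin and the median over three pairs absorb
this, and the calibration test (100 null tables) verifies that false
positives stay at the $\alpha$ level.

# Growth modes by NMF

Phylum-level growth folds across all conditions form a non-negative matrix
$G$ (40 phyla x 130 conditions at full design). `nmf_decompose()` factors
$G \approx WH$ at rank 2 by Lee-Seung multiplicative updates (Frobenius
objective) from at least ten random restarts, keeping the best; no NMF
package ships with the analysis stack, and the algorithm is ten lines. Two
post-processing steps remove the factorization's scale ambiguity: rows of
$H$ are normalized to unit length with the magnitude absorbed into $W$ (so
phylum weights are comparable across modes), and modes are ordered by
total weight. `variance_retained()` reports
$1 - \|G - WH\|_F^2 / \|G\|_F^2$; "variation retained" admits several
definitions, and the Frobenius fraction is the most common reading. On synthetic panels with the planted two-group
structure the two modes separate Bacillota (basic-pH growth) from
Pseudomonadota + Bacteroidota (moderate-pH growth) and retain over 90% of
the matrix variation.

# Predicting native pH from resurgent-growth taxa

Samples classified as Regime III form a binary presence matrix over the
enriched (grower) taxa, at a chosen taxonomic level (aggregation ORs
member presences) and relative-abundance threshold (0, 0.001 or 0.005).
`fit_lasso_cv()` fits native pH on presences with an L1 penalty chosen by
10-fold cross-validation (CV-minimum rule, seed-pinned folds, glmnet).
Prediction quality is summarized by $R^2$ on per-soil means
(`r2_by_soil`), in-sample and under leave-one-soil-out (`loso_predict`),
where all samples of one soil are held out so the model never sees the
target pH level. Significance uses a soil-level permutation test: the
soil-to-pH assignment is permuted 1,000 times (preserving the within-soil
replicate structure), the model is refitted in-sample each time, and
$p = (1 + \#\{R^2_{\mathrm{perm}} \ge R^2_{\mathrm{obs}}\})/(1 + n)$.

Degenerate designs are handled explicitly: zero-variance presence columns
are dropped before glmnet; if none remain the model degenerates to the
grand mean; and if a tiny leave-one-soil-out training set leaves a CV fold
without any varying predictor, the un-cross-validated lasso path at its
least-penalized $\lambda$ is used. One calibration property is worth
stating: on null data the LASSO shrinks to constant predictions, so many
permuted and observed $R^2$ values tie at exactly zero and the p-value
mass piles up near 1. The permutation p-value is therefore conservative
(valid), not uniform, under the null — the tests assert exactly that.

# Assay corrections

Three plate-level corrections precede fitting. Evaporation: wells holding
known 2 mM standards concentrate as the plate evaporates, and sample
readings are rescaled by nominal/control per time point. Moisture: the
soil brings its own water (5-9% gravimetric), diluting the 2 mM amendment;
assuming additive volumes and unit water density, the effective input is
$2 \times w/(w + \theta)$ for $w$ g added water and $\theta$ g soil water
per g dry soil (the published protocol states the correction but not its
arithmetic; this volume bookkeeping is the package's reading).
Chloramphenicol backgrounds: the drug reads as 0.5 mM ammonium and 0.4
mgC/ml WSOC; those constants (or measured no-nitrate chl+ controls) are
subtracted from treated samples and floored at zero.

# The synthetic microcosm generator

Every stage is testable without sequencing data because
`synth_soil_gradient()` and `synth_count_table()` generate panels with the
statistical structure the analysis assumes. Defaults are the study
conditions: 10 soils with native pH 4.7-8.3, 13 perturbed pH levels
between 3 and 9, triplicates, the ten-point 91-hour grid, 2 mM nitrate
with 2% multiplicative measurement noise, spike-ins at 8.9% of reads, and
count noise at $c_{\mathrm{frac}} = 0.21$, $c_0 = 4.5$ (the printed
Soil-11 values).

Choices that deserve justification:

* **Regime truth parameters** are drawn around the three anchor points
  ($\tilde x(0)$ = 0.01, 0.1, 0.001 mM/day with $\tilde C(0)$ = 0.005,
  0.05, 2 mM), jittered ±50% and redrawn into the planted regime's
  threshold quadrant with a 20% margin, so the planted label is exactly
  recoverable in the noiseless limit. Within Regime II, $\tilde x(0)$
  rises with perturbed pH; regime boundary pH values shift upward with
  native pH, so acidic soils enter the death regime after smaller acidic
  perturbations.
* **Count noise is the analysis's own effective model** (truncated
  Gaussian with $\sigma(c_0, c_{\mathrm{frac}})$, rounded, floored at
  zero) rather than Poisson or negative binomial: the generator must match
  the null the caller assumes.
* **Depth varies mostly across runs**: conditions are processed in
  separate sequencing runs, so the per-condition depth factor is wide
  (lognormal sd 0.7 — this drives the near-unit correlation between the
  two spike ASVs and a wide spike-fraction dispersion) while within-triplet
  depth varies little (sd 0.15) and is absorbed by the fitted noise model.
* **Spike-ins get small independent noise** (Poisson + 5% cv) on top of
  the shared depth factor: spike DNA is pipetted in known equal amounts,
  so its per-sample variability is technical, not the biological
  replicate-to-replicate variability of community ASVs. Giving spikes the
  full $c_{\mathrm{frac}}$ noise would make the spike-ratio correction a
  shared error across all ASVs of a sample and occasionally shift a whole
  condition's z-scores.
* **Planted signals**: ten Bacillota growers boosted in Regime-III
  conditions and ten Pseudomonadota/Bacteroidota growers in Regime-II
  conditions, 100-fold by default (dominant-group growth folds over four
  days reach one to two orders of magnitude; the 10-fold case is exercised
  separately as the detection-power condition); two no-nitrate responders
  planted among the abundant copiotrophic phyla and boosted in every chl-
  arm; acid-sensitive phyla (everything but Bacillota) depleted 0.3-fold
  per pH unit below 4 in endpoint samples; Regime-III growers occupy
  ±1.2-pH-unit native-pH niches so their presence carries a recoverable
  native-pH signal.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: taxonomy assignment errors and chimeras;
compositional coupling through a fixed sequencer output (growth adds reads
here rather than compressing everything else); overdispersed
library-preparation artefacts beyond the Gaussian model; nitrite and
ammonium dynamics; within-regime ecological heterogeneity beyond the ±50%
parameter jitter; and relic-DNA degradation, which in real soils mixes
with death in the survival folds.

# Problem sizes used by the tests

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in a few minutes while every statistical claim retains
power: sensitivity scans use the three anchor scenarios with five γ values
and four affinity values (27 refits, four multistarts each); parameter
recovery uses a 4-soil × 7-pH panel (28 fits); noise-model recovery uses
2,000 ASVs × 3 replicates; enrichment calibration uses 100 null tables of
2,000 ASVs and 50 powered tables; NMF and enrichment recovery use the full
10-soil × 13-pH count design (870 samples × 400 ASVs) or a 3-soil × 5-pH
reduction; the permutation test uses 1,000 permutations for the planted
signal and 16 × 49 for null calibration.

# Known limitations

* Point estimates only: no uncertainty quantification on the fitted
  parameters.
* The closed-form solution is a small-affinity limit; at the default
  affinities it deviates visibly near the resurgent-growth exhaustion
  corner (see above).
* The noise model treats replicate deviations as independent per ASV;
  sample-wide shared errors (e.g., a bad spike measurement) violate that
  assumption and are exactly why the spike-in noise convention above
  matters.
* The permutation p-value is conservative under the null because of ties
  at $R^2 = 0$.
* γ is fixed per site (default 4.8/day); the sensitivity scan justifies
  this within 2-6/day, but soils far outside that growth-rate range would
  need their own plateau scan.
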