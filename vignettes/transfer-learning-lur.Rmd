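---
title: "Transfer-learning land-use regression: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer-learning land-use regression: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lurtransfer)
```

## The modelling problem

Land-use regression predicts a pollutant concentration at a location
from traffic, population and land-use covariates. When the training
responses come from a mobile campaign — cars measuring second-by-second
on the carriageway, on weekdays between 08:00 and 22:00, visiting each
50 m road segment on a handful of days — the training domain differs
systematically from the application domain of long-term near-road
exposure:

* the mobile mean exceeds the long-term mean (on-road plumes, daytime
  traffic);
* the mobile distribution is wider;
* the correlation between mobile aggregates and long-term means at the
  same locations is only moderate, because the on-road/near-road
  difference varies from street to street (canyon geometry, distance
  decay, instrument differences).

Supervised learners trained on mobile data minimize mobile-domain risk.
The flexible ones (random forests) delineate that domain faithfully and
therefore transfer it faithfully — including its biases. This package
implements two instance-based corrections plus the two mobile-only
baselines and the validation protocol that compares all four.

## Data preparation

Roads are cut into consecutive pieces of a target length (50 m default)
with exact length conservation; a final remainder below 20% of the
target is merged into its predecessor so no sliver segments survive.
Observations are snapped to the segment with minimal Euclidean
point-to-polyline distance (all coordinates are planar meters in a
projected CRS); ties break to the lexicographically smaller segment id,
and points farther than `max_snap_distance` (default 25 m — half a wide
carriageway plus GPS error) stay unassigned. Temporal correction
compares a fixed background reference site's calendar-hour mean with
its campaign mean, subtracting the anomaly (additive mode, NO2 default)
or rescaling by the ratio (multiplicative mode, the convention for
particle counts, UFP default); both modes are no-ops for a constant
reference series. A drive-pass is a calendar date (timezone
configurable) with at least one observation on the segment. Segments
within 30 m of a long-term site form that site's validation
neighbourhood.

## The baselines

**SLR.** Forward stepwise selection from an empty model: at each step
the candidate with the largest adjusted-R² gain enters, provided the
gain exceeds 0.01 and the signs of its own and all previously selected
coefficients match the predeclared direction of association (positive
for traffic intensity, negative for green space, ...). After selection,
covariates with p > 0.10 are removed and the model refit; sign
violations introduced by removal are also pruned, so the sign invariant
holds on every returned model. At most one member of a buffer-size
family may enter (buffer variants of the same variable are nearly
collinear). The 0.01 / 0.10 thresholds are the ESCAPE-style criteria
this modelling tradition uses; VIF pruning is available behind a flag
but off by default. Adjusted-R² ties break to the smaller column index,
making the fit fully deterministic.

**RF_LUR.** A random forest (the `ranger` engine, one thread, seeded)
with the three conventionally tuned hyperparameters: number of trees,
`m_try`, and a terminal-node cap. The engine exposes a depth cap rather
than a leaf-count cap, so a cap of `k` terminal nodes is honoured as
`max.depth = ceiling(log2(k))` — a tree with at most the requested
number of leaves. Instance weights act as bootstrap sampling
probabilities: they are scale-free, and uniform weights reproduce the
unweighted fit bit-for-bit at a fixed seed (the package always passes
an explicit weight vector, so the weighted and unweighted code paths
are identical). Tuning is a grid search scored by 5-fold CV squared
Pearson R² on identical fold assignments for every grid point; the
published design's overfitting check (train R² minus test R² on a
70/30 split below 0.05) is provided as `overfit_check()`.

## Prior_RF: density-ratio risk reweighting

The prior-shift view says the domains differ mainly in the response
distribution: long-term concentrations p_t(y) versus mobile
concentrations p_s(y). Reweighting the training loss by
w(y) = p_t(y)/p_s(y) makes mobile-domain empirical risk approximate
long-term-domain risk. RuLSIF estimates the α-relative ratio

r_α(y) = p_t(y) / (α p_t(y) + (1 − α) p_s(y))

directly, as a Gaussian-kernel expansion centred on (at most 100)
target samples, with the closed-form ridge solution
θ = (Ĥ + λI)⁻¹ĥ, Ĥ = α·mean_t[k kᵀ] + (1−α)·mean_s[k kᵀ],
ĥ = mean_t[k]. Bandwidth and penalty are selected by 5-fold CV of the
RuLSIF squared-loss criterion. Numerical choices:

* α = 0.1 — a mild relative smoothing; at α = 0 the estimator is plain
  uLSIF (and is cross-checked against an independent naive
  implementation in the tests), near α = 1 the ratio flattens to 1.
* bandwidth grid = median heuristic × {0.5, 1, 2, 4}. Bandwidths far
  below the median heuristic yield spiky ratio estimates that the CV
  criterion — which is quite flat across bandwidths — cannot reliably
  reject, so they are excluded from the default grid.
* penalty grid 10⁻³…10 (log-spaced); a singular system escalates λ to
  the next grid value with a logged message.
* weights are floored at 10⁻³ (no zero-weight instances) and
  normalized to mean 1 before entering the forest, whose
  hyperparameters are kept identical to the tuned RF_LUR so the two
  models differ only in the reweighting.

The ratio is estimated on the response axis by default, matching the
prior-shift assumption; a covariate-shift variant over the predictor
space is available (`ratio_on = "covariates"`).

## Two-stage TrAdaBoost.R2

Source (mobile) and target (long-term) instances are merged with equal
initial weights. The algorithm alternates two stages over S = 10 steps:

* *Stage 2, within each step:* AdaBoost.R2 with all source weights
  frozen — only target weights adapt during boosting. AdaBoost.R2
  itself follows the classic recipe: adjusted errors e_i = L(|y_i −
  f(x_i)|/D) with D the maximum residual and L the linear loss by
  default; weighted error ε stops boosting at 0.5; β = ε/(1−ε);
  unfrozen weights update by β^(1−e_i) and renormalize; the ensemble
  predicts with the weighted median under learner weights log(1/β).
* *Stage 1, between steps:* source instances are de-emphasized
  per-instance, w_i ← w_i·β_t^{e_i}, where e_i is the instance's
  adjusted error under the current step's model — instances that
  disagree with the target-calibrated fit lose the most weight. β_t is
  found by bisection (in log space, with the β → 0 limit handled
  exactly) so the total target-weight fraction follows the schedule
  n_t/(n_s+n_t) + t/(S−1)·(1 − n_t/(n_s+n_t)), ending at full target
  weight. If perfectly fitting source instances make a fraction
  unreachable, the nearest achievable value is used and logged.

Each step is scored by 5-fold cross-validated squared error on the
target instances only (folds shrink automatically for tiny target
sets, e.g. 9 training sites), and the best step's model is returned.
The base learner is a depth-capped CART (depth 6, minimum split 5,
minimum leaf 2, complexity 0): the mild leaf regularization matters —
fully interpolating trees destabilize boosting when only a handful of
target instances carry most of the weight. All randomness (fold
assignment) derives from one seed; given the seed the fit is
deterministic because CART itself is.

Degenerate contracts: with an empty source set every step reduces to
plain AdaBoost.R2 on the target; a perfectly fitting base learner
yields a single-learner ensemble.

## The validation protocol

Per iteration (20 by default): the long-term sites split 50/50 at
random **by site** (odd counts as ceiling/floor, e.g. 17 → 9 train /
8 validate); TrAdaBoost trains on the mobile segments plus the training
half and is validated on the other half; SLR, RF_LUR and Prior_RF are
validated on the full site set, with RF_LUR and Prior_RF refit on a
bootstrap resample of the mobile segments per iteration (SLR is fit
once — the deterministic linear fit is conventionally reported without
a bootstrap CI). Sensitivity variants (`rf_lur_half`, `prior_rf_half`)
validate on the same half as TrAdaBoost to separate the effect of the
smaller validation set from the effect of the method. Site-level
predictions are means over each site's matched segments. Metrics:
nMAE and nRMSE (each normalized by the mean of the validation
observations) and squared Pearson R². Summaries are the mean, the
2.5/97.5 percentile interval of the iteration values (the "95% CI"),
and the median; improvement percentages, 100·(transfer −
conventional)/conventional, use medians and are reported to one
decimal. A model failure in an iteration is excluded from that model's
summary with a logged count.

## The synthetic generator

`generate_scene()` builds a grid street network (every 4th street
major), segments it through the same code path real roads take, and
attaches six covariates: traffic intensity, two buffer variants of
major-road proximity (a deliberate collinear family), population,
industry and green fractions (smoothly varying fields). The true
long-term surface is the declared linear combination plus a mild
quadratic traffic term and spatially correlated noise (smoothed white
noise — the exact covariance model is not material), kept positive by
construction. Scales mimic an NO2-like pollutant (~16–45 units).

`generate_mobile_campaign()` emulates the mobile domain: per segment
1 + Poisson(passes_mean − 1) drive-passes (mean 8, minimum 1), each
pass one observation on a weekday between 08:00 and 22:00 with

value = y*·(1 + a·traffic) + daytime bias + on-road excess +
day/hour temporal term + per-pass noise,

floored at zero. The temporal term is shared with an emitted reference
series so temporal correction can remove it. The **on-road excess** is
a persistent per-segment discrepancy between carriageway and near-road
levels (street geometry, instruments): it does not average out over
passes and is what drives the weak mobile-vs-long-term correlation
seen in real campaigns. `generate_longterm_network()` places a sparse
site network (82 NO2-like or 17 UFP-like sites) at a 7 m perpendicular
offset from randomly chosen segments, with low site noise (long
averaging periods).

Preset calibration (defaults, explicitly not ground truth): the
NO2-like preset targets a mobile/long-term mean ratio near 1.05 and a
matched-location R² near 0.45; the UFP-like preset targets a ratio
near 1.18 and a weak matched-location correlation. For the UFP preset
the excess spread is capped at sd 11 (matched R² ≈ 0.16 rather than
the weaker published correlation) because a larger spread would floor
a substantial share of concentrations at zero at this scene's scale —
a known limitation of emulating a particles/cm³ process on a µg/m³
scale. What the generator deliberately omits: realistic traffic
microsimulation, meteorology, instrument drift, GPS error structure
and map-matching; passing tests therefore demonstrate the estimators'
contracts and the direction of the transfer effect, not performance on
real campaigns.

## Problem sizes and expected behaviour

The test and acceptance suites run scenes of 300 segments (6×6 street
grid), forests of 250 trees, RuLSIF with up to 100 centers, and
TrAdaBoost with S = 10 × 30 estimators — sizes at which every suite
completes in minutes on a single core while leaving the comparisons
well-resolved. Under the default UFP-like shift, Prior_RF beats RF_LUR
on long-term nMAE essentially always, and TrAdaBoost — trained on 9
sites and validated on 8, the published comparison design — wins in
most repetitions but with visibly higher variance, mirroring the
published finding that boosting-based transfer fluctuates more than
density-ratio reweighting when target data are scarce. Under a
no-shift null (identically distributed domains) both transfer models
track RF_LUR within a small margin, as they should: the density ratio
is ≈ 1 and the de-emphasis schedule's early steps dominate.

## Known limitations

* The response-axis prior-shift assumption cannot repair shifts that
  are purely conditional on covariates within identical response
  distributions; the covariate-shift variant exists but is untested
  against real data.
* TrAdaBoost's step selection by CV over very small target sets (folds
  of ~2 sites) is noisy; its advantage is genuinely marginal in that
  regime.
* The GeoJSON interface is the minimal dialect the pipeline needs
  (LineString roads with `id`, Point sites with `site_id`, `value`,
  `pollutant`), not a full GIS reader, and all geometry is planar.
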