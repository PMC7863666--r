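# loonhab

Habitat-selection inference for lake-dwelling birds: do juveniles visit
lakes that resemble their natal lake more than random lake choice would
predict?

After fledging, juvenile common loons leave their natal lake to forage on
neighbouring lakes before autumn migration. Natal habitat preference
induction (NHPI) — the tendency to prefer habitats resembling the natal one —
predicts that the visited ("destination") lakes should be unusually similar
to the natal lake in traits such as pH, surface area, depth, shape and water
clarity. Testing this is complicated by spatial autocorrelation: nearby
lakes tend to share trait values, and juveniles do not fly far, so apparent
similarity may be geography rather than preference. `loonhab` implements the
full inferential pipeline for this problem, for movement ecologists working
with lake attribute tables and visit records.

## The statistics

**Randomization test.** For trait $z$ with visits $v = 1, \dots, n$, the
observed statistic is the mean absolute natal–destination difference
$\bar D_{obs} = \tfrac1n \sum_v |z_{natal(v)} - z_{dest(v)}|$. In each of
$B$ iterations (default $B = 10{,}000$) every destination is replaced by a
uniform draw, with replacement, from that visit's null pool — all suitable
lakes except the natal lake — giving a null distribution of mean
differences. The lower-tail p-value with add-one correction is

$$p = \frac{\#\{b : \bar D_b \le \bar D_{obs}\} + 1}{B + 1},$$

with Bonferroni-adjusted decisions across the five traits
($\alpha = 0.05 / 5 = 0.01$).

**Spatial guard.** Empirical semivariograms
$\gamma(h) = \frac{1}{2N_h}\sum_{i,j} (z_i - z_j)^2$ (optionally
directional, for anisotropy screening) are fitted with exponential or
spherical models by pair-count-weighted least squares; the practical range
(distance at 95% of the sill) estimates how far the trait is spatially
autocorrelated. When a trait is autocorrelated and most visits are shorter
than that range, a second, deliberately conservative test constrains each
null pool to lakes within the autocorrelation threshold of the natal lake.

**Trophic selection.** Visited trophic-class frequencies are tested against
the availability of each class among suitable lakes within 40 km of the
natal lakes, with chi-square goodness-of-fit tests
($X^2 = \sum_k (O_k - np_k)^2 / np_k$), overall and per natal class.

**Baselines.** Welch two-sample t tests compare natal and destination lake
trait distributions; great-circle travel distances and bearings are
summarised for each visit.

A synthetic landscape generator (Gaussian random pH field with exponential
covariance and controllable practical range, anisotropy and preference
strength) makes the whole pipeline testable end to end without field data.

## Worked example

```r
library(loonhab)

lakes  <- generate_landscape(landscape_config(n_lakes = 120,
           ph_field = "autocorrelated", ph_range_km = 20, seed = 1))
visits <- simulate_visits(lakes, preference_model(w_ph = 4,
           max_travel_km = 15, n_juveniles = 40, seed = 2))
analysis <- pipeline_analyze(lakes, visits, n_iterations = 2000,
                             autocorr_threshold_km = 20, seed = 3)
print(analysis)
```

```
NHPI analysis: 80 visits over 120 lakes
Spatially structured traits (majority of visits in range): area_ha, max_depth, secchi, ph

Trait-similarity randomization tests (per-test alpha 0.01 = 0.05/5)
  area_ha      observed 406.9803  null 375.7591  p = 0.8456
  max_depth    observed 38.7948  null 35.1306  p = 0.907
  shape_index  observed 1.2896  null 1.3067  p = 0.4363
  secchi       observed 2.1472  null 2.1209  p = 0.5652
  ph           observed 0.2678  null 1.0031  p = 0.0004998 *

Spatially constrained re-tests:
...
Randomization test of natal-destination similarity in 'ph'
  n = 80 visits, 2000 iterations, pool constrained to 20 km
  observed mean |diff| = 0.2678; null mean 1.0132 [0.8749, 1.1566]
  lower-tail p = 0.0004998

Trophic-class goodness of fit (all)
           CCC  CCD  CWC  CWD   SCC  SCD  SWC  SWD    TS
observed 15.00 8.00 5.00 9.00 12.00 5.00 9.00 6.00 11.00
expected 12.63 8.42 8.42 5.61 11.23 7.02 9.12 4.21 13.33
  X^2 = 5.7007, df = 8, p = 0.6807  [expected count < 5]
```

The juveniles were simulated with a pH-similarity preference (`w_ph = 4`)
and no other bias. The pipeline recovers exactly that: the observed mean
|ΔpH| of 0.27 falls far below the null expectation of 1.00 (p ≈ 5e-4,
the floor for 2,000 iterations), the effect survives the conservative
20 km pool constraint, and no other trait or the trophic-class composition
deviates from availability. The starred decision is at the Bonferroni
per-test alpha of 0.01.

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/scripts/loonhab.R`.

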