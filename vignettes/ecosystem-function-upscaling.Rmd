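---
title: "From per-capita rates to reef-level function: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From per-capita rates to reef-level function: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holofun)
```

`holofun` estimates two ecosystem functions delivered by two sympatric
Caribbean sea cucumbers — ammonium excretion and sediment processing — at
the individual level, and propagates them to per-unit-area reef-level
contributions with bootstrap uncertainty. This vignette is the package's
account of the underlying models, the choices we made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Survey geometry and density

Divers record the perimeter of each patch reef's hard bottom and of the
outer edge of its seagrass halo. Patches are quasi-circular, so
`perimeter_to_area()` applies the circular model `A = P²/(4π)` — the shape
model is an explicit argument so an ellipse variant can be added later,
but no field evidence currently justifies the extra eccentricity
parameter. Seagrass area is total minus hard-bottom area; a non-positive
difference is treated as a data error and named by reef. Densities are
individuals per m² of seagrass, and species absent from a reef are
materialised as explicit zero-density records so reef-level estimates
exist (with value 0) everywhere — cross-reef means deliberately include
absence, because absence is part of the abundance story.

## Per-capita sediment processing

Each tracked animal yields hourly pellet counts (three 1-h windows by
default), hourly distances, and a pooled pellet sample that is dried
(DW), combusted (AW), and differenced into ash-free dry weight
`AFDW = DW − AW`, with organic matter `%OM = 100·AFDW/DW`. Choices worth
stating:

* **Egestion rate is the mean of hourly counts**, not total/3, so
  variable-length observation windows (missing hours) are supported
  without bias.
* **Per-pellet weight** is the pooled dry weight over the number of
  pellets collected. When an animal yielded no pellets its hourly rate
  uses the **species-mean pellet weight**; the individual-first,
  species-mean-fallback rule is the default and a `species_mean`-only
  rule is available (`pellet_weight_rule`), since either reading is
  defensible for dot-plot-style summaries of this kind of data.
* **Annual extrapolation** multiplies the hourly rate by the species
  activity budget (12 h d⁻¹ HMEX, 10 h d⁻¹ AAGA) and 365, assuming rates
  are constant year-round. Both species also feed at night, which the
  daytime observations cannot capture, so annual figures are likely
  conservative; this is documented, not modelled.
* Egested mass is assumed equal to ingested mass (the standard
  deposit-feeder accounting assumption).

Species contrasts use Welch's t (unequal variances). Zero-variance groups
with unequal means are exact separation; rather than crash, the summary
reports the limiting `t = ±Inf, p = 0` with a warning.

## Per-capita ammonium excretion

Sealed-bag incubations give
`rate = (C_animal − mean C_control) × V × 60/t` in µmol NH₄⁺ h⁻¹.
Negative control-corrected rates are **retained and flagged**, not floored
at zero: flooring would bias species means upward, and a slightly negative
value is an honest realisation of measurement noise around a small rate.

Excretion is modelled by OLS on data-centred wet weight, species, and
their interaction, with AAGA as the reference level. The centring constant
(grand mean weight of the fitted animals) is **stored in the model**, so
predictions are reproducible independent of the fitting data. Prediction
is the conditional mean — no residual noise — and uses the full fitted
model including the interaction even when that term is not significant:
dropping terms post hoc based on p-values would make the prediction rule
data-dependent in a way that is hard to reproduce.

The length→weight allometry is a single pooled OLS over both species
(`W = a + b·L`); the species share one weak body-size relationship, and a
per-species option exists for sensitivity work. The percent difference
between species excretion means is reported on the **larger-mean base**
(means of 15.6 and 12.0 µmol h⁻¹ differ by 23% under this convention);
the conventional smaller-mean base is emitted alongside, since the two
bases are routinely confused in the literature.

## Bootstrap upscaling

For each reef × species × function, the per-area contribution is the sum
of individual rates divided by seagrass area. Uncertainty comes from a
resampling scheme (default `n_boot = 5000`) whose SE is the SD of the
resampled totals:

* **Sediment** resamples the *measured animals'* hourly-rate pool, `n_rs`
  draws with replacement — the surveyed animals on the reef were counted
  and measured but never tracked, so the species-level empirical pool is
  the only rate information available, and the reef enters through its
  count and area.
* **Ammonium** resamples the *reef's own* length-derived weight set (same
  size, with replacement) and predicts each draw's conditional-mean rate.
  Residual resampling is deliberately off by default: the bootstrap is
  meant to propagate abundance-and-size composition uncertainty, not
  refit noise; adding residual draws is a documented extension point.

The **point estimate is the plug-in value** (observed individuals, no
resampling); the bootstrap serves only the SE. A `boot_mean` rule is
available for sensitivity checks, and the two agree as `n_boot → ∞` —
asserted in the tests within 3 Monte-Carlo SEs. Zero-count species give
exact zeros for both estimate and SE.

Each (reef, species, function) draws from its own RNG stream derived by
hashing the master seed with the reef id, so estimate tables are
bit-identical under reruns, reef reordering, or parallel execution. Tests
assert the contract (determinism, order invariance), not the hash
mechanism.

For pools of ≤3 rates the bootstrap distribution can be enumerated
exhaustively; the tests check the Monte-Carlo SE against the enumerated
resample SD within 5% at 5,000 iterations — e.g. a pool {1, 3} g h⁻¹
drawn twice for AAGA on 1 m² has enumerated per-area annual SD
√2 × 10 × 365/1000 ≈ 5.163 kg m⁻² yr⁻¹.

## Cross-reef comparison conventions

* The reef-level species comparison is a **paired t across reefs** by
  default (each reef contributes both species' estimates, and reef
  effects — area, habitat quality — are shared); an unpaired Welch option
  exists. Constant per-reef differences are handled like the degenerate
  Welch case.
* Two per-reef contributions count as **equal** when their relative
  difference is ≤1% (of the larger magnitude); the tolerance is a
  parameter because "equal at one reef" needs an explicit criterion to be
  computable at all.
* Ratios of cross-reef means are reported raw and rounded to **2
  significant figures**; a non-positive denominator mean gives an
  undefined (NA) ratio rather than ±Inf.
* No multiple-testing correction is applied across the ~10 tests the
  comparison stage runs; the report records the number of tests so a
  reader can apply their own.

## The synthetic-data generator

The generator exists so the full pipeline is runnable and testable at
realistic scale without field data. Its defaults are calibrated once to
published summary statistics and are not tuned thereafter:

* **35 reefs**; AAGA counts zero-truncated negative binomial with mean 11
  and dispersion 3 (overdispersion mimics the observed 1–62 per-patch
  range); HMEX present with probability 24/35 and, when present,
  zero-truncated negative binomial with conditional mean 4×35/24 ≈ 5.8 so
  the overall mean is ~4. Treating HMEX absence as an explicit Bernoulli
  parameter (rather than a negative-binomial tail accident) makes the
  absence rate — which drives the all-reefs vs both-present contrast —
  directly controllable.
* **Lengths** truncated normal: HMEX mean 26.5 cm, SD 4.9, bounds 17–47;
  AAGA mean 21.9 cm, SD 4.3, bounds 13–45. SDs are reconstructed from
  printed standard errors as SE×√n (n = 223 and 462). Truncation uses the
  inverse-CDF construction; a configuration whose mean lies >4 SD outside
  its bounds is rejected as infeasible.
* **Seagrass areas** lognormal with mean 54 m² (sdlog 0.9, giving a
  ~5–300 m² realistic range); hard-bottom areas lognormal with mean 35 m².
  Areas are drawn first and re-expressed as the perimeters a diver would
  have measured, so the geometry stage is exercised end to end.
* **Pellet processes**: Poisson hourly counts (means 12 h⁻¹ AAGA, 3 h⁻¹
  HMEX), lognormal per-individual pellet weights (means 0.085 g and
  1.02 g), beta-distributed OM (4.5% vs 3.0%), gamma hourly distances.
  The distribution families are generator conventions, not field claims.
  The published per-hour ratios (AAGA egests ~4× faster, HMEX pellets ~7×
  heavier, HMEX processes ~3× more per hour) are mutually inconsistent as
  printed (4 × 1/7 ≠ 1/3), so the calibration prioritises the **~3×
  hourly-rate ratio** — the quantity that propagates into reef-level
  estimates — keeping the 4× count ratio and letting the weight ratio
  land at ~12×.
* **Incubations**: 40 animals (20 per species) plus 3 controls. Rates are
  generated in rate space from the true coefficients (AAGA intercept
  12.0 µmol h⁻¹, HMEX offset +3.6, weight slope 0.004 µmol h⁻¹ g⁻¹,
  residual SD 4.5 — calibrated so the fitted model's r² is ~0.17 and the
  weight term hovers around p ≈ 0.07) and back-converted to bag
  concentrations through the 20 L / 60 min arithmetic, so the incubation
  subtraction is exercised rather than bypassed. Two of the 40 animals
  have their length dropped, leaving the pooled allometry fitted on 38 —
  matching its published degrees of freedom (1, 36), which imply two
  fewer animals than were incubated.
* Per-reef length and abundance are drawn independently; no covariance
  between body size and density is imposed because none is reported.
* The ground-truth file records every generating parameter plus the
  closed-form expected per-area contribution of each species at each reef
  (`n_s × E[per-capita rate] / area`, with the activity-budget conversion
  for sediment), which the tests use as an analytic oracle.

What passing tests on synthetic data do **not** show: the generator has no
spatial autocorrelation between reefs, no tidal or depth effects, no
nocturnal activity, no handling-stress decay in incubations, and no
length–abundance covariance. Agreement on synthetic data demonstrates that
the estimators recover the generating process at field-like sample sizes —
not that any particular field system matches the defaults.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to keep the full suite
comfortably under a minute of simulation-heavy work while leaving
Monte-Carlo margins wide: parameter-recovery coverage uses 200 replicates
at the default incubation size (40 animals; 2-SE coverage must be ≥93%,
below the nominal 95.4% to absorb replicate noise); the
headline-reversal property uses 50 replicates of the full 35-reef
pipeline with a reduced `n_boot` (the property concerns plug-in point
estimates, which do not depend on the bootstrap); enumeration-oracle
checks run at `n_boot = 5000` where the 5% tolerance reflects the
Monte-Carlo SE of an SD over 5,000 draws. Degenerate inputs (zero-count
reefs, constant pools, residual-free fits, zero-variance groups) are
routed to exact limits rather than numerical near-misses.

## Known limitations

Rates are daytime rates; annual sediment figures assume year-round
constancy; the excretion model is linear in weight over the observed range
and extrapolation beyond it is allowed but logged by design review, not
prevented; the bootstrap treats the measured-animal pools as exchangeable
with surveyed animals of the same species; and per-area estimates inherit
the circular-perimeter assumption of the geometry stage.
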