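# holofun

Per-capita and reef-level ecosystem-function estimation for sympatric sea
cucumbers.

Deposit-feeding sea cucumbers (Holothuroidea) supply two quietly important
ecosystem functions on tropical patch reefs: they excrete inorganic
nitrogen as ammonium, fertilising benthic primary producers, and they
ingest and rework surface sediment. Two co-occurring Caribbean species —
*Holothuria mexicana* (`HMEX`) and *Actinopyga agassizii* (`AAGA`) — differ
in the per-individual rate at which they deliver each function, but also
in abundance, and abundance can reverse the per-capita ranking at the reef
scale. `holofun` is an R package for ecologists who want to estimate both
levels from standard field inputs: reef surveys (perimeters plus per-animal
species and length), timed fecal-pellet observations, and sealed-bag
ammonium incubations. It also ships a seeded synthetic-survey generator
calibrated to published summary statistics, so the full pipeline runs and
is testable with no field data.

## What it computes

**Per-capita rates.**
Sediment processing per individual combines the egestion rate (mean hourly
pellet count) with the per-pellet dry weight:

    hourly rate  (g h⁻¹)   = egestion rate × pellet weight
    annual rate  (kg yr⁻¹) = hourly rate × activity hours × 365 / 1000

with species activity budgets of 12 h d⁻¹ (HMEX) and 10 h d⁻¹ (AAGA), and
pellet organic matter as `%OM = 100 · (DW − AW) / DW` (ash-free dry weight
over dry weight). Ammonium excretion per individual comes from sealed-bag
incubations:

    rate (µmol NH₄⁺ h⁻¹) = (C_animal − C̄_control) × V × 60 / t

for bag volume `V` (L) and duration `t` (min). Excretion is modelled as
`rate ~ (W − W̄) × species` (OLS with data-centred wet weight, species, and
their interaction), and surveyed lengths are converted to wet weight with a
pooled linear allometry `W = a + b·L`.

**Reef-level per-area contributions.**
For each reef `r`, species `s`, and function, the population contribution
per m² of seagrass halo is estimated as

    F_rs = Σ_{i=1..n_rs} rate_i / seagrass area_r

with uncertainty from a bootstrap (default 5,000 iterations): sediment
resamples the measured animals' hourly-rate pool `n_rs` times with
replacement; ammonium resamples the reef's own length-derived weight set
and predicts each draw through the fitted excretion model. The reported SE
is the standard deviation of the resampled totals; the point estimate is
the plug-in value. Cross-reef summaries then give species means ± SE,
ratios of means, and dominance proportions (the share of reefs where each
species contributes more).

## Worked example

```r
library(holofun)

study <- generate_study(synthetic_config(seed = 42))  # 35 reefs, default calibration
dir <- file.path(tempdir(), "demo")
write_study(study, dir)

rates <- run_rates(dir)        # per-individual rates + fitted models
print(rates$allometry)
#> Length-weight allometry (pooled, n = 38)
#>   weight(g) = 175.00 + 24.71 x length(cm)
#>   F(1,36) = 20.04, p = 7.34e-05, r^2 = 0.358

contrast <- per_capita_contrast(rates$excretion)
print(contrast$means)
#>   species     n  mean    se
#> 1 AAGA       20  12.1  1.25
#> 2 HMEX       20  15.5  1.03
```

Per capita, HMEX excretes ~22% more ammonium than AAGA here (percent
difference on the larger-mean base). Upscaling reverses the ranking:

```r
estimates <- run_upscale(dir, seed = 42, n_boot = 5000)
summary <- reefwise_summary(estimates, "AMMONIUM_UMOL_M2_H")
print(summary)
#> Reef-wise summary: AMMONIUM_UMOL_M2_H (35 reefs, 25 with both species)
#>   scope        species n_reefs  mean    se
#> 1 all          AAGA         35  4.61 1.63
#> 2 all          HMEX         35  2.29 0.614
#> ...
#> AAGA:HMEX ratio of cross-reef means: all 2.01, both-present 1.68
```

Despite its lower per-capita rate, AAGA contributes about twice as much
ammonium per m² of seagrass across reefs and contributes more than HMEX at
71% of reefs (25 of 35) — its higher abundance outweighs the per-capita
deficit. `run_compare()` and `run_report()` render the full set of
species-contrast statistics; the same stages are available from a shell via
`inst/cli/holofun {simulate|rates|upscale|compare|report|all}`.

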