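# itdepot

Tissue pharmacokinetics and efficacy analysis for long-acting intratumoral
microsphere depots.

## The problem

Drugs injected into a tumor usually escape within hours. A way around this
is to tether the drug to ~50 µm hydrogel microspheres through a
β-eliminative linker: the particles stay where they are deposited, the
linker cleaves by first-order, base-catalysed elimination at a rate set by
its modulator group, and the released drug "bathes" the tumor for days to
weeks. `itdepot` is the quantitative toolkit for such systems, aimed at
pharmacologists designing or analysing depot studies:

* **Linker kinetics** — $k = \ln 2 / t_{1/2}$ conversions, the
  tenfold-per-pH-unit specific-base scaling
  $k' = k\,10^{\Delta\mathrm{pH}}$, tumor-vs-subcutaneous fold-factor
  corrections, and a YAML-backed registry of reference linkers.
* **Depot → tissue exposure** — the two-step first-order (Bateman) cascade
  $B(t) = D\,\tfrac{k_{rel}}{k_{local}-k_{rel}}(e^{-k_{rel}t} -
  e^{-k_{local}t})$ with a numerically safe equal-rate branch, peak
  exposure $t_{max} = \ln(k_{local}/k_{rel})/(k_{local}-k_{rel})$, and
  time-above-threshold windows.
* **Ratio-metric tissue PK** — the internal-standard estimator for
  destructive biopsy sampling: payload fluorescence is normalised to a
  co-attached stable marker so the measurement is independent of how much
  depot a biopsy recovers, then
  $\ln[(R/F)_t / \overline{(R/F)}_{t_0}] = -k_{rel} t$ is fitted by OLS.
  A synthetic biopsy generator with shared-recovery noise structure
  validates the estimator (and exposes the bias of the unnormalised
  alternative).
* **Efficacy analysis** — tumor growth simulation under
  concentration-driven log-kill, fractional-AUC tumor growth
  ($TG = \mathrm{AUC}_T/\mathrm{AUC}_V$, $TGI = 1 - TG$), the Bliss-style
  additivity index $TG_A TG_B / TG_{obsd}$ for combinations, and
  time-to-2000 mm³ Kaplan–Meier survival with exponential extrapolation of
  non-crossing controls.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on fitted objects, ggplot2 figures.

## Worked example

```r
library(itdepot)

# Reference linkers (literature values, editable via YAML)
linker_registry()
#>   modulator_name t_half_ref_h ph_ref temp_ref_c t_rg_h
#> 1 4-ClPhSO2                 9    7.4         37   1000
#> 2 PhSO2                    27    7.4         37   1000
#> 3 4-MePhSO2                40    7.4         37   1000
#> 4 MeSO2                   160    7.4         37     NA

# A 10 nmol depot releasing with a 156 h half-life into tissue that clears
# free drug with a 1.5 h half-life:
p <- depot_params(dose_nmol = 10, k_rel = half_life_to_rate(156),
                  k_local = half_life_to_rate(1.5))
peak_exposure(p)
#>   t_max_h c_max_nmol c_max_uM
#> 1    10.1     0.0919    0.613
time_above_threshold(p, c_thresh_um = 0.01)
#> [1] 938.5009        # ~ 5.6 weeks above 10 nM

# Simulate a biopsy cohort (t = 0/8/24/32/48 h, n = 3, 10% noise) for a
# 43 h linker and recover its half-life ratio-metrically:
set.seed(7)
rec <- simulate_release_cohort(cohort_design(), release_model(half_life_to_rate(43)))
fit_release_halflife(rec)
#> <halflife_fit: ratiometric, pellet pool>
#>   t1/2 = 41.61 h (95% CI 33.7-54.36); k = 0.01666 /h; R^2 = 0.867; n = 15

# Four-arm combination study under independent action (Bliss null):
coh <- simulate_combination_cohort(seed = 42)
analyze_combination(coh, "agent_a", "agent_b", "combination")
#>    tg_a  tg_b tg_calc tg_obsd index classification          window_end
#> 1 0.370 0.321   0.119   0.141 0.846 approximately additive         24

# The literature worked example: single-agent TGs 0.33 and 0.38 with an
# observed combination TG of 0.04
additivity_index(0.33, 0.38, 0.04)
#>    tg_a  tg_b tg_calc tg_obsd index classification
#> 1  0.33  0.38   0.125    0.04  3.14 supra-additive

# Time-to-2000 mm^3 survival with product-limit medians:
km_median(survival_times(coh))
#>   group       median_days reached label
#> 1 agent_a            44.9 TRUE    44.92
#> 2 agent_b            42.6 TRUE    42.61
#> 3 combination        42   FALSE   > 42
#> 4 vehicle            23.6 TRUE    23.62
```

Reading the numbers: the half-life fit recovers the true 43 h within its
CI from 15 noisy samples; the simulated independent-action combination
yields an index below 1 (the AUC-ratio index is conservative under
sustained exposures — see the methods vignette), so the reported observed
index of 3.1 sits far above its own null; and the combination arm's median
survival is an open bound because most animals never reach the volume
endpoint on study.

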