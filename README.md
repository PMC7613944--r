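# opioidblockr

Tools for estimating central opioid receptor blockade after opioid
antagonist administration, for researchers planning or interpreting
pharmacological-blockade studies of the human mu-opioid system.

Non-selective antagonists such as naloxone and naltrexone are the standard
instruments for probing mu-opioid-dependent processes (pain, reward, stress,
social bonding), yet doses and assessment times in the literature vary by
orders of magnitude. This package turns the available PET and dual-detector
occupancy data into quantitative answers: how much mu- (MOR), delta- (DOR),
and kappa-opioid (KOR) receptor blockade a dose produces, how long full
(>90%) MOR blockade lasts, how long to wait between sessions, and what the
drug costs.

## The models

**Dose-blockade.** Receptor blockade measured at the study's assessment
window follows a log-logistic (Hill) curve with fixed limits 0 and 100 and
Hill slope 1, leaving a single free parameter:

```
Blockade(D) = 100 * D / (D + ED50)
```

`ED50` is estimated by non-linear least squares from the packaged
observations: 16 intravenous-naloxone points (doses 0-1.0 mg/kg, assessed
~55 min post-injection) and 7 oral-naltrexone points (2-50 mg, within 8 h).

**Kinetics.** Central blockade decays exponentially with half-life 110 min
(IV naloxone) or 72 h (oral naltrexone), so `k = ln 2 / t_half`. Blockade at
the assessment window is back-extrapolated to the administration time by
`exp(k * t_measure)`, deliberately allowing pseudo-percent amplitudes above
100 (central drug levels can exceed what full blockade requires). For
naloxone, blockade peaks 25 min after a bolus; the first-order absorption
rate reproducing that peak solves `ln(ka/k)/(ka - k) = t_max`, inverted in
closed form with the lower Lambert W branch:
`ka = -W_-1(-k t_max e^(-k t_max)) / t_max`.

**Time profiles.** Blockade-time curves are closed-form one-compartment
profiles (volume 1, clearance `k`) superposing absorbed or instantaneous
boluses and zero-order infusions.

**Other receptors.** DOR and KOR ED50s are the MOR ED50 times the
antagonist's relative affinities (naloxone 1:41:8, naltrexone 1:79:2 for
MOR:DOR:KOR), with absorption and elimination assumed shared.

## Worked example

```r
library(opioidblockr)

fit <- fit_ed50(blockade_observations("iv_naloxone"), drug = "iv_naloxone")
fit
#> Log-logistic dose-blockade fit (lower 0, upper 100, Hill slope 1)
#>   drug:      iv_naloxone
#>   ED50:      0.002295  (SE 0.0004296)
#>   n = 16, RMSE = 9.432, pseudo-R2 = 0.919
```

A 0.0023 mg/kg bolus blocks half of central MOR at the 55-min assessment
window; the fit explains 92% of the variance in the published observations.

```r
full_blockade_window("iv_naloxone", dose = 0.10)
#> >90% MOR blockade from 8.9 to 76.2 min (duration 67.4 min, ~65 min)

full_blockade_window("iv_naloxone", dose = 0.01)
#> >90% MOR blockade from 13.9 to 46.5 min (duration 32.5 min, ~35 min)
```

A standard 0.10 mg/kg bolus holds full MOR blockade for about an hour; a
tenth of that dose still gives ~30 min of full blockade (with less
concurrent DOR/KOR blockade), starting ~15 min after injection.

```r
blockade_at_fit_window("oral_naltrexone", 50, c("MOR", "DOR", "KOR"))
#> # A tibble: 3 x 3
#>   receptor  dose value
#>   <chr>    <dbl> <dbl>
#> 1 MOR         50  90.0
#> 2 DOR         50  10.2
#> 3 KOR         50  81.7

washout_time(drug_defaults("oral_naltrexone")$half_life_min) / 1440
#> [1] 15
```

The standard 50 mg naltrexone tablet produces ~90% MOR and ~82% KOR
blockade but only ~10% DOR blockade, and needs a 15-day interval (five
72-h half-lives) for complete washout between sessions.

A command-line front end over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/opioid-blockade.R", package="opioidblockr"))')" \
  plan --drug iv_naloxone --dose 0.1 --weight 70
```

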