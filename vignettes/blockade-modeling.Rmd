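---
title: "Modeling central opioid receptor blockade with naloxone and naltrexone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling central opioid receptor blockade with naloxone and naltrexone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidblockr)
```

## The problem

Pharmacological blockade with non-selective opioid antagonists is the
workhorse method for testing whether a psychological or physiological
process depends on the brain's mu-opioid system. Its logic requires knowing
how much of the mu-opioid receptor (MOR) population is actually blocked at
the time the outcome is measured — and how much of the delta (DOR) and
kappa (KOR) populations is blocked alongside, since antagonist binding to
those receptors muddies the inference. Occupancy has been measured directly
with PET and dual-detector radiotracer displacement, but only at a handful
of doses and times. This package interpolates and extrapolates those
measurements with a small set of pharmacologically standard models.

## Dose-blockade model

Blockade at the assessment window is modeled as a four-parameter
log-logistic curve with the lower limit fixed at 0, the upper limit at 100,
and the Hill slope at 1:

$$\mathrm{Blockade}(D) = \frac{100\,D}{D + ED_{50}}.$$

Fixing everything but $ED_{50}$ reflects both the data (a receptor either
is or is not occupied; a zero dose blocks nothing; occupancy saturates at
100%) and the small sample: 16 observations for intravenous naloxone and 7
for oral naltrexone, several contributed by single participants. All
observations are equally weighted and the zero-dose control is kept in the
fit.

`fit_ed50()` minimizes the residual sum of squares over $\log ED_{50}$ with
a bounded golden-section search. The log parameterization guarantees
positivity and removes the scale sensitivity that the naloxone data's
three-orders-of-magnitude dose range would otherwise induce; the objective
is smooth and unimodal in $\log ED_{50}$ for monotone dose-response data,
so a bracketed 1-D search converges without an initial guess. The standard
error is the usual Gauss-Newton (linearized) estimate at the optimum with
residual variance $RSS/(n-1)$.

```{r fit}
fit <- fit_ed50(blockade_observations("iv_naloxone"), drug = "iv_naloxone")
glance(fit)
```

Two goodness-of-fit conventions coexist in this literature, so the fit
reports both: `rmse` is the root-mean-square error $\sqrt{RSS/n}$, and
`sigma` is the residual standard error $\sqrt{RSS/(n-p)}$ with $p = 1$. The
RMSE convention is the one under which the packaged naloxone refit
reproduces the fit quality reported for these data (9.4% here).
`pseudo_r2` is $1 - RSS/TSS$ with the total sum of squares taken about the
observation mean.

Residual diagnostics (`fit_diagnostics()`) run Shapiro-Wilk on the
residual vector and Levene's test across a grouping factor, by default the
measurement method (PET vs dual detector) — the only two-group split
consistent with the published df structure $(1, 14)$ for 16 observations.
Levene centering defaults to the group mean and can be switched to the
median (Brown-Forsythe). The Levene *F* value itself is sensitive to
unstated details of the original computation and is not a quantity we
attempt to reproduce; the df structure and the non-significance are.

`method_difference_test()` refits the model with a method-specific ED50.
Because the two method groups share no parameters, the joint least-squares
optimum decouples into two one-dimensional fits; the contrast's standard
error uses the pooled residual variance $RSS/(n-2)$ and the block-diagonal
Gauss-Newton covariance. The difference is parameterized as PET minus dual
detector, which for the naloxone data is positive (PET studies tended to
report lower blockade, hence higher ED50) and not significant at the 5%
level.

For the naltrexone data the refit of the seven published points gives
$ED_{50} \approx 5.58$ mg but does not exactly reproduce the originally
reported RMSE of 6.96 (a plain refit gives $\approx 7.0$ under the RMSE
convention); the original fit may have used subject-level rather than the
printed summary data. The package treats the printed values as approximate
anchors for these two summaries, not as exact targets.

## Kinetics

Central blockade (not plasma concentration) decays exponentially.
`elimination_rate()` converts the blockade half-life — 110 min for IV
naloxone, pooled from published estimates of 100 and 120 min
(`pool_half_lives()`), and 72 h for oral naltrexone — to
$k = \ln 2 / t_{1/2}$. The dose-blockade fit refers to the assessment
window; for naloxone this is taken as 55 min, the midpoint of the 45-65 min
recording window of the source studies (exposed as the `t_measure`
parameter). `back_extrapolate()` multiplies a blockade measured at
$t_{measure}$ by $e^{k\,t_{measure}}$ to obtain the amplitude at the
administration time, assuming no absorption phase. The result is
deliberately **not** truncated at 100%: central antagonist levels can
exceed what full blockade requires, and discarding that excess would
underestimate how long full blockade lasts. Internally $k$ is carried at
full precision ($0.006301\ldots$ for naloxone); the rounded 0.006 appears
only in display output, since the downstream absorption-rate value 0.126 is
only reproduced from the unrounded rate.

A one-compartment profile with first-order absorption $k_a$ and elimination
$k$ peaks at $t_{max} = \ln(k_a/k)/(k_a - k)$. Given $k$ and the observed
time-to-peak (25 min for IV naloxone), `absorption_rate()` inverts this
transcendental identity in closed form on the lower Lambert W branch:

$$k_a = -\frac{W_{-1}\!\left(-k\,t_{max}\,e^{-k\,t_{max}}\right)}{t_{max}},$$

which requires $k\,t_{max} < 1$ (a peak later than $1/k$ is unattainable
with first-order absorption) and always yields $k_a > k$. The Lambert W
evaluation delegates to `pracma::lambertWn` followed by a Halley polish;
the contract is a residual $|w e^w - x| \le 10^{-12}$, verified in the test
suite against an independent bisection solver.

Two published timing quantities are knowingly not reproduced: the pooled
time-to-peak mean of 24.7 (SE 1.2) is inconsistent with the three printed
raw values (29, 23, 26, mean 26), so the package uses the stated working
value $t_{max} = 25$ min; and oral naltrexone has no established
time-to-peak at all ("likely 1-2 h"), so naltrexone time profiles are
disabled unless the user supplies `t_max` explicitly — its headline output
is the fit-window estimate.

## Time profiles and superposition

`pk_profile()` evaluates the blockade-time curve as a pointwise sum of
closed-form single-event terms (unit volume, clearance $k$, dose replaced
by the back-extrapolated blockade amplitude): the two-exponential
absorbed-bolus (Bateman) term, the single exponential of an instantaneous
bolus, and the rise-and-washout of a zero-order infusion. No ODE solver is
involved, so superposition of events holds to machine precision and the
$k_a = k$ degeneracy is handled by its analytic limit
$A\,k\,t\,e^{-kt}$ rather than an error. The default grid is 0 to 10
elimination half-lives at 1-min resolution. Truncation at 100% is on by
default for display (occupancy cannot exceed 100%) and off inside the
planner, which needs the untruncated amplitudes.

One deliberate asymmetry, inherited from the modeled procedure: amplitudes
are back-extrapolated assuming *no* absorption phase, but forward
simulation *includes* absorption. The simulated curve at the measurement
time therefore sits slightly above the dose-response value there (~5% for
large naloxone doses). This is the documented behavior of the procedure
being modeled and is intentionally not "corrected".

## Delta- and kappa-receptor scaling

`receptor_panel()` multiplies the MOR ED50 by the antagonist's MOR:DOR and
MOR:KOR affinity ratios from cloned human receptors (naloxone 41 and 8;
naltrexone 79 and 2), giving $ED_{50}$ values of 0.094 and 0.018 mg/kg for
naloxone DOR/KOR and ~441.8 and ~11.2 mg for naltrexone DOR/KOR when chained
from the packaged fits. DOR and KOR time profiles assume the same $k$ and
$k_a$ as MOR. The published ratio *ranges* behind the display bands live in
supplementary material that is not packaged, so ratio ranges default to
absent and are user-configurable in `dose_response_curves()`; bands are
`NA` unless supplied.

## The planner

`full_blockade_window()` finds the interval where the untruncated profile
exceeds a threshold (default 90%, the conventional definition of full
blockade): crossings are bracketed on a 1-min scan and refined by bisection
to 0.01 min. Durations print both at full precision and rounded to the
nearest 5 min, the granularity at which such recommendations are usually
quoted. With the packaged naloxone model, a 0.10 mg/kg bolus gives a ~67-min
window (~65 at 5-min granularity) and 0.01 mg/kg gives ~33 min starting
~14 min post-injection.

`washout_time()` is the five-half-life rule (10 available as the
conservative option): 550 min ≈ 9 h for naloxone, 360 h = 15 days for
naltrexone.

`min_dose_for()` inverts the simulation chain analytically rather than by
search: the untruncated profile is linear in the administration amplitude,
so the required amplitude is the target divided by the unit-amplitude
profile shape at the requested time, mapped back through the elimination
correction and the inverse dose-blockade curve; the result is verified by
forward simulation to $10^{-6}$ percent. Because a single bolus's
amplitude saturates (blockade at the fit window cannot reach 100%), some
(threshold, time) combinations are unattainable by any bolus and raise a
classed error instead of returning a boundary dose.

`regimen_hold()` designs a bolus-plus-infusion regimen that maintains a
threshold from the bolus's onset to a requested hold time. The bolus is
the minimum dose first reaching the threshold at a configurable onset time
(default 15 min, the recommended minimum assessment delay for low boluses);
if the bolus's own window already covers the hold, no infusion is added.
Otherwise a zero-order infusion runs from administration to the hold time
at rate $k$ times the back-extrapolated threshold amplitude, whose steady
state sits at that amplitude and keeps the superposed profile above
threshold as the bolus washes out. Every returned regimen is re-verified by
forward simulation on a 1-min grid. The regimen's drug-equivalent total
converts the bolus amplitude exactly and the infusion via its per-minute
amplitude (the mapping is near-linear far below saturation); this
approximation is reported as `total_dose_equivalent`, not as a dose
prescription.

`cost_estimate()` rounds the total drug amount up to whole purchasable
units (0.4 mg naloxone vials at 4.58-7.07 USD; 50 mg naltrexone tablets at
4.28-9.72 USD). Price midpoints are order-of-magnitude anchors only.

## Synthetic data generator

`simulate_observations()` draws blockade values on the log-logistic curve
plus independent Gaussian noise, clipped to [0, 100] as a percent
measurement would be. Its default noise SD of 9% matches the residual
scatter of the packaged naloxone fit, and the recovery tests use the actual
16-dose naloxone design. What it emulates is measurement noise around a
correctly specified curve in a fixed design; what it does not emulate is
between-study heterogeneity, method bias (visible in the real data as the
PET/dual-detector contrast), dose-dependent variance, or censoring of
values at 100%. Passing recovery tests therefore demonstrate the
estimator's correctness and stability at the study's design and noise
level, not robustness to misspecification.

## Numerical choices and degenerate inputs

- ED50 search bracket: $[\log(\min_{+} dose) - 20,\; \log(\max dose) + 20]$;
  convergence to the bracket edge raises a convergence error rather than
  returning a boundary value.
- Designs with all-zero doses or constant blockade raise a
  degenerate-design error.
- Confidence bands (`confidence_band()`) are delta-method bands,
  $\hat f \pm t_{n-1,\,0.975}\,|\partial f/\partial ED_{50}|\,SE$, clipped
  to [0, 100]; at dose 0 both the curve and its derivative vanish, so the
  band collapses to a point.
- 100% blockade is asymptotic under the model; inversions at or above 100%
  raise an unattainable error.
- All errors are classed conditions (`opioidblockr_*`), so callers and the
  CLI can branch without parsing messages.
- Test and acceptance problem sizes: fits use the packaged 16- and 7-point
  datasets; property suites use 100-point Lambert W grids, 1-min profile
  grids over 10 half-lives, and a 500-replicate Monte-Carlo recovery run —
  all chosen to be comfortably desk-scale.

## Known limitations

- The underlying occupancy data are sparse, partly single-subject, and
  mostly from male participants; the models inherit those limits.
- Affinity-ratio scaling uses in-vitro ratios from CHO cells; human DOR/KOR
  validation data are limited and partly discordant (notably published DOR
  blockade above what the scaling predicts).
- The one-compartment, first-order framework ignores distribution-phase
  complexity and saturable elimination; it models central blockade, not
  plasma pharmacokinetics, and the two diverge during distribution.
- Repeated dosing accumulation (relevant to daily naltrexone) is outside
  the packaged models: superposition handles multiple events within a
  session, but no accumulation-to-steady-state summaries are provided.
- Nothing here is clinical dosing guidance; doses for treatment must rest
  on clinical outcomes, not occupancy arithmetic.
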