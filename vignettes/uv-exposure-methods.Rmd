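---
title: "Methods: erythemal UV exposure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: erythemal UV exposure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythemal)
```

This vignette is the package's account of its science: the models it
implements, the defaults it ships, the choices made where the design was
genuinely open, and what its synthetic-data tests do and do not demonstrate
about real observations.

## Solar geometry

All timestamps are stored and processed in UTC. The station's civil UTC
offset is used only when grouping by local calendar day or local
minute-of-day; this avoids the perennial confusion between civil time and
mean solar time (at 43.25° E the two differ by about seven minutes, and
both are colloquially called "local time").

Solar zenith angle (SZA) and local solar noon come from the NOAA/Spencer
low-precision ephemeris: solar declination and the equation of time are
Fourier series in the fractional year. The tests check it against an
independent declination approximation and a brute-force minute scan of the
daily SZA minimum; agreement is well within 0.5°, ample for a 45° filtering
gate and for the clear-sky power law, whose SZA sensitivity near the daily
minimum is weak. Refraction is ignored — it is a horizon-scale effect,
irrelevant below 90° by several orders of magnitude compared with the 0.5°
budget. The ephemeris is restricted to 1950–2100, the window over which the
series' coefficients are trustworthy.

## The clear-sky model

Clear-sky UVI is the analytic power law

$$\mathrm{UVI}_{cs} = U_0\,\mu_0^{a}\,(\Omega/\Omega_0)^{b},$$

with defaults $U_0 = 12.50$, $a = 2.42$, $b = -1.23$, $\Omega_0 = 300$ DU
(`clearsky_coef()`). The coefficients are configuration, not constants: the
same functional form with different fits appears throughout the UV
literature. The model is strictly decreasing in both SZA and total ozone
column and goes to zero continuously at the horizon, which the test suite
verifies on a 50×50 grid.

Radiative-transfer modelling (spectral resolution, ozone and temperature
profiles, aerosol optical properties) is deliberately out of scope. Two
simplifications stand in for it:

* **Altitude** is a linear gradient, `uvi * (1 + rate * altitude_km)`,
  default 6 %/km and restricted to [0, 0.25]. Observed UV altitude effects
  in the tropics span roughly 5–8 %/km depending on aerosol and albedo;
  a single configurable rate captures the first-order behaviour needed for
  hike-style altitude profiles.
* **Aerosols and surface albedo** collapse into one constant multiplicative
  `sky_factor` (default 1.0). They vary slowly compared with clouds and
  SZA, and the package consumes no aerosol climatology.

Total ozone enters as one scalar per day (a `date, toc` CSV), matching how
daily satellite ozone products are distributed.

## Clear-sky filtering

Two methods classify each minute as `clear`, `cloudy` or `unknown`:

* `cf_threshold_filter()` (**AF**): clear iff the nearest cloud-fraction
  sample within ±2 minutes has CF below the threshold *and* SZA < 45°.
  Minutes with no CF sample in tolerance are `unknown`. The ±2 min matching
  window is the package's choice; the data layer only promises nominally
  1-minute sampling with gaps, and two minutes is short relative to cloud
  evolution while tolerant of camera hiccups.
* `bell_shape_filter()` (**MF**): an explicit, parameterised version of the
  manual practice of inspecting each daily profile against the clear-sky
  bell curve. A sliding 60-minute window is clear when ≥ 90 % of its
  minutes deviate from the reference by at most 10 % (relative, with a
  0.5-UVI floor to avoid dividing by twilight values); minutes covered by
  any clear window are clear. Turning a visual judgement into a rule is the
  only way to make it reproducible; the defaults (window 60 min,
  `rel_tol` 0.10, `min_frac` 0.9, `eps` 0.5) were fixed once so that the
  two methods agree at the high-90s percent level on synthetic data with
  well-separated regimes, mirroring the agreement regime reported for
  operational stations.

`select_cf_threshold()` scans a candidate grid (default 0.05–0.95 by 0.05)
and returns the threshold maximising `sky_agreement()` between the two
masks, ties toward the smaller value. Agreement for the selection is scored
over minutes inside the SZA gate: outside it the AF mask is `cloudy`
whatever the threshold, so including those minutes adds a large constant
term that dilutes the signal without discriminating between candidates.
`sky_agreement()` itself carries no such restriction — it simply drops
minutes either mask calls `unknown` — and accepts an exclusion list, so
both the all-minutes and the daylight-only flavours are available.

## Doses and exposure categories

1 UVI = 0.025 W·m⁻² of erythemally weighted irradiance; 1 SED = 100 J·m⁻².
`sed_per_window()` integrates on a regular 1-minute grid aligned to
station-local midnight, so a window's dose is the mean irradiance times the
window length over 100. Daily totals are invariant to the window size on
gap-free days (checked to 1e−6 between 60 s and 300 s windows), and
cumulative doses match second-by-second brute-force integration to 1e−9.

**Gap policy.** Real radiometer records have holes. Gaps of at most 10
minutes are bridged by linear interpolation; longer gaps contribute zero
dose and flag the day `partial`. This is conservative — a partial day's
cumulative dose is a lower bound — and the flag lets downstream analyses
exclude such days.

**Phototype thresholds.** `fitzpatrick_thresholds()` ships daily tolerance
defaults of 2, 2.5, 3, 4.5, 6 and 10 SED for phototypes I–VI, conventional
MED-scale literature values. They are explicit configuration; every report
that uses them takes the table as an argument.

**WHO categories.** Bins follow the WHO convention with inclusive lower
bounds: [0,3) low, [3,6) moderate, [6,8) high, [8,11) very high, [11,∞)
extreme. Popular summaries sometimes shift the high/very-high boundary to
9 or 10; the 6/8/11 edges used here are the WHO standard, and the bin
constants live in one place.

## Colocation statistics

`match_estimates()` applies the distance gate first (haversine on a
6371 km sphere — sub-1 % accurate at the 10 km scale involved), then pairs
each surviving estimate with the nearest ground minute within 60 s,
averaging multiple survivors per minute. `compare_pairs()` reports
AD = estimate − ground and RD = 100·AD/ground with means, SDs and medians,
plus Pearson r and r². Two numerical choices:

* **RD floor**: pairs with ground UVI below 0.5 are excluded from RD (not
  AD) statistics, since relative differences diverge as the ground value
  approaches zero at twilight.
* Both **r and r²** are reported; validation tables in this field are
  ambiguous about which is meant, so the object carries both.

`stratify_by_sky()` splits pairs by the sky label of the ground minute, and
`comparison_table()` lays several strata side by side in the familiar
rows-of-statistics layout.

## Climatology

`monthly_climatology()` produces boxplot statistics per calendar month:
type-7 (linearly interpolated) quartiles, Tukey fences at 1.5·IQR, whiskers
at the most extreme in-fence points, and the outliers themselves. The
"about ±2.7σ" phrasing often attached to boxplot outliers *is* the
1.5·IQR fence under normality; the IQR form is used because a literal σ
fence is unstable on skewed UVI distributions. `diurnal_cycle()` groups by
station-local minute-of-day and reports mean, SD and count — the count
curve is the data-availability diagnostic that, after clear-sky filtering,
mirrors the diurnal cloud cycle inversely.

## The synthetic generator

`synthetic_config()` fixes the study conditions; every stochastic call
derives from its mandatory integer seed (per-day sub-seeds, so any day can
be regenerated in isolation), and identical configurations reproduce
identical records across platforms.

* **Diurnal cloud cycle** (`cloud_model = "diurnal"`, the default):
  a piecewise-linear baseline with total CF ≈ 0.55 at dawn, a morning dip
  to ≈ 0.45 near 09:30, a rise to a 0.80 maximum at 17:00 local, scaled by
  wet-season (Nov–Apr, ×1.15) and dry-season (×0.85) multipliers, plus
  stationary AR(1) noise (marginal sd 0.12, persistence 0.995 per minute,
  i.e. decorrelation over a few hours) clipped to [0, 1]. Thin cloud is a
  constant 0.15 deck from 08:00 local; thick cloud is the remainder.
* **Separated regimes** (`cloud_model = "separated"`): 180-minute blocks
  that are clear (CF ~ U(0, 0.1)) or cloudy (CF ~ U(0.5, 0.95)) with equal
  probability. Three hours is a realistic persistence scale for tropical
  convective cloud regimes; the configuration exposes it. This mode gives
  filtering and colocation tests known, well-separated truth.
* **Cloud modification**: `cmf = 1 − a·cf^b` with defaults a = 0.75,
  b = 2 — full overcast removes 75 % of the clear-sky index, small CF
  attenuates mildly (quadratically). On broken-cloud minutes
  (0.2 < CF < 0.7) enhancement occurs with probability 0.05, drawing
  cmf in (1, 1.2]: broken clouds backscatter and can push the surface UVI
  up to ~20 % above clear sky. The functional form is a modelling choice;
  only the attenuation/enhancement bounds are empirically anchored.
  Generated all-sky UVI is clamped to [0, 1.2 × UVI_cs].
* **Ozone**: a sinusoid with mean 260 DU and amplitude 15 DU — plausible
  tropical values, configuration only, never asserted as measurements.
* **Estimates**: one point per day at local solar noon + 60 min (satellite
  mode) or at fixed UTC forecast hours (model mode); the truth is smoothed
  over ±15 min as a surrogate for the footprint-versus-point mismatch,
  multiplied by a bias, jittered with multiplicative noise, and placed at
  coordinates within 5 km of the station. The `smooth_cloudy_only` switch
  confines the mismatch to cloudy minutes, reproducing the qualitative
  pattern that clear-sky validation statistics are tighter than all-sky
  ones.
* **Sensor noise**: multiplicative, sd 2 %, typical of a well-calibrated
  broadband radiometer.

**What the generator does not emulate**: real cloud fields (spatial
structure, anvils, haze), aerosol episodes, radiometer drift and cosine
error, satellite retrieval error structure. Passing tests on synthetic data
therefore demonstrate that the *pipeline logic* is correct under known
truth — not that any particular instrument or satellite product meets a
given accuracy.

## Problem sizes and numerical choices

The test suite and the acceptance script run the filtering study on 90
synthetic days (129,600 minutes), the colocation study on 50 days with 200
model-mode estimates, and single days elsewhere — sizes chosen so the whole
pipeline re-runs from scratch in well under a minute while leaving
Monte-Carlo error far below the tolerances being checked. Other choices:
quantiles use R's default type 7; threshold-selection ties break toward the
smaller threshold (prefer the stricter filter when indifferent); the
bell-filter's ε floor (0.5 UVI) doubles as its twilight `unknown` boundary;
`exceedance_time()` treats a zero threshold as crossed at the first
non-zero dose.

## Known limitations

* The clear-sky power law ignores aerosol and albedo variability beyond a
  constant factor; under heavy aerosol it overestimates.
* The altitude gradient is linear; above ~4 km the true dependence bends.
* The bell-shape filter can mislabel a few minutes at sharp clear/cloudy
  transitions (a window that is 90 % clear marks its whole span), which is
  the main residual disagreement between the two filtering methods on
  synthetic data.
* `sed_per_window()` assumes the 1440-minute local day; stations straddling
  DST changes are not modelled (UTC offsets are fixed per station).
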