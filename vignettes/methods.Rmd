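---
title: "Models and methods behind paleodem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleodem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodem)
```

`paleodem` infers relative population dynamics from radiocarbon dates,
typologically dated grave goods, and pollen records, and compares the
resulting time series statistically. This vignette explains each model,
its assumptions, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic validation
does and does not demonstrate.

## Calendar conventions

All series live on a `cal_axis` of integer years BCE, counting down
toward the present. Radiocarbon work uses the cal BP scale internally;
the package converts at the boundary with the fixed rule
**cal BP = BCE + 1949** (1 BCE ↔ 1950 cal BP; there is no year zero).
Publications are rarely explicit about this ±1 choice, so the package
declares one convention and applies it everywhere rather than risking
silent one-year drifts between modules. The canonical observation
window is 2850–1700 BCE; all filters and models run on the window padded
by 100 years (2950–1600 BCE) to keep KDE and calibration boundary
artefacts away from the years that are interpreted.

## Radiocarbon calibration

A determination d ± σ is modelled as
Normal(μ(θ), σ² + σ_c(θ)²) given calendar age θ, where μ and σ_c are
the calibration curve and its error, interpolated **linearly** between
knots (modern curves are published at 5-yr spacing in this era, so the
interpolation rule is visible in oracle tests and documented here for
that reason). Calibrated densities are renormalized over the axis; when
more than 0.1 % of the untruncated mass falls outside, a warning is
attached. The truncation diagnostic evaluates the likelihood on the
axis extended by ten total-sigma (clipped to curve coverage): mass
mapped further away by curve wiggles is treated as negligible, an
approximation that is exact for monotone curves.

Two modes are kept because summed probability distributions are
published both ways: *normalized* (each date contributes unit mass —
required for year-sampling, and the default everywhere) and
*unnormalized* (raw likelihood heights × step). Year-sampling from a
calibrated density always uses the normalized form, since sampling
requires a proper distribution.

The forward model `uncalibrate()` draws a measured age from
Normal(μ(θ), √(lab_error² + σ_c(θ)²)) and rounds to whole ¹⁴C years —
the rounding adds variance 1/12, negligible against laboratory errors
of 20–100 yr.

## SPD and the composite KDE model

The SPD is the cellwise sum of calibrated densities. It is kept simple
deliberately: no site binning by default, because the source datasets
this package targets are curated at the date level. An optional
site-binning switch (single-linkage clustering of ¹⁴C ages within a
site at h = 100 ¹⁴C yr, each cluster weighted equally) is available for
datasets where single over-sampled sites would otherwise dominate.

The composite KDE model addresses the SPD's known pathologies
(calibration spikes, sampling noise) by simulation. Each of `n_sim`
(default 1000) rounds:

1. resamples the n dates **with replacement at full n** (`boot = TRUE`),
2. draws one calendar year per sampled date from its calibrated density,
3. computes a Gaussian KDE (bandwidth 50 yr) on the annual axis,
   renormalized to unit mass.

The ensemble is summarized by its pointwise mean and 2.5/97.5-percentile
envelope. Two open choices deserve a note. First, "randomly selecting a
subset" of dates admits several readings; the package uses the ordinary
bootstrap (full-n, with replacement) because it is the standard
resampling scheme of the composite-KDE literature and yields a proper
sampling-error envelope — a subsampling fraction would need an arbitrary
extra parameter. Second, the envelope quantiles are fixed at 2.5/97.5 %
to match the conventional 95 % band; they are summaries of the stored
ensemble, so users can recompute any band from `model$ensemble`.

Growth rates are computed per ensemble row as
g(t) = (K(t+w)/K(t))^(1/w) − 1 (geometric annualization, forward-looking
window w = 25 yr, matching the conventional 25/50-yr binning of these
analyses) and summarized by mean and envelope. Computing on the ensemble
rather than the mean curve propagates uncertainty into the growth
envelope; a `on = "mean"` option exists for comparison. Cells with zero
density are masked (`NA`), not propagated as infinities.

## Exponential-null testing

`exp_null_test()` fits A·exp(λt) to the observed SPD by least squares
(`nls`, initialized from a log-linear fit; non-convergence is an error,
not silently patched), then simulates datasets of the observed size
from the fitted curve: calendar years drawn proportional to the null,
laboratory errors resampled from the observed error set, measurements
forward-modelled through the curve and recalibrated. The observed SPD
is compared with the simulation ensemble twice:

* **locally** — runs of years where it exits the 2.5/97.5 envelope
  become signed deviation intervals;
* **globally** — SPDs are z-scored per cell against the simulation mean
  and SD, and the summed exceedance beyond the z-envelope gives a
  statistic whose Monte Carlo p-value is (1 + #{sim ≥ obs})/(1 + n_sim).

Cells with zero simulation variance contribute nothing to the statistic
(their z-scores are forced to zero) — they carry no evidence either way.

## Aoristic sums

Spans are closed intervals of whole years: an artifact dated to [a, b]
BCE has weight 1/(a − b + 1) per in-span year, so each record
contributes exactly one unit of mass and group totals equal record
counts — an invariant the tests enforce to 1e−9. Spans truncated by the
axis keep their per-year weight and the lost mass is reported rather
than renormalized, since renormalizing would silently overweight
boundary types.

The typochronology (type code → span) ships as editable CSV config. The
period anchors are fixed by the conventional scheme — battle axes span
the MNB with the late K–L types reaching 2350–2250 BCE, daggers span
LNI (2350–1950) and LNII (1950–1700) — but the per-subtype boundaries
within those anchors are *assumptions*, documented as such, because no
canonical per-subtype table exists in print. Analyses sensitive to
subtype boundaries should vary this table. Only grave finds are
comparable across the axe/dagger divide (axes outside graves mostly
represent destroyed graves; daggers also occur in settlements and
hoards), so `contexts = "grave"` is the default restriction in the
pipeline.

## Vegetation openness

The openness score is the first principal component of the pollen
proportion matrix over a selected terrestrial taxa list. Proportions
(of the selected-taxa row sum) absorb counting depth; no transform is
applied by default because the literature this follows reports none — a
square-root switch is provided for users who prefer variance
stabilization of proportion data. The decomposition is by SVD of the
column-centered matrix; PC1's sign is fixed by requiring the mean
loading of the declared open-indicator taxa (grasses, heather, ribwort
plantain, sorrel, mugwort, cereals by default) to be positive, making
the score's orientation reproducible across platforms.

Records lacking a key discriminating taxon can be withheld from the
decomposition and only *projected* onto it afterwards
(`project_only`) — the joint loading structure is then estimated
without the distorting absence, while the record still receives scores
for observation. The `summary()` diagnostic reports PC1's variance
share and the open/forest loading separation; when the loading ranges
overlap, the openness gradient did not project onto the first axis and
the score must not be interpreted as openness for that dataset (this
failure mode occurs in practice, e.g. in regions with weak
forest/open contrast, and is why the diagnostic exists).

Regional aggregation interpolates each record's scores linearly onto a
50-yr grid **restricted to the record's own age span** (no
extrapolation), then averages records per bin without weighting; empty
bins are missing, not zero. Optional smoothing is a centered 3-bin
moving average. Age-depth modelling is out of scope: sample ages arrive
as inputs.

## Cross-proxy statistics

Detrending subtracts an OLS line; binning takes non-overlapping block
means labelled at midpoints (trailing partial bins dropped and
reported); correlations are plain Pearson r over aligned years in the
window of interest (full 2850–1700, MNB 2850–2350, LN 2350–1700 BCE).
Cross-correlation reports r at every integer-bin lag with the
convention that **positive lag means the first series leads**; lags
with fewer than three overlapping points are skipped.

Event detection z-scores a series against its own mean and SD over the
analysis window and flags maximal runs with |z| ≥ k. The threshold k
defaults to 1.0 SD: the sources name the statistic but not the
multiplier, and k = 1 flags the visually prominent excursions of
smoothed series without drowning the output; k is exposed everywhere
and should be reported with any result. A stricter
`require_envelope = TRUE` mode flags only years where the whole KDE
envelope crosses the threshold. Neither detrended series nor growth
rates are stationary, so these are descriptive anomaly markers, not
formal changepoint inference.

## Synthetic generators and what validation shows

The generators emulate the statistical structure of each proxy from
known ground truth:

* `simulate_dates()` — events drawn from a trajectory (constant,
  exponential, logistic, piecewise boom/bust), forward-modelled to
  ¹⁴C age ± error, with Dirichlet-weighted site assignment;
* `simulate_artifacts()` — deposition years from a trajectory, assigned
  the typology span containing them (ties to the narrowest span),
  optional Gaussian misdating jitter;
* `simulate_pollen()` — multinomial counts from a two-end-member
  forest/open mixture driven by an openness trajectory o(t) ∈ [0, 1],
  with Gaussian age noise emulating age-depth uncertainty.

The default synthetic calibration curve is the identity plus an
optional sinusoidal wiggle and an optional flat plateau segment, so the
plateau artefact of real curves (probability smeared over wide calendar
intervals, e.g. around 2450–2200 BCE) can be reproduced on demand.

The validation suite measures, among others: per-cell equality of
`calibrate()` with a brute-force likelihood (≤ 1e−12); mass
conservation of SPD (1e−6), aoristic sums (1e−9) and KDE rows (1e−6);
recovery of an exponential rate of 0.001/yr from the KDE mean's
log-linear slope (±30 %, n = 500 dates, the slope read off the window
trimmed by ~150 yr to avoid KDE boundary effects); boom-interval argmax
recovery (n = 800, 50 replicates); type-I calibration of the null test
at nominal 5 % (200 replicates of n = 60 dates with 99 internal
simulations each — 99 makes the 5 % level exactly attainable since
p ≤ 0.05 iff at most 4 simulations exceed the observed statistic); and
correct-sign detection of a 150-yr inter-regional lead from
growth-series cross-correlation (50 replicates of 300 dates per region,
20-simulation KDEs). These problem sizes are the package's validation
conditions — large enough for the asymptotics to bite, small enough to
run routinely.

What passing does **not** show: the generators draw i.i.d. events from
a trajectory, so they do not emulate research-history bias (clustered
sampling around excavation campaigns), taphonomic loss, marine-diet
reservoir offsets, grave-good fashion drift (the fraction of burials
with axes/daggers varied over time), or pollen-productivity differences
between taxa. Results on real data inherit all of those; the synthetic
suite validates the *computations*, not the proxies' fidelity to
population.

## Degenerate inputs and numerical details

* Zero/negative lab errors, axes outside curve coverage, all-zero
  densities, constant proportion matrices and zero-SD series are
  errors, not NaNs.
* Duplicate calibration-curve knots are rejected; files are sorted by
  θ on read, so knot order in the file is irrelevant.
* `nls` initialization for the exponential fit comes from a log-linear
  regression with values floored at max(v)·1e−9 to tolerate empty SPD
  cells.
* Span/typology ties are broken toward the narrowest (most precise)
  span; artifact deposition years covered by no span are dropped and
  counted, never silently.
* PCA sign is resolved by the open-taxa rule before any score is
  returned; taxa constant across fitted samples are dropped with a
  warning (they carry no signal and would only add zero loadings).

## Known limitations

Region membership is taken from the input's region column (no
geometry); marine reservoir correction is out of scope (shell dates are
filtered out instead); the null test offers only the exponential family
(logistic or other parametric nulls are not implemented); aoristic
fashion-drift correction and pollen-productivity (REVEALS-type)
reconstruction are out of scope. The correlation machinery reports
plain Pearson r; with non-stationary, autocorrelated series these
coefficients are descriptive and inherit the usual spurious-correlation
caveats.
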