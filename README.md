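# paleodem

Multi-proxy archaeodemographic time-series inference in R.

`paleodem` is for archaeologists and palaeoecologists who want to infer
*relative* population dynamics — never absolute numbers — from the three
proxy classes that dominate Neolithic demography studies of Southern
Scandinavia and similar regions:

1. **Radiocarbon dates** ("dates as data"): the more intense an
   occupation, the more datable material it leaves. The package
   calibrates determinations, sums them into SPDs, and fits bootstrap
   composite KDE models with Monte Carlo exponential-null testing and
   annualized growth rates.
2. **Typologically dated grave goods** (battle axes, flint daggers):
   each artifact's unit mass is spread uniformly over its
   typochronological date span and summed into an aoristic time series.
3. **Pollen records**: the first principal component of a terrestrial
   pollen proportion matrix separates forest from light-demanding taxa
   and serves as a vegetation-openness score, a proxy for human land
   opening.

Cross-proxy statistics (detrending, binning, windowed Pearson
correlation, lagged cross-correlation, SD-threshold event detection) and
seeded synthetic-data generators for all three proxy classes make every
pipeline stage testable against known ground truth without downloading
anything.

## The core models

**Calibration.** A lab measurement d ± σ (¹⁴C yr BP) is inverted through
a calibration curve (μ(θ), σ_c(θ)) into a probability distribution over
calendar years θ:

    L(θ) ∝ exp( −(d − μ(θ))² / 2(σ² + σ_c(θ)²) ) / √(σ² + σ_c(θ)²)

The SPD is the cellwise sum Σᵢ pᵢ(θ) of the calibrated densities.

**Composite KDE model.** Each of R simulations (default R = 1000)
bootstrap-resamples the n dates, draws one calendar year per date from
its calibrated density, and computes a Gaussian KDE with a fixed 50-yr
bandwidth, renormalized to unit mass. The ensemble's pointwise mean and
2.5/97.5-percentile envelope carry sampling and chronological
uncertainty. Growth rates are annualized geometrically per ensemble row:
g(t) = (K(t+w)/K(t))^(1/w) − 1 with w = 25 yr.

**Exponential-null test.** A·exp(λt) is fitted to the observed SPD by
least squares; simulated datasets drawn from the fitted null (with the
observed error mix, forward-modelled through the curve) give a pointwise
envelope, deviation intervals, and a global p-value from the summed
exceedance statistic.

**Aoristic sum.** An artifact dated to the closed span [a, b] BCE gets
weight 1/(a − b + 1) on each in-span year; group sums conserve one unit
of mass per record.

**Openness score.** Counts → proportions of the selected terrestrial
sum → column-centering → SVD; the PC1 score is oriented so open-land
indicator taxa load positively. Regional series are unweighted means of
per-record interpolations on a 50-yr grid.

## Worked example

```r
library(paleodem)
set.seed(1)

cc   <- synthetic_calcurve(3000, 5500, wiggle_amp = 15)
ax   <- cal_axis(2950, 1600)                       # 2850-1700 BCE, padded
traj <- population_trajectory(ax, "exponential", rate = 0.001)
dd   <- simulate_dates(traj, 200, cc)

m <- composite_kde(dd, cc, ax, n_sim = 50)
print(m)
#> Composite KDE model: 200 dates, 50 simulations (bootstrap on), bandwidth 50 yr
#>   axis 2950-1600 BCE; mean-curve mode at 1847 BCE

g <- kde_growth(m, window = 25)
print(detect_events(g, k = 1))
#> Event set (threshold 1 SD): 3 event(s)
#>   positive 2950-2856 BCE (peak z +4.95)
#>   negative 1812-1740 BCE (peak z -1.28)
#>   negative 1661-1625 BCE (peak z -2.73)
```

The KDE mode near 1850 BCE and the positive growth event early in the
window are exactly what an exponentially growing trajectory should
produce: density is highest at the recent end of the axis, and the
z-scored growth series flags the steepest relative growth (the
KDE-boundary rise) as its strongest excursion. On real data the same
calls — after `read_dates_csv()` and `apply_filters()` — yield the
regional boom/bust chronology; `run_full_analysis()` wires all stages
(filters → regional KDE/SPD → growth/events → aoristic → openness →
correlation tables) into one provenance-stamped bundle.

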