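---
title: "Methods: from backscatter and hydrography to micronekton habitat models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from backscatter and hydrography to micronekton habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echomix)
```

`echomix` chains four analyses that are usually run separately:
water-mass classification of CTD sections, echo integration of ship
backscatter, echo counting of single-target detections, and Tweedie GAM
habitat modelling.  This vignette documents the models, their
assumptions, the parameters that matter, and the numerical choices made
where the design was genuinely open.  A synthetic-scene generator with
known ground truth backs every claim the package's tests make.

## Water-mass mixing inversion

At each hydrographic sample the observed temperature and salinity are
assumed to arise from *linear mixing of exactly three water types*
(endmembers), giving the square system
$$x_1T_1+x_2T_2+x_3T_3=T,\qquad x_1S_1+x_2S_2+x_3S_3=S,\qquad
x_1+x_2+x_3=1 .$$
Because the system is exactly determined, `solve_mixing()` solves it
directly; the residual it reports is a numerical-health check (order
1e-15), not a model misfit.  Key choices:

* **Density layers.** Which triple of endmembers applies is decided by
  potential density anomaly: lower layer $\sigma_\theta>27.25$, middle
  $27<\sigma_\theta\le27.25$, upper $\sigma_\theta\le27$ kg m$^{-3}$.
  The boundary values themselves are measure-zero cases; they are
  assigned to the less-dense side so the rule is deterministic
  (`assign_layer(27.25)` is `"middle"`).
* **Equation of state.** $\sigma_\theta$ uses the EOS-80 one-atmosphere
  International Equation of State, computed from practical salinity and
  potential temperature.  EOS-80 was chosen over TEOS-10 because it
  operates directly on the measured practical-salinity scale without an
  absolute-salinity climatology; the formulation name travels with every
  output so downstream users can audit the choice.  The implementation
  reproduces the formulation's published check values to five decimals
  (`potential_density(5, 35)` → 27.67547 kg m$^{-3}$).
* **Negative fractions.** Observations outside the endmember triangle
  produce fractions outside $[0,1]$.  They are *flagged*
  (`in_triangle = FALSE`, with 1e-9 tolerance for roundoff at vertices)
  but never clipped or re-solved under constraints: the mixing system is
  exactly determined and constraining it would hide disagreement between
  the endmember model and the data.
* **Dominant type.** The label is the argmax of the *raw* fractions,
  ties broken by the triple's listed order, so classification is
  deterministic even on degenerate edges.
* **Endmember defaults.** The shipped registry (STUW, u-NACW, l-NACW,
  AAIW, MOW) carries illustrative reference values chosen to be
  oceanographically plausible for the North-East Atlantic and to give
  the five types well-separated densities ($\sigma_\theta$ = 25.60,
  26.55, 27.15, 27.55, 27.78 kg m$^{-3}$).  They are configuration, not
  survey calibrations, and real applications should substitute
  regionally characterised values.

A brute-force check used in the tests deserves a note: the simplex
grid-search oracle (step $10^{-3}$, minimising squared T/S
reconstruction error) is itself displaced along the thin axis of
near-collinear endmember triangles, by more than its own step.  Oracle
agreement is therefore asserted on well-conditioned triangles, while
mass conservation ($\sum x_i=1$ to $10^{-10}$) and exact reconstruction
are asserted on all of them.

## Echo integration

Sv grids are long tibbles of half-open depth bins $[z_{top},
z_{bottom})$, metres below surface, positive down; Sv depth equals
transducer depth plus range (default transducer depth 11.6 m).  Two
distinguished values keep *absence of scatterers* and *absence of data*
apart: below-threshold samples become $-\infty$ dB (zero in the linear
domain, integrating as genuine emptiness), while excluded or dropped
samples become `NA` and propagate as missing — a cell with no valid
samples reports `NA`, never 0.

* **Threshold** −85 dB re 1 m$^{-1}$; **surface exclusion** of bins
  wholly above 15 m (transducer depth plus near field); **cells** of
  5 m × 600 s with
  $\mathrm{NASC} = 4\pi\,1852^2\,\overline{s_v}\,dz$ in m$^2$
  nmi$^{-2}$.
* **Absorption/sound speed.** Re-referencing logged Sv to a revised
  absorption coefficient adds $2(\alpha_{true}-\alpha_{nom})r$ dB at
  range $r$; a revised sound speed stretches the depth axis by
  $c_{true}/c_{nom}$ about the transducer.  Both are static (profile
  averaged) corrections; re-deriving time-varied-gain sample by sample
  is out of scope.
* **Daylight filtering.** Three nested masks computed from a NOAA
  (Meeus-style) solar-position algorithm, accurate to ~0.01°: sun above
  the apparent horizon (elevation > −0.833°, the standard
  refraction-plus-radius depression); at least 1 h inside
  sunrise/sunset; and sun more than 50° above the horizon (used for DSL
  width estimation, where residual vertical migration biases widths).
  The 1-h mode is evaluated as "apparent sun up at both $t-1$ h and
  $t+1$ h", which is equivalent to the sunrise/sunset formulation for
  days with a single daylight period because elevation is unimodal
  about solar noon.  Tests compare all three masks against an
  independently formulated Astronomical-Almanac ephemeris with a ±2-min
  guard band at event boundaries.
* **DSL detection.** Per column, local maxima of the (optionally
  moving-average smoothed) *linear* profile are retained if their
  topographic prominence exceeds 3 dB — a stand-in for the visual layer
  judgement an analyst would make, and deliberately configurable.  Half-
  maximum crossings are located by linear interpolation between bins;
  width is their separation (FWHM $=2\sqrt{2\ln2}\,\sigma$ = 117.74 m
  for a Gaussian layer of $\sigma$ = 50 m).  Peaks whose half-max region
  reaches the search-window edge, or runs into an unresolved
  neighbouring layer, are flagged `truncated` rather than assigned a
  fabricated width.
* **Water-mass labels for cells.** The join rule between acoustic cells
  and the CTD section is not dictated by the analysis itself; the
  package uses nearest-station great-circle lookup, at the station depth
  nearest the cell mid-depth, because it is deterministic, assumption-
  light, and reduces to the obvious answer for a single station.

## Echo counting

Single-echo detections are accepted iff TS ≥ −80 dB re 1 m$^2$, echo
length within 0.6–1.4 of the pulse, phase deviation ≤ 10 steps, and
gain compensation ≤ 3 dB (boundaries inclusive).  Rejection reasons are
reported in the fixed evaluation order TS, length, phase, gain, so a
record violating several criteria has a deterministic label.

Densities divide accepted, range-gated echo counts per 40-m depth bin by
the acoustically sampled volume of the pings whose platform depth lay in
that bin: $V=n\,(\Omega/3)(r_{max}^3-r_{min}^3)$ with
$\Omega=10^{EBA/10}$.  The default equivalent beam angle, −20.7 dB re
1 sr, is the nominal value for a 7° split-beam transducer and is
configurable.  Volume accounting is per ping over the full gate, not per
echo.  For the headrope-mounted, forward-pointing beam, echo depth is
taken as platform depth: over a ≤ 20 m gate a 7° beam spreads less than
~1.3 m vertically, far below the 40-m bin height.  Range gates are open
intervals; a degenerate gate ($r_{min}=r_{max}$) has zero volume and
excludes everything.  Paired-frequency profiles are compared by OLS of
one profile on the other over paired non-missing bins (slope, $R^2$)
plus the overall density ratio $\sum B/\sum A$; the regression is fitted
with an intercept, since the comparison is diagnostic rather than a
calibration.

## Habitat models

Model rows join a nonnegative acoustic response to hydrographic
covariates interpolated from the nearest station's profile at the row's
mid-depth, an `hour` factor (integer UTC hours; hour resolution is a
choice — finer factors would exhaust daylight levels), and a stratum:
surface $[0,200)$ m or deep $[200,1200]$ m, with the 200-m boundary
assigned to deep so the strata partition the column.  NASC datasets are
restricted to hours 7–18.

The four canonical model structures are hour factor plus thin-plate
spline smooths: `s(temperature) + s(depth) + s(oxygen)` (NASC surface),
`s(temperature) + s(oxygen)` (NASC deep), `s(temperature) + s(depth)`
(echo surface) and `s(temperature) + s(salinity) + s(oxygen)` (echo
deep).  Fitting uses `mgcv::gam` with the Tweedie family — power
$p\in(1,2)$ handles the zero-inflated, overdispersed positive responses
— and REML estimation of both the smoothing parameters and $p$.
Screening happens in two passes: variance-inflation factors
($1/(1-R^2)$ of each covariate on the rest, iteratively dropping the
worst until all ≤ 3), then the concurvity of the fitted smooths using
mgcv's *worst-case* index (the most conservative of mgcv's three; the
0.8 cutoff flags terms for removal and refitting).  Model choice among
candidates is minimum AIC, ties to the first listed, with residual
diagnostics attached to the winner.  Non-convergence warns loudly with
the smoothing parameters attained — it is never silent.

## What the synthetic scenes do and do not emulate

`scene_config()` defaults describe a May transect from 17 to 48° N:
20 CTD stations to 1200 m at 5-m resolution; an oxygen minimum of
1.5 ml l$^{-1}$ at 200–600 m south of 21° N over a >4 ml l$^{-1}$
background; near-surface fluorescence strong north of 37° N; an upper
DSL at 400 m deepening to 550 m by 30° N, a lower DSL at 650–850 m that
vanishes north of 30° N, a 50-m surface layer absent between 37 and
45° N (peaks −70 to −75 dB over a −90 dB floor); and a single-echo
stream from a density field combining a near-surface exponential with a
mesopelagic Gaussian peak of 0.15 m$^{-3}$ at 400 m, TS ~
N(−65, 4²) dB.  Layer intensities are summed in the linear domain
(intensities add; decibels do not), echo counts are Poisson in
density × sampled volume, and ranges are drawn with density ∝ $r^2$,
mirroring conical-beam volume growth — which is exactly what makes the
sampled-volume correction testable.

The CTD construction guarantees invertibility by design: endmember
weights are built by depth-wise stick-breaking so that each sample's
active endmembers always form a subset of the triple its density layer
selects, weights below 2×10$^{-3}$ are truncated to zero and
renormalised, and the transition depths are spaced so truncation clears
each density boundary.  Noise-free casts are therefore *exact* convex
combinations, and the classifier must recover fractions to 1e-10 and
dominant labels at 100% — a round-trip identity, not a statistical
claim.

What the scenes deliberately do not contain: sound-propagation physics,
transducer noise spectra, impulse/transient interference, tides or
currents, target-strength frequency response, or avoidance behaviour.
Passing tests therefore demonstrate the *processing chain* is correct
and unbiased under the stated statistical structure, not that the
defaults describe any particular ocean.

All randomness flows from one integer seed with a fixed sub-stream per
product (ctd = seed+101, echogram = seed+202, sed = seed+303), so
products are independently reproducible; the pipeline writes a manifest
of config hash and product checksums, and identical config and seed
yield byte-identical CSVs.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: 10⁴ random mixing
samples; a 20-station noise-free transect (4 820 samples) for the
round-trip; 240-bin columns for integration oracles (fine grid 0.01 m);
100 noisy layers at 10 dB SNR for FWHM consistency; 1 000 random
(time, lat, lon) points within ±65° latitude for the ephemeris
comparison; 200 seeds of ~2 300 echoes each for density-recovery bias;
10⁶ Monte-Carlo points for the cone volume; and three n = 5 000
datasets for GAM parameter recovery.  These sizes make every stochastic
check's sampling error small relative to its tolerance while keeping a
full run light.  Conventions throughout: UTC everywhere, ISO-8601 in
files; depths in metres, positive down, half-open bins; dB re 1 m$^{-1}$
(Sv), re 1 m$^2$ (TS), re 1 sr (EBA).

## Known limitations

Cells are labelled by the nearest station, so label boundaries are
Voronoi edges rather than interpolated fronts.  The FWHM estimator
reports truncated rather than deconvolved widths when layers overlap
within their half-max regions.  Spatial autocorrelation in model
residuals is not modelled — AIC comparisons remain valid for the
candidate set but standard errors are optimistic where residual
correlation persists.  The daylight masks assume a single daylight
period per day and are untested poleward of 65°.  Echo-count responses
are aggregated per 40-m bin and deployment before modelling; when a
deployment spans few hours the `hour` factor may collapse to a single
level, in which case it is dropped from the formula.
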