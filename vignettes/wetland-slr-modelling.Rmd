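---
title: "Modelling coastal wetland response to sea-level rise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coastal wetland response to sea-level rise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidemarsh)
```

## The problem

Saline coastal wetlands occupy narrow elevation ranges set by tidal
inundation. Under rising sea level a cell's fate is decided by a race
between the local rate of sea-level rise and the rate at which the wetland
surface builds vertically (surface elevation change, SEC). Spatial models
of this race are widely used for coastal planning, and they differ mainly
in two places: how SEC is computed, and what a cell is allowed to become
when its inundation regime changes. `tidemarsh` implements one shared
raster world with three interchangeable SEC engines and two succession
rules, together with the evaluation procedures — retrospective validation,
agreement statistics, one-at-a-time sensitivity analysis and cross-engine
comparison — that such models should pass through before their projections
are taken seriously.

The setting is a wave-dominated barrier estuary of the kind found along
southeastern Australia: a constricted entrance attenuates the tide as it
propagates upstream, so the tidal range — and with it every elevation that
matters ecologically — varies along the channel.

## The raster world

Three co-registered rasters describe the state: substrate elevation (m
above a height datum), a categorical vegetation map, and a subsite map.
The seven vegetation classes are ordered by inundation frequency,

`open_water < mudflat < mangrove < mixed < saltmarsh < casuarina < upland`,

and a class's integer code is its rank in that order, so "landward of" is
an integer comparison. The `mixed` class is a mangrove–saltmarsh mosaic
and sits between the two; `casuarina` stands for the terrestrial fringe
forest above the salt boundary. Nodata is propagated, never imputed, and
every operation conserves the mask, so the per-class areas of any step sum
exactly to the unmasked area — a conservation law the test suite asserts
for every engine.

## Tides, subsites and the frequency–elevation bridge

Each subsite carries a local mean sea level offset, a great diurnal range
`GT` (MHHW–MLLW), and a salt boundary elevation stored *relative to local
MSL* so that it attenuates with the subsite automatically. Ecological
zonation is described in the literature by inundation frequency bands
(mangrove where inundation exceeds 25%, saltmarsh where it is rare, and so
on). To convert frequency `f` to elevation we assume a single-constituent
sinusoidal tide of amplitude `GT/2`:

    z(f) = (GT/2) * cos(pi * f),      f(z) = acos(2 z / GT) / pi.

A real tide is a sum of harmonics, but no tide-curve model is implied by
frequency-band zonation itself, and the sinusoid is the minimal defensible
closure. The conversion is isolated in one pair of functions
(`exceedance_elevation()`, `frequency_at()`) precisely so a harmonic-sum
tide could replace it. R's `cospi()` makes `f = 0.5` map to exactly local
MSL, and the pair invert each other to better than 1e-10 across the whole
domain.

The default bands are: mudflat (inundated 50–100% of the time), mangrove
(25–50%), mixed (12.5–25%), saltmarsh (<12.5% up to the salt boundary),
then casuarina and upland in bands whose widths are fractions of `GT`
(0.25 each by default) so that *every* between-band gap scales linearly
with the tide range. Band intervals are half-open and lower-inclusive,
`[lower, upper)`, which resolves boundary ties deterministically: a cell
exactly at local MSL is mangrove. Explicit elevation bands can be supplied
instead when a site has surveyed limits.

The no-attenuation control (`global_frame()`) broadcasts one subsite's
parameters everywhere. The reference defaults to the subsite with the
largest range — the most seaward one under attenuation — because an
open-coast gauge value is what a single-range run would naively use.

## Succession rules

The SLAMM-style rule forces each cell through the class sequence in the
seaward direction only: proposals to move landward (progradation) are
refused, and open water is absorbing — water never revegetates, however
favourable the elevations become. Because classes are rank-coded this is
just `pmin(previous, proposed)`. The boundary-free rule used by the
comparison engines accepts whatever the bands propose in either direction.
The contrast is deliberate: the inability of the constrained rule to
simulate progradation where sediment supply is high is one of the
behaviours the comparison harness is designed to expose.

## The three SEC engines

All engines return a rate field in mm/yr and share one explicit-Euler
update, `z' = z + rate * dt / 1000`. SEC — the net vertical change a
surface elevation table measures — is used in place of raw accretion
throughout, because it implicitly includes autocompaction; there is no
separate subsidence term.

* **slamm**: a flat rate per class, or optionally a rate interpolating
  linearly across the class band (accretion proportional to elevation and,
  through the bands, to tidal range). Pairs with the constrained
  succession rule.
* **cm1**: `rate = k exp(-l (z - z_low)+) exp(-m d_c)`, with `z_low` the
  lower intertidal limit (`MSL - GT/2`) and `d_c` the distance to the
  channel; zero above the salt boundary. Accretion is maximal for low
  cells on the channel bank, which produces the characteristic levee: a
  bank that keeps pace while flooding onsets landward of it. The
  exponential is re-evaluated each step against the current sea level,
  which is the minimal way to make a static empirical accretion surface
  time-dependent.
* **cm2**: a linear predictor in site covariates — days since start,
  previous-month rainfall, six-month water level, distance to shore,
  three-month SOI, and mean sea level. With covariates held constant the
  single-cell trajectory is exactly linear in time (quadratic when the
  time coefficient is non-zero), and the tests require the stepped
  trajectory to match that closed form at machine precision.

The shipped coefficient values for all three engines are synthetic
defaults of plausible magnitude for the setting; they are configuration,
not fitted site values. Whether "distance to the shore" means the channel
bank or the estuary mouth is genuinely ambiguous in the source material,
so both distances are computed (Euclidean, cell-centre, frozen at the
start of the run — distance is treated as a static morphometric
covariate) and a config switch selects one, defaulting to the channel.

## The simulation step

Each step applies operator splitting in a fixed order: (1) sea level —
every subsite's MSL rises by the scenario increment; (2) elevation — the
engine's rate field, computed from the *pre-step* classification, advances
the substrate; (3) vegetation — cells are reclassified against the new
frame and the succession policy arbitrates against the previous class.
Computing rates from the pre-step state makes steps reproducible and
matches the accrete-then-reclassify convention of cellular wetland models.
Decadal steps are the conventional resolution; the step length is a
parameter, and a convergence test compares Euler trajectories at dt = 0.1
and dt = 0.001 yr (the coarse trajectory is required to sit within 1%).

Two exact identities pin the step semantics down: zero rise with zero SEC
is a bit-identical fixed point, and SEC identically equal to the rise rate
leaves the classification unchanged while absolute elevation gains the
scenario total.

## Retrospective validation

Lacking a historic DEM, a contemporary surface is forced to represent an
earlier year by lowering every subsite's mean sea level by
`trend * years` (`backstep_datum()`); projecting forward from that state
and comparing with a mapped distribution rehearses the validation
procedure. Back-stepping then replaying the same linear trend with zero
SEC reproduces the initial classification exactly — an identity the
acceptance suite asserts for 11- and 48-year retrospections at 2.1 mm/yr.
When no historic elevation source exists at all, `veg_to_dem()` is the
vegetation preprocessor: each mapped class region is assigned its band
bounds, with elevation interpolated linearly from the lower bound at the
region's seaward edge to the upper bound at its landward edge along the
distance-to-seaward-edge axis. Regions lacking one of the two edge sets
(including single cells) sit at the band midpoint — the two-sided
interpolation is simply undefined there, and the midpoint is the neutral
choice.

## Agreement statistics and the validity rule

Two measures are computed, and only these two: the signed percent area
difference per class, `100 (modeled - observed) / observed` (negative =
underestimate; undefined ratios are reported as explicit `NA`, never
infinity), and the overlap matrix `O[i, j]` = fraction of cells modelled
as class `i` observed as class `j`, whose diagonal is a class's
"correspondence". A class passes the validity rule when its absolute
percent difference is strictly below 10%; a run passes when every defined
class passes. The strictness at exactly 10% is a deliberate tie-break,
asserted in the tests.

## Sensitivity analysis

One-at-a-time, multiplicative, ±10% by default: each named parameter is
scaled by `1 ± 0.1` with everything else fixed, the run repeated, and the
percent change of each class's final-year area recorded. Both directions
are stored; the headline table uses the +10% run — the source convention
is not documented anywhere, so the choice is fixed here and recorded in
the output rather than left implicit. Multiplicative perturbation has the
useful property that pathway-less parameters (a zero coefficient; the
historic trend in a scenario-driven forward run) give exactly zero rows,
which the tests use as a regression guard against configuration leakage.

## The synthetic estuary

All inputs are generated: a sinusoidally meandering channel incised into a
cross-shore floodplain ramp that climbs from below low-tide level at the
bank to a low backing plateau, with seeded Gaussian microtopography;
along-channel subsites with `GT(s) = GT_mouth (1 - attenuation)^km(s)`; a
salt boundary at a fixed fraction of the local range; a quadratic
(pure-acceleration) projection scenario plus a linear historic trend; and
seeded covariate series. The defaults — 120 x 200 cells at 10 m, 1.2 m
range at the mouth decaying to roughly 0.4 m at the head across eight
subsites, 2.1 mm/yr historic trend, 0.9 m rise by 2100 — describe a small
barrier estuary with strong attenuation and limited high ground, so that
rising seas squeeze the upper intertidal zone against terrestrial land.
These sizes also keep every end-to-end test in seconds; a run of the full
default world takes well under a second.

`make_initial_veg()` perturbs a zonation-consistent map by swapping a
seeded fraction of intertidal cells to an adjacent class, standing in for
the disagreement between photo-interpreted mapping and pure elevation
zonation — with the advantage that ground truth is known, so the expected
overlap diagonal is the swap fraction's complement.

What the generator does *not* emulate matters for interpreting green
tests: there is no hydrodynamic tide propagation (attenuation is imposed,
not computed), no erosion, overwash, storm or flood pulsing, no salinity
structure, and no vegetation lag — classification responds instantly to
elevation. Passing the property suite therefore demonstrates internal
consistency of the engines and procedures under controlled conditions,
not predictive skill on a real estuary; the package's own evaluation
tools are the instrument for establishing the latter against real maps.

## Numerical choices

* Half-open, lower-inclusive bands; `findInterval()` does the
  classification, so ties resolve identically regardless of floating-point
  representation.
* `cospi()` for the frequency conversion (exact at half-integers).
* Distance transforms and connected-component labelling use `EBImage`
  (Euclidean `distmap`, 4-connected `bwlabel`).
* Rates are computed from the pre-step classification (see above); masked
  cells never enter any update.
* ASCII grid values are written with 17 significant digits so write/read
  round-trips are bit-identical.
* The run loop takes a shorter final step when the horizon is not a
  multiple of `dt`, rather than overshooting the scenario.

## Known limitations

Cells evolve independently given the shared fields: there is no lateral
sediment routing, so the cm1 levee emerges purely from the distance decay,
not from flow. The vegetation preprocessor's edge cells sit exactly on the
half-open band boundary and can classify one class over on
reconstruction; the round-trip identity is guaranteed on region interiors
only. The sensitivity statistic inherits the granularity of cell counts:
on coarse grids a small perturbation can move a band boundary by less
than one cell, making the first-order linearity visible only on fine
grids (the test uses a 1 mm elevation-increment strip for exactly this
reason).
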