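---
title: "Methods: swept-area standardization, VMS effort mapping and QC in trawlmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swept-area standardization, VMS effort mapping and QC in trawlmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlmetrics)
library(dplyr)
```

`trawlmetrics` implements the computation chain of a bottom-trawl fisheries
monitoring programme: from raw haul GPS tracks and individual length
measurements to standardized abundance and biomass, quality control,
VMS-based fishing-effort maps fused with daily landings, and the static data
products a monitoring web portal serves. This vignette is the package's own
account of the underlying methods, their assumptions, and the design choices
that were genuinely open.

## The sampling design the package assumes

Scientific observers sample daily commercial trips, one haul at each of
several depth strata. For each haul the catch is sorted into four categories
— landed, discarded, natural debris and marine litter — and a weighed
subsample of each fraction is measured individual by individual. A laboratory
subsample is additionally weighed per individual; individuals measured at sea
carry only a length. Haul geometry comes from a GPS logging positions every
minute, with manual onboard fixes every 15 minutes marking the start and end
of the tow.

## Swept-area standardization

The sampling unit is the haul and the effort unit is the area swept by the
gear: swept distance times gear width. Catch is standardized to densities:

- abundance of species $x$ in length class $y$ of sample $z$
  (individuals/km²):

$$A_{xyz} = \frac{F_{xyz}\; SP_z\; DP_z}{SD \cdot GW}$$

- biomass of species $x$ in category $k$ of sample $z$ (kg/km²):

$$B_{xkz} = \frac{\sum_{i=1}^{N} w_i \; SP_z \; DP_z}{SD \cdot GW}$$

where $F$ is the count of measured individuals, $SD$ the swept distance (km),
$GW$ the gear width (km), and $w_i$ the weight of individual $i$: the
measured weight when the individual went through the laboratory, otherwise
the allometric conversion $a_x L_i^{b_x}$ (grams, converted to kg) fitted
from the laboratory individuals. Debris and litter items are always weighed
and never length-converted.

$SP$ and $DP$ are **raising factors** $\ge 1$: the ratio of the sorted
fraction weight to the measured subsample weight ($SP$), and the analogous
ratio for the sorted discard fraction ($DP$, equal to 1 in all other
categories). Some descriptions of this design call them "proportions"; the
equations only balance dimensionally if they scale a subsample *up* to the
full catch, so the package treats them as multipliers, validated to be
$\ge 1$.

Two aggregation products average these densities over groups of hauls (a
port, an area, a year-season, or the whole survey):

$$\bar A_{xy} = \frac{1}{N}\sum_{z=1}^{NS} A_{xyz}, \qquad
  \bar B_{xk} = \frac{1}{N}\sum_{z=1}^{NS} B_{xkz}$$

with $N$ the number of hauls in the group and $NS$ the number of samples in
those hauls. Two consequences of taking the formula literally, which the
tests pin down with a brute-force oracle:

- a haul whose landed and discarded samples both contain the species
  contributes the *sum* of the two sample densities before division by $N$;
- a haul where the species is absent contributes nothing to the sum but
  still counts in $N$ — the aggregate is an average over effort, not over
  presences.

### Length classes

Lengths are binned into half-open classes $[mw, (m+1)w)$ labelled by their
lower bound, so a length exactly on a boundary falls in the upper class. The
default width is 1 cm for fish and cephalopods and 0.5 cm for crustaceans
(which are measured in carapace length and span a much narrower range); both
are configurable per taxon group or can be forced globally.

### Length-weight fitting

`fit_length_weight()` estimates $a$ and $b$ by ordinary least squares on
$\log w = \log a + b \log L$, the standard estimator for allometric
length-weight parameters. The residual standard deviation on the log-log
scale doubles as the QC outlier yardstick (below). The fit requires at least
three pairs and two distinct lengths; with fewer the result would be
meaningless and the function refuses rather than extrapolating.

## Haul geometry

A haul track is cut from the raw GPS track by **timestamp**: all points in
the inclusive window spanned by the first and last onboard fix. No snapping
or boundary interpolation is applied; at a 1-minute cadence the worst-case
truncation is half a minute of tow (~46 m at 3 kn), well below the other
uncertainties of gear geometry. Onboard coordinates are used for visual
validation, never for cutting.

Swept distance sums great-circle (haversine) distances over consecutive
points with a spherical Earth of radius 6371.0 km. At haul scale (~5 km) the
difference from an ellipsoidal geodesic is far below a metre, so the simpler
model is used; distances are delegated to `geosphere::distHaversine()` with
the radius overridden. Swept area is `SD (km) × GW (m) / 1000` in km².

## Quality control

The QC layer mirrors a human-in-the-loop validation workflow: checks never
mutate data, and every finding is an issue row with a severity, a rule id and
a record locator.

- **Range check** (`length_range`): a length outside the species' usual
  range `[length_min_cm, length_max_cm]` is a *warning* — extreme values can
  be true observations that an operator confirms.
- **MCRS check** (`below_mcrs`): a *landed* individual below the species'
  minimum conservation reference size is a warning; the same individual in
  the discarded fraction is legitimate.
- **Length-weight outliers** (`lw_outlier`): weighed individuals whose
  log-weight residual from the fitted log-log line exceeds $k$ residual
  standard deviations, default $k = 3$ (configurable; no published threshold
  exists for this workflow, and 3 sd flags ~0.3% of well-behaved data).
- **Completeness** (`check_completeness()`): referential breaks — hauls
  without tracks or onboard fixes, samples pointing at missing hauls,
  individuals at missing samples, subsample weight exceeding fraction
  weight, non-positive swept area — are *errors*: the record cannot be
  processed at all.

The severity policy (out-of-range values warn, referential breaks error) is
a design choice: the workflow this mirrors distinguishes warnings from
errors without publishing criteria, and this split matches which findings an
operator can legitimately wave through.

## VMS pipeline

Commercial vessels report position, speed and course at least every 2 hours.
The pipeline is:

1. **Clean**: collapse exact (vessel, timestamp) duplicates; drop pings
   inside land polygons (point-in-polygon via `mgcv::in.out()`).
2. **Trip coding**: a trip is one vessel-day — the fleet lands daily — with
   the calendar date taken in a configurable port timezone (default
   Europe/Madrid, since landings are recorded on local dates).
3. **Densify**: linear interpolation of position at every whole 10-minute
   multiple inside the trip window. Linear interpolation in (lon, lat) is
   adequate at the 2-hour/10-minute scales involved; great-circle
   interpolation would differ by centimetres here. Interpolated pings get a
   speed recomputed as segment distance over segment duration on the
   densified mesh. A trip already on the mesh gains no points, making the
   operation idempotent.
4. **Classify**: a ping is fishing iff its speed lies in the trawling speed
   range **and** the seabed depth at its position lies in the permitted
   trawling depth band. Defaults: speed 1.0–4.5 kn (a conventional bottom
   trawling range — a convention of this package, not a published value) and
   depth 50–1000 m (the legal trawling depths of the study area). Pings with
   no bathymetry are conservatively marked not fishing.
5. **Fishing time**: each fishing ping represents 10 minutes; totals above
   the 12-hour daily legal limit raise a warning but are never truncated —
   the data may legitimately record infractions.
6. **Landings fusion**: each species' daily weight and revenue are divided
   equally among the trip's fishing pings. Trips with landings but no
   fishing pings cannot be mapped; their records are returned as
   "unallocated" and excluded, never silently dropped.
7. **Rasterize**: pings are projected onto a local square grid (default
   1 km cells — the output maps are per-km² and 1 km resolves a coastal
   shelf adequately) and accumulated per cell into effort (h/km²), landings
   (kg/km²) and revenue per unit effort, defined as
   $\sum € / (\sum h \times \text{cell area})$ and left undefined (NA) in
   cells without effort.

The grid projection is a **local equirectangular tangent plane** centred on
the grid origin rather than a formal projected CRS: at the ≤200 km extent of
a coastal effort grid the metric distortion is negligible, and it keeps the
package free of projection-library dependencies. Cell polygons are
inverse-projected back to WGS84 for the GeoJSON export.

Conservation is an invariant, not an aspiration: allocation and
rasterization preserve total kg, €, and hours to floating-point accuracy,
and the tests assert it.

## The synthetic generator

`generate_survey()` produces a complete, internally consistent dataset with
the exact structure the pipeline ingests — GPX text, onboard fixes, samples
with raising factors, laboratory weights, VMS pings and daily landings — so
every stage is testable without any field data. Defaults describe a small
campaign: 3 vessels, 4 sampling dates 45 days apart (so several
meteorological seasons appear), 3 hauls per vessel-day at 80/350/600 m
strata, 60-minute tows at 3 kn with a 25 m gear, 1-min GPS, 15-min onboard
fixes, 2-h VMS pings. Species are six demersal taxa typical of a NW
Mediterranean trawl fishery with synthetic, literature-plausible
length-weight parameters; lengths are truncated lognormal (no published
length distributions exist for this purpose, and lognormal is the
conventional skewed-positive choice); laboratory weights are
$aL^b \times$ lognormal noise (sd 0.05 on the log scale). Individuals under
the MCRS are discarded with probability 0.9, so a landed undersized
individual is rare but possible — as in real fleets. Each entity type draws
from its own seeded stream derived from the master seed, so enlarging the
fleet does not perturb haul draws.

Haul geometry goes through the *real* ingestion path (GPX text is written,
parsed, cut by the onboard window, and measured), which is why the simulated
swept distance recovers `speed × duration` to within the GPX coordinate
precision.

What the generator does **not** emulate: movement ecology, stock dynamics,
seasonality beyond the stratum weights, price variability, VMS transmission
gaps, GPS measurement noise. Tests passing on synthetic data therefore
demonstrate the *computation chain* is correct, not that the defaults
describe any real fishery.

## Numerical choices

- Export artifacts round to 6 significant digits and use stable ordering, so
  rebuilding the same product is byte-identical.
- Conservation identities are asserted at 1e-9 relative or tighter;
  floating-point summation order keeps them from being bit-exact.
- Empty groups aggregate to empty results, not errors; degenerate hauls
  (zero swept area) are errors at standardization time and completeness
  findings at QC time.
- Master seeds derive child seeds through an integer hash kept below
  $2^{31}$.

## Problem sizes

The test suite runs surveys of 3–36 hauls and fleets of up to 4 vessels × 3
days, brute-force oracle fixtures of ≤ 20 hauls × 10 species, and Monte
Carlo length-weight fits of n = 500 — sizes chosen so the full suite
completes in well under a minute per file while still exercising every
aggregation path. The acceptance script regenerates the default 36-haul
survey from its seed and recomputes every reported quantity from scratch.

## Known limitations

- The land filter needs caller-supplied polygons; no coastline ships with
  the package.
- Bathymetry is a callback; the built-in `shelf_bathymetry()` is a linear
  ramp for simulation and testing, not a real seabed model.
- The equal-split landings allocation attributes catch uniformly over a
  trip's fishing positions; it conserves totals but smears spatial detail
  within a trip, as any equal-allocation scheme does.
- Season boundaries are meteorological quarters; programmes using
  astronomical or survey-specific seasons should relabel `hauls$season`.
- The port→area mapping is data (a `ports` table), not knowledge the package
  has.
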