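---
title: "Methods: attributing vegetation change to natural, social, economic and policy drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing vegetation change to natural, social, economic and policy drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegdrivers)
```

## The problem

Long-term greening or browning of a landscape — measured here by leaf area
index (LAI), the one-sided leaf area per unit ground area — is driven by a
mixture of natural conditions (temperature, precipitation, terrain), social
and economic development, and deliberate policy such as China's
Grain-for-Green cropland-conversion program. `vegdrivers` implements a
complete attribution pipeline for a panel of administrative units (cities)
observed annually over several decades:

1. **Trend products**: per-pixel and per-series linear trends with
   significance classes and area fractions; piecewise rates around a policy
   break year.
2. **Driver construction**: per-capita / per-area socioeconomic indicators
   from yearbook-style fields, and a land-use-derived policy intensity
   variable (the Grain-for-Green ratio, GRGR).
3. **Collinearity screen**: variance inflation factors with a single-pass
   exclusion rule.
4. **Temporal attribution**: geographically and temporally weighted
   regression (GTWR) giving a local coefficient for every driver at every
   unit-year, summarized into per-year coefficient distributions, per-unit
   mean-coefficient maps, and a dominant driver per unit.
5. **Spatial attribution**: the geographical-detector factor q-statistic
   per driver and census year, averaged by driver dimension.

Every stage can run on synthetic inputs with known ground truth, so the
whole pipeline is testable without any external data.

## Models

### Local regression (GTWR)

At unit coordinates $(u_i, v_i)$ and year $t_i$,

$$y_i = \beta_0(u_i, v_i, t_i) + \sum_{k=1}^{p} \beta_k(u_i, v_i, t_i)\,
  x_{ik} + \varepsilon_i ,$$

estimated by one weighted least-squares fit per record. Record $j$ enters
record $i$'s fit with weight $w_{ij} = K(d_{ij}; b)$, where

$$d_{ij}^2 = \lambda\left[(u_i-u_j)^2 + (v_i-v_j)^2\right] +
  \mu\,(t_i-t_j)^2$$

is the standard GTWR spatiotemporal distance. We fix $\lambda = 1$ and
carry the space–time trade-off in the single ratio
$\tau = \mu/\lambda$ (km$^2$/year$^2$): with coordinates in km and time in
years, $\tau = 1$ means one year of separation counts like one kilometre.
$\tau = 0$ recovers a purely spatial GWR. The default kernel is Gaussian,
$K(d; b) = \exp(-d^2/b^2)$; a compact-support bisquare kernel is available.
Neither the kernel nor the metric parameters are dictated by the source
methodology for this class of studies, which typically leaves them
unstated; they are documented package defaults, echoed in every fit object.

**Bandwidth.** Fixed (distance) bandwidths are the default — with a few
dozen units the spatial configuration is stable — selected by minimizing
the leave-one-out cross-validation score
$\sum_i (y_i - \hat y_{\ne i}(b))^2$, where $\hat y_{\ne i}$ is the local
prediction at $i$ with the focal weight forced to zero (equivalent to
deleting the record, which the test suite verifies against literal
delete-one refits). The grid argmin is refined by golden-section search
between its neighbours; ties resolve to the smaller bandwidth. An adaptive
(k-nearest-neighbour) bandwidth and a hat-trace AICc criterion are
available. An optional outer grid selects $\tau$ on the same criterion
(default candidates 0.25, 1, 4 km²/yr²).

**Numerical safeguards.** The focal record is included in its own fit
(standard GWR practice); LOOCV removes it only for scoring. A local
cross-product matrix that fails to invert is retried once with a
trace-scaled ridge ($10^{-8}\,\overline{\mathrm{diag}}$) and the record
flagged; flagged records are excluded from summaries, and a fit aborts if
more than 10 % of records are unsolvable (the advice is a larger
bandwidth). Two limit properties anchor correctness: at astronomically
large bandwidths all local estimates collapse onto global OLS, and
zero-noise data from one global linear model is reproduced exactly at any
bandwidth.

**Standardization.** Variables are z-scored across all unit-years before
GTWR (invertibly; parameters stored). This makes coefficient magnitudes
comparable across drivers, which the dominant-factor rule needs. The
dominant driver of a unit is the factor with the largest absolute
*time-mean* standardized coefficient, signed by that mean; alternatives
(final-year coefficient, mean $|\beta x|$ contribution) sit behind a flag
because the selection rule is genuinely open in this literature.

### Spatial heterogeneity (geographical detector)

For a stratification $h = 1, \dots, L$ of a candidate driver,

$$q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2}
    = 1 - \frac{SSW}{SST},$$

with **population** variances throughout, so that $SSW + SSB = SST$ holds
exactly for unequal stratum sizes (with sample variances it does not, and
$q$ could stray outside $[0,1]$). Continuous drivers are discretized by
sample quantiles with $L = 5$ by default (ties to the lower stratum, empty
strata collapsed); Jenks natural breaks (exact dynamic program) and equal
intervals are alternatives, because the stratification scheme behind any
given published q-table is rarely stated — which is also why such tables
are not exactly reproducible even with the source data.

Significance defaults to a seeded permutation test
($p = (1 + \#\{q_{\text{perm}} \ge q_{\text{obs}}\}) / (B+1)$, $B = 999$),
which is distribution-free and calibrated (the suite checks type-I error
at $N = 200$ over 200 replicates). The canonical noncentral-F reference —
$F = \frac{N-L}{L-1}\frac{q}{1-q}$ against
$F(L-1, N-L;\lambda)$, $\lambda = \big(\sum_h \bar y_h^2 -
\frac{1}{N}(\sum_h \sqrt{N_h}\,\bar y_h)^2\big)/\sigma^2$ — is provided
for parity with the standard geodetector software.

Dimension-averaged explanatory power is the unweighted mean of available
q-values within each driver dimension (natural, social, economic, policy)
per year; missing cells (e.g. the policy driver before the program existed)
are excluded from the mean and never imputed as zero.

### Trends

The per-series trend is the OLS slope
$\hat\beta = \sum(t-\bar t)(y - \bar y) / \sum(t-\bar t)^2$ with a
two-sided t-test on $n-2$ df — the estimator that matches the
"significant increase ($p < 0.05$)" idiom; Theil–Sen with a Mann–Kendall
test is available for outlier-heavy series, since trend papers frequently
leave the estimator unstated. Classification is total and mutually
exclusive: `SIG_INC`/`NONSIG_INC`/`NONSIG_DEC`/`SIG_DEC` by slope sign and
$p < \alpha$, with an exact-zero slope as its own `FLAT` class (mergeable
into `NONSIG_INC` for area summaries via `merge_flat`). Cells with fewer
than three finite values are `NO_DATA` and excluded from area fractions.
Piecewise rates around a split year (2000 by policy context, configurable)
include the split year in *both* segments, matching the
"1980–2000" / "2000–2019" convention.

### Indicators and the Grain-for-Green ratio

Socioeconomic indicators are exact ratios of yearbook fields (population
density; employed/total population; per-capita investment, GDP and retail
sales; fiscal expenditure/revenue; grain yield per sown hectare;
tertiary/secondary GDP; GDP/investment; urban/rural income). Records with
a zero denominator are excluded with a logged reason, never silently
patched. Monetary values are used nominal — no deflator is part of the
design.

The policy variable is built from annual land-use class grids:

* **Permanent cropland** = cells classified cropland in *every* baseline
  year (1980–2000 by default) — a strict conjunction.
* **GRGR(unit, year)** = permanent-cropland cells in the unit's zone that
  have *ever* been forest, shrubland or grassland in any
  conversion-window year $\le$ the target year, divided by the zone's
  cropland base. "Ever converted" makes the ratio cumulative and
  monotone; reversion to cropland does not decrement it.
* The denominator is configurable — baseline-union cropland (default),
  permanent cropland only, or contemporaneous cropland — because
  "total cropland area" in this indicator's usual definition does not pin
  down a reference year; the choice is recorded in the output.

### Collinearity

$\mathrm{VIF}_j = 1/(1-R_j^2)$ from regressing predictor $j$ on the others
with intercept (QR-based; exact collinearity reported as `Inf`, not an
error). Screening is **single-pass** at threshold 7.5 — everything above
the cutoff is dropped at once, mirroring the practice of removing a named
set of collinear indicators together — with an iterative
remove-the-worst mode behind a flag. VIF is computed on the pooled panel
(all unit-years as rows), as in a single global OLS.

## The synthetic-data generator

The generator defines the reference study conditions and gives every
stage a recoverable target:

* **Panel** (default 50 units × 40 years, 1980–2019): units on a jittered
  regular grid (jitter sd = 5 % of spacing) over a 1000 × 600 km planar
  domain; coefficient surfaces affine in $(u, v, t-t_0)$ — smooth enough
  for a local regression to track, with closed-form truth stored alongside
  the panel; predictors i.i.d. (optionally equicorrelated) Gaussian;
  response noise sd 0.1 in response units by default, a realistic
  interannual residual for a basin-scale vegetation index.
* **Trend raster**: each cell gets an intended class
  (significant/non-significant × increasing/decreasing), a linear signal
  sized so that intended-significant slopes are detectable at
  $\alpha = 0.05$ with high probability at the default noise, and an
  i.i.d. Gaussian noise track. The label grid ships with the raster. Worked
  examples that check fraction recovery use strong slopes and small noise
  so that the intended sign is essentially always recovered.
* **Land-use stack**: a configured cropland fraction at baseline (a small
  churn fraction lapses for one interior baseline year, so the
  "permanent" conjunction is non-trivial), then a nondecreasing schedule of
  cumulative conversion fractions of the permanent cropland to
  forest/shrub/grass. The default schedule concentrates conversion in
  2005–2010, plateaus to 2015 and inches up to 2020, ending at 20 % of
  permanent cropland — the implementation tempo and city-level intensity
  range reported for the program.

One global seed feeds named substreams (panel / raster / land use), so a
module can be regenerated independently and identical configurations are
byte-identical.

What the generator does **not** emulate: spatial autocorrelation of real
satellite LAI, climate-reanalysis structure, non-Gaussian noise, or
measurement error in yearbook statistics. Passing tests therefore
demonstrate correctness of the estimators under their own assumptions, not
fidelity of any particular published coefficient map.

## Numerical and design choices

* Planar km coordinates throughout; lon/lat inputs are converted by an
  equirectangular projection about the domain centroid before distances
  are computed — adequate at basin scale, not at continental scale.
* $p = \alpha$ is *not* significant (strict inequality), and the exact
  boundary is tested.
* Zonal assignment of grid cells is by cell centre; synthetic zones are
  contiguous rectangular blocks (`make_zone_grid()`).
* Grids travel as plain 3-D arrays and serialize to long-format CSV
  (`row, col, year, value`), with a JSON sidecar for land-use class codes.
  This keeps every artefact text-based and diffable; no geospatial raster
  stack is required anywhere in the pipeline.
* Pipeline runs write a JSON manifest (seed, full configuration, package
  version, md5 per output) and contain no timestamps, so identical
  configuration + seed reproduces every output checksum.
* Problem sizes in the shipped checks — 50 × 40 panels, 100 × 100 × 21
  rasters, 1000 random q instances, 200 × 999 permutation replicates —
  were chosen as the smallest sizes at which the statistical properties
  under test are stable.

## Known limitations

* GTWR assumes locally linear driver–response relationships; threshold or
  saturating responses will be smoothed through.
* The q-statistic depends on the discretization (method and $L$); results
  should be reported with both.
* Single-pass VIF screening can drop a variable that would survive after a
  worse one is removed; the iterative mode exists for that comparison.
* The permutation p-value has resolution $1/(B+1)$.
* No spatial-error or spatial-lag structure is modelled in the residuals.
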