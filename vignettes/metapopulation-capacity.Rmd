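---
title: "Metapopulation capacity as a fragmentation metric: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapopulation capacity as a fragmentation metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcap)
```

## The model

Metapopulation capacity summarizes what a landscape of habitat patches
offers a species in the long run. Given patch areas $A_i$ (km²) and
minimum edge-to-edge distances $D_{ij}$ (km), the landscape matrix is

$$m_{ij} = A_i^{x}\, f(D_{ij})\, A_j,$$

and the capacity $\lambda$ is its leading eigenvalue. The ingredients map
onto the two halves of patch-occupancy dynamics: $A_i^x$ stands in for
expected persistence of an occupied patch (extinction risk scaling as
$A^{-x}$), and $f(D_{ij}) A_j$ for the colonization pressure patch $j$
exerts at distance $D_{ij}$. In Levins-type models the landscape supports
a positive occupancy equilibrium exactly when $\lambda$ clears a threshold
set by the ratio of extinction to colonization rate constants, which is why
the eigenvalue — and not any single patch statistic — is the right summary
of spatial configuration. Its units are relative ("Levins patch
equivalents"), so $\lambda$ is meaningful as a comparison across species or
scenarios, not as an absolute persistence probability.

This package's headline variant, $\lambda_{self}$, **retains the matrix
diagonal**: $m_{ii} = A_i^{x+1}$ (since $f(0) = 1$). Biologically this is
self-colonization — a large patch is likely to retain survivors of a local
extinction event and re-seed itself, a within-patch rescue effect that the
classical zero-diagonal capacity ignores. The practical consequence is
large: for a range dominated by one big patch, $\lambda_{self} \approx
A_{max}^{x+1}$ regardless of the constellation of fragments around it,
whereas scattering the same total area across many small fragments drops
$\lambda_{self}$ by orders of magnitude. Both variants are computed side by
side (`metapop_capacity(..., both_variants = TRUE)`), and
$\lambda_{self} \ge \lambda_{classic}$ always, because zeroing a
nonnegative diagonal can only shrink the spectral radius.

Two structural facts the implementation leans on, and the test suite
asserts: the alternative reading $m_{ij} = A_j^x f(D_{ij}) A_i$ is just the
transpose and has the same spectrum, so the exponent placement is
immaterial for $\lambda$; and $M = \mathrm{diag}(A^x)\, F\,
\mathrm{diag}(A)$ with symmetric $F$ is diagonally similar to the symmetric
matrix $\mathrm{diag}(\sqrt{A^{x+1}})\, F\, \mathrm{diag}(\sqrt{A^{x+1}})$,
so the whole spectrum is real and the Perron eigenvector is nonnegative.

## The dispersal kernel

The default $f$ is the survival-rate transformation of the log-sech
dispersal kernel,
$$f(D) = 1 - \tfrac{2}{\pi}\arctan\big((D/\alpha)^{1/\beta}\big),$$
a heavy-tailed law proposed for tropical forest birds. The
parameterization is chosen so both parameters are interpretable:
$\alpha$ (km) is the **median** dispersal distance — $f(\alpha) = 1/2$ for
every $\beta$ — and $\beta$ (dimensionless) controls how heavy the tail is,
with $\beta \to 0$ approaching a step function at $\alpha$. The shipped
defaults ($\alpha = 1$ km, $\beta = 0.5$) are deliberate placeholders for
exploration: dispersal ability is a species trait, and the command-line
interface refuses an assessment run without explicit kernel parameters.
A negative-exponential kernel $f(D) = e^{-D/\alpha}$ (the classical
choice in incidence-function models) is available behind the same
one-argument survival contract for comparison, and any function with
$f(0) = 1$, nonincreasing, can be plugged in directly.

The extinction-area exponent defaults to $x = 1$ (extinction risk
$\propto 1/A$), a standard middle-ground choice; it is exposed everywhere
and the exact scale law $\lambda(cA) = c^{1+x}\lambda(A)$ is tested.

## Landscape conventions

Habitat maps are binary lattices of square cells (default 1 km, so one
cell is 1 km²). Conventions the results depend on, all tested:

* **Connectivity** defaults to 8 (diagonal cells touch) and is exposed as
  a flag; 4-connectivity is stricter and splits diagonal contacts.
* **Patch ids** are assigned in decreasing area order, ties broken by the
  earliest cell in a row-major scan — labeling is fully deterministic.
* **Edge-to-edge distance** is the minimum Euclidean distance between
  *boundary-cell centers* of two patches, in projected km. Cell-edge or
  polygon-boundary conventions would differ by up to one cell size; the
  center convention is simple and bit-for-bit reproducible at the 1-km
  resolution the metrics are meant for. Distances are planar; there is no
  great-circle support, since the intended inputs are regional projected
  grids.
* **No-data cells count as non-habitat**, which is conservative for
  connectivity.
* Patches of one cell are legal; an optional minimum-patch-area filter
  (`filter_patches()`) supports screening rules that demand a minimum
  viable fragment size.

The `patch_set_from_table()` path accepts a precomputed patch inventory
(id, area, representative point); distances are then point-to-point, which
overestimates edge-to-edge separation for large patches — fine for quick
screening, not for final numbers.

## Comparison metrics and their pathologies

`total_range_area()` and `area_risk_flags()` implement the
fragmentation-blind screen: total habitat area compared against the
11,000 km² habitat-range threshold and the 20,000 km²
Extent-of-Occurrence threshold, with a strict `<` (a species exactly at a
threshold is not flagged; both thresholds are configurable).

`cumulative_area_curve()` implements the size-ranked cumulative-area plot:
points $(a_k, \sum_{j \le k} a_j)$ over ascending patch areas, ties merged
at their common area so the curve stays a function, and an OLS fit of
$\log_{10}(\text{cum})$ on $\log_{10}(\text{area})$. The right-most point
is always (largest fragment, total area). A slope needs at least two
distinct areas; otherwise it is reported missing, not zero.

The slope's folklore reading — shallower means more fragmented — comes
with a caveat that the test suite documents precisely. A constellation of
tiny fragments prepended to a range forms a left branch whose own scaling
is close to slope 1, so the fitted slope is pulled *toward* 1: steep
curves (several comparable large patches) get shallower, as the folklore
says, but already-shallow curves (one dominant patch plus scatter — the
common shape in heavily fragmented regions) are pulled *up*. The direction
of the artifact is therefore configuration-dependent, which is one more
reason the curve is kept here as a comparison metric rather than a risk
metric: biologically, tiny unoccupiable fragments should move no needle at
all, and in $\lambda_{self}$ they barely do.

## Cohorts, clustering and omission rates

`assess_cohort()` runs the per-species pipeline over a tibble of species
(grids, rasters, patch tables, or bare areas), isolating failures per
species, and clusters finite $\log_{10}\lambda_{self}$ values into
low/high groups. The split is the exact 1-D two-means partition: every
split point of the sorted values is enumerated and the within-group sum of
squares minimized — deterministic, no iterative k-means seeding — so labels
are invariant to any strictly increasing transform of the capacities. The
ratio of between-group to total sum of squares is reported as a bimodality
diagnostic; near 0 the split is arbitrary and callers should not read the
groups as modes. A fixed user threshold on $\log_{10}\lambda$ is supported
as an alternative, mimicking manual histogram binning. Red List handling:
CR/EN/VU count as threatened, NT/LC as non-threatened, anything else
(DD, NE, unknown) becomes `NA` and is excluded from omission arithmetic.
`omission_rate()` then reports the fraction of a cluster that current
assessments class as non-threatened, and `slopegraph_ranks()` produces the
paired range-vs-capacity rankings (ascending, ties sharing mean ranks)
that make the reordering visible.

## Synthetic landscapes and the patch-occupancy validation

The generator (`generate_landscape()`) emulates the one feature of real
fragmented ranges that drives capacity bimodality: whether habitat is
concentrated in a dominant patch or scattered. Nuclei are dropped
uniformly at random and accrete random adjacent cells;
`big_patch_fraction` forces a share of the habitat budget into one
nucleus, sweeping configurations from a single contiguous patch to a
constellation of single cells. It is deterministic under its seed. It does
*not* emulate real-landscape features such as spatial autocorrelation of
deforestation, linear barriers (roads, rivers), elevation-constrained
ranges, or patch shape complexity — so passing validation here shows the
metric orders *configurations* correctly, not that any particular real
landscape's value is right.

The simulator (`simulate_spom()`) runs discrete-time stochastic
patch-occupancy dynamics, all patches initially occupied. Each step has an
extinction phase — occupied patch $i$ empties with probability
$E_i = \min(1, e/A_i^x)$ — then a colonization phase: every patch empty
after the extinction phase is colonized with probability
$C_i = 1 - \exp(-c \sum_j p_j A_j f(D_{ij}))$, where $p_j$ is
start-of-step occupancy and the $j = i$ term is included iff `rescue` is
on. Computing pressure from start-of-step occupancy means a large patch
that just blinked out can rescue itself within the step — the simulator's
counterpart of the retained diagonal in $\lambda_{self}$. Metapopulation
extinction is absorbing; replicates surviving the horizon are censored at
it.

`validate_capacity()` is the shipped validation experiment: 20 synthetic
40×40 landscapes sweeping `big_patch_fraction` 0–0.95 with accretion
budgets cycling 0/3/12 (largest patches roughly 1–150 km², capacities
spanning about four orders of magnitude), each simulated for 100
replicates × 500 steps, and the Spearman correlation between
$\log_{10}\lambda_{self}$ and median extinction time reported. The
dynamics parameters ($e = 1$, $c = 0.01$, $x = 1$, log-sech $\alpha = 2$
km, $\beta = 0.5$, rescue on) were chosen so extinction times actually
vary across the panel: single-cell patches are near-certain to blink out
each step, while the largest patches persist close to the horizon. A much
larger $c$ makes every sizable patch effectively immortal and every median
equal to the horizon — a degenerate experiment with nothing to correlate.
The correlation is a rank statistic by design: the theory links $\lambda$
to a persistence *threshold*, so ordering, not linearity, is the claim
being checked. The acceptance script recomputes this experiment from
scratch at the stated sizes.

## Numerical choices

* Eigen-solving detects the symmetric-similar structure and uses the dense
  symmetric solver; a power-iteration route (with a diagonal shift
  $\sigma = \max_i \sum_j m_{ij}$ so that zero-diagonal, bipartite-like
  matrices do not oscillate) is kept as an independent cross-check, and
  both must agree to relative $10^{-8}$.
* Empty landscapes: $\lambda = 0$ with an empty eigenvector, by
  convention; a single patch gives exactly $A^{1+x}$ under
  self-colonization. An all-zero matrix returns $\lambda = 0$ with a
  uniform vector.
* The leading eigenvector is clipped at zero (dense solvers can return
  $-10^{-17}$ entries) and normalized to sum 1.
* Curve fits use $\log_{10}$ throughout (the slope is base-invariant);
  $R^2$ is computed from residuals directly so that exact fixtures report
  exactly 1.
* The probability clamp in the simulator ($E_i = \min(1, e/A^x)$) keeps
  tiny patches well-defined at high extinction rates.
* Test and validation problem sizes — 40×40 to 50×50 grids, panels of
  20–100 landscapes, 100–2000 simulator replicates — were chosen as the
  smallest scales at which the checked contrasts (orders-of-magnitude
  capacity gaps, Monte-Carlo means within a few standard errors) are
  unambiguous.

## Known limitations

* Distances are planar km on projected grids; no reprojection, no
  polygon geometry, no great-circle support.
* $\lambda$ values are relative; comparing across different kernels,
  exponents or cell sizes is not meaningful without rescaling.
* The default kernel parameters are placeholders, not fitted values; any
  real assessment must supply species-appropriate dispersal parameters.
* The simulator is a minimal discrete-time model: no environmental
  stochasticity, no correlated extinctions, no habitat dynamics. It is a
  validation instrument for the metric's ordering, not a forecasting tool.
* The cumulative-curve slope has the configuration-dependent artifact
  described above; its interpretation should always be accompanied by the
  endpoints (largest fragment, total area).
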