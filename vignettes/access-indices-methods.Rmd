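---
title: "Methods: distance-distribution inflection indices and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-distribution inflection indices and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaccess)
```

## The model

The package treats geographic access to an in-home service as a property of
the distribution of user-to-nearest-provider distances. For participants
$i = 1..n$ with nearest-provider distances $d_i$, the distances are grouped
into half-open bins $[kw, (k+1)w)$ of width $w$ (default 50 m) and a
polynomial $y = f(x)$ of degree $p$ is fitted by ordinary least squares to
the bin counts $y_k$ against bin midpoints $x_k$. Two catchment indices are
defined by derivative sign changes of $f$:

* $D_1$ (**PWD**, profit-willing distance): the smallest interior root of
  $f'$ at which the slope changes $+\to-$ over $(D_1-\delta, D_1+\delta)$ —
  the curve's first local maximum, the distance band holding the most
  participants.
* $D_2$ (**TLD**, tolerance-limited distance): the smallest root of $f''$
  greater than $D_1$ (greater than 0 when no PWD exists) at which the
  curvature changes $-\to+$ — the flattening of the post-peak decline.

When several roots qualify, the one nearest the origin is always taken. Each
detected root is reported with its containing bin and with a buffer radius
equal to the bin's **upper** edge; buffer-ring multiplicity tables are then
computed at those radii.

The indices are metric-agnostic: distances are Euclidean on projected
planar meters, or haversine great-circle distances (mean Earth radius
6371008.8 m) for longitude/latitude input. Road-network travel distance is
out of scope; the coordinate frame is always declared, never guessed.

Why a polynomial? The index definitions need a twice-differentiable fitted
curve whose derivative roots exist in closed form. A polynomial gives exact
companion-matrix roots and is the minimum structure able to express the
rise–peak–decline–flatten shape the indices describe. Degree is
configurable (2–10, default 4) with an optional AIC-based selection
(`select = "aic"`); degree 4 is the lowest degree with enough curvature
freedom for both indices while resisting tail oscillation.

## Detection guards

Two guards distinguish a genuine peak from a fit artifact; both matter in
the sparse-supply regime, where the count distribution decays monotonically
from the origin:

1. **Boundary dominance.** A least-squares polynomial fitted to a
   monotone-decaying histogram almost always oscillates in the flat tail,
   producing a shallow interior "local maximum". A detected $D_1$ is
   therefore required to satisfy $f(D_1) \ge f(x)$ at both ends of the fit
   domain: a peak lower than the curve's value at the origin is not the
   distance of maximum participant frequency, which is what the PWD means.
2. **No interior empirical mode.** If the bin counts themselves are
   monotone nonincreasing over the fit domain, the empirical maximum sits
   in the first bin and no interior mode exists; the PWD is undetected by
   definition, regardless of what the fitted polynomial does.

With these guards, monotone count patterns never yield a PWD, while
unimodal patterns (analytic or sampled) are unaffected. Undetected indices
are values, not errors, and serialize as `null`.

The TLD sign convention deserves a note: for a unimodal count curve the
second inflection past the peak is a concave-down to concave-up transition,
and that geometry ($f''$ changes $-\to+$) is the package default. The
opposite convention is available as `convention = "concave-down"` for users
who want the mirrored definition.

## Numerical choices

* Fitting uses a scaled Vandermonde basis ($x/x_{hi}$) solved by QR, so
  degree-10 fits over multi-kilometer domains stay well conditioned;
  coefficients are returned on the meter scale. When the counts are exactly
  polynomial of degree $\le p$ at the midpoints the fit interpolates them,
  which is how the analytic recovery tests pin the estimator to symbolic
  derivative roots.
* Derivative roots come from `polyroot` (companion-matrix eigenvalues).
  Roots are kept when their imaginary magnitude is below
  $10^{-8} \times$ the domain span and their real part lies strictly inside
  the open fit domain; roots within $\delta$ of either end are rejected as
  boundary artifacts. Sign changes are assessed at root $\pm\delta$ with
  $\delta = w/100$ (0.5 m at the default bin width).
* The fit domain runs from 0 to the upper edge of the last retained nonzero
  bin; trailing empty bins are always dropped. `tail_quantile` (default 1)
  optionally ends the domain at the first bin reaching that cumulative
  count share. The trim exists because a handful of extreme distances
  otherwise stretch the domain by dozens of empty-ish bins and bias the
  curvature root; 0.99 discards at most 1% of the sample from the fit
  (never from the binning) and makes the domain essentially
  seed-independent.
* Ties in nearest-provider assignment are broken by the lexicographically
  smallest provider id. Buffer multiplicity uses a closed ball
  ($\le R$). Percentages are rounded half-away-from-zero at two decimals,
  the convention of the two-level choice tables; `round()`'s half-even rule
  would differ on exact ties.
* Degenerate inputs: an empty provider set is an explicit error (not a
  silent infinity); an empty choice table flags undefined percentages; a
  fit with fewer data bins than coefficients is an explicit
  underdetermination error; a zero-variance two-sample comparison with
  unequal means is an explicit degenerate-variance error.

## Cohort statistics

Between-region comparisons of demographic tables use the uncorrected
Pearson chi-square on $r \times 2$ count tables (df $=(r-1)$), switching to
Fisher's exact test for $2\times2$ tables with any expected cell below 5
(the conventional trigger), and a two-sample $t$ computed from printed
summary statistics (mean, SD, n per group). Both pooled-variance
(default) and Welch variants are implemented and labelled in the report,
since published tables are not always consistent about which they used.
Eligibility filtering keeps records whose 0–100 self-care score is at or
above a threshold (default 39.93, a population-mean cutoff of the
functional-assessment instrument used in the motivating study design).

## The synthetic generator

No real address data ship with the package; every downstream stage is
validated on generated scenarios with known truth.

* `urban-default` — 15 km × 15 km, 33 providers placed uniformly,
  participants in Gaussian clusters (SD 300 m) around a 10 × 10 grid of
  zone centroids with a 10% uniform background. Emulates a dense city where
  the nearest-distance distribution is unimodal: a PWD exists.
* `rural-default` — 20 km × 20 km, 5 providers, 40% of participants
  co-clustered tightly with the providers (SD 40 m) over a 60% uniform
  background. Emulates sparse supply concentrated in settlement cores:
  counts decay from the origin into a heavy tail, the PWD is undetected,
  and — because most of the population is far from the few providers — the
  median nearest distance exceeds the urban one. The extents are
  order-of-magnitude stand-ins for a compact city versus a large rural
  county, not calibrated maps.
* `planted-gamma` — a single central provider and participants placed at a
  gamma(shape 4, scale 150 m) distance and uniform bearing, so the
  nearest-distance sample *is* a draw from the planted density. The
  analytic truth is closed-form: the density mode $(k-1)\theta = 450$ m is
  what the PWD estimates, and the first curvature change beyond it,
  $\theta\,(k-1+\sqrt{k-1}) \approx 709.8$ m, is what the TLD estimates.
  (For a lognormal plant, mode $e^{\mu-\sigma^2}$ and curvature change
  $e^{\mu + \sigma^2 u}$ with $u = (-3+\sqrt{1+4/\sigma^2})/2$.)

Generation is reproducible bit-for-bit given (config, seed); each placement
component draws from its own named substream derived from the seed, so
adding a draw site never shifts existing components. Planted configurations
whose 0.9999 distance quantile exceeds the extent's inscribed radius are
rejected as infeasible.

For planted-density recovery the recommended analysis is degree 6 with
`tail_quantile = 0.99`. The choice was made against noise-free expected
counts and held fixed: lower degrees carry visible approximation bias in
the curvature root of a gamma-shaped curve, higher degrees buy less bias at
the price of variance, and the untrimmed domain lets the random sample
maximum move the fit domain by many bins between replicates. Validation
sizes used throughout: n = 5000 per replicate and 200 replicates for
planted-bin recovery; 100 seeds per regime for urban/rural detection; these
are the problem sizes at which the binomial noise of a recovery rate is a
few percent.

What the generator does **not** emulate: road networks and travel time,
anisotropic settlement shapes (coastlines, valleys), provider capacity
limits, and the empirical Taipei/Hualien maps themselves — the study's raw
geocoded addresses are not available, so passing synthetic tests shows the
estimator recovers known truth under the generator's assumptions, not that
it reproduces any particular published index value.

## Known limitations

* A single polynomial is a global fit: histograms with several comparable
  modes can place $D_1$ at whichever peak the smallest qualifying root
  hits; the raw argmax bin is emitted alongside the curve-based index so
  users can spot such disagreement.
* Bin-containment of an index is knife-edge when the underlying truth lies
  within the estimator's noise of a bin boundary; report users should read
  the root together with its bin.
* The privacy convention of snapping participants to zone centroids
  coarsens the distance distribution; with very large zones the first bins
  are dominated by the zone geometry rather than by individual locations.
  Snapping is therefore an explicit, optional step, applied only when the
  input data were collected under that convention.
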