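---
title: "Scoring phage efficiency with the Centroid Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phage efficiency with the Centroid Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemetrics)
```

## The problem

When a phage or phage cocktail is incubated with its bacterial host in a
plate reader, the OD trace summarizes the whole interaction: growth, lysis,
and — crucially — any late regrowth of resistant cells. Single-number
efficiency scores that integrate the curve (the area-ratio Virulence Index)
or fit a parametric model (logistic-family regressions) either ignore *when*
the bacterial mass occurred or assume a canonical curve shape that
phage-treated cultures routinely violate. The Centroid Index takes a third
route: treat the curve as the upper boundary of a plane region and summarize
that region by its geometric centroid, which moves right when growth happens
late and up when growth is large, with no model fitting at all.

## The statistic and its computation

For a curve sampled at times $t_0 < \dots < t_n$ (hours) with nonnegative
ODs $y_j$, each time interval contributes a trapezoidal strip of area
$A_j = \tfrac{1}{2}(y_{j-1}+y_j)(t_j - t_{j-1})$ whose centroid has the
closed form

$$\bar x_j = t_{j-1} + \frac{(t_j - t_{j-1})(y_{j-1} + 2 y_j)}{3(y_{j-1}+y_j)},
\qquad
\bar y_j = \frac{1}{3}\Bigl(y_j + \frac{y_{j-1}^2}{y_{j-1}+y_j}\Bigr).$$

The second expression equals the symmetric trapezoid-centroid form
$(y_{j-1}^2 + y_{j-1} y_j + y_j^2)/(3(y_{j-1}+y_j))$; the tests verify this
identity on random strips, and the implementation uses the first form as
written. The curve centroid is the area-weighted mean of strip centroids, and

$$\mathrm{CI}_i = 1 - \frac{\bar x_i \, \bar y_i}
{\bar x_{\mathrm{ctrl}} \, \bar y_{\mathrm{ctrl}}}.$$

Because the curve between samples *is* piecewise linear, the strip
decomposition is exact: the package's independent check
(`centroid_oracle_dense()`) recomputes the area and both first moments by
brute-force midpoint quadrature on a refined grid and agrees with
`curve_centroid()` to better than $10^{-6}$ relative error at refinement
1000, with the quadrature error of the oracle shrinking quadratically in the
refinement — which is how we know the closed forms, not the oracle, are the
exact ones.

Properties the test-suite enforces over seeded random ensembles:

* $\mathrm{CI} \le 1$ always; $\mathrm{CI} = 1$ for a zero-area treated
  curve; $\mathrm{CI} = 0$ for a treated curve identical to the control.
* $\mathrm{CI} < 0$ exactly when
  $\bar x_i \bar y_i > \bar x_{\mathrm{ctrl}} \bar y_{\mathrm{ctrl}}$ —
  treated growth larger or later than the control.
* Scaling both curves' ODs by a common factor leaves CI unchanged; scaling
  only the treated curve down strictly increases CI.
* For two treated curves that are time-reflections of each other (equal
  areas, equal $\bar y$), VI is identical while CI strictly penalizes the
  member whose mass sits later — the discrimination VI cannot make. The
  analogous blind spot of $\mu_{max}$ (identical exponential phases,
  divergent later behaviour) is exercised the same way.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| time unit | `read_plate_table()` | hours | plate readers commonly export minutes; 15-min reads are `step = 0.25` h |
| `rezero_time` | ingestion/CLI | `FALSE` | $\bar x$ depends on the time origin; the input's origin is preserved unless the user explicitly rezeroes |
| clamp floor | `clamp_nonnegative()` | 0 | blank subtraction may produce small negative ODs; clamping (not dropping) keeps grids aligned and areas nonnegative |
| `window` | `mu_max()` | 5 points | a sliding log-linear fit needs enough points to damp noise without smearing the exponential phase; 5 points = 1 h at 15-min sampling |
| `od_floor` | `mu_max()` | 0.01 OD | keeps near-blank readings out of `ln(OD)` |
| `tie_tol` | `rank_treatments()` | 5e-3 | indices are conventionally reported to two decimals; values equal at that precision should share a rank |
| alignment tolerance | `align_time_grids()` | 1e-9 h | grids that differ only by floating-point noise count as identical |

## Replicate policy and control handling

Replicate handling is genuinely open — neither averaging order is canonical —
so both are implemented. The default is *metric-first*: compute CI/VI/μmax
per replicate well, then report mean ± SD per condition, preserving
between-replicate variance. *Curve-first* (average replicate curves, then
score once) is available via `replicate_policy = "curve_first"` and via
`aggregate_replicates()`. When several control wells exist they are always
averaged pointwise into a single control curve first, because the index
definition takes a single control centroid.

VI is computed as the raw area ratio $1 - A_i/A_{\mathrm{ctrl}}$; any
per-time normalization of the areas cancels in the ratio, so the choice is
immaterial.

`mu_max` rankings are ascending (a slower-growing treated culture is the
better outcome), while CI and VI rank descending; `rank_treatments()` encodes
the direction per metric.

## Numerical choices and degenerate inputs

* **Degenerate strips** ($y_{j-1} = y_j = 0$): zero area and an undefined
  centroid. They are excluded from the weighted sums — the unique consistent
  choice, since their weight is zero.
* **Zero-area treated curve**: CI is defined as exactly 1, the limit of the
  index as the treated area shrinks to zero and the intended "complete
  lysis" score. Logged as an edge case.
* **Degenerate control** (zero area, or centroid product ≤ 0, which requires
  a rezeroed grid whose only mass touches $t = 0$): CI is refused with an
  error rather than returning ±∞.
* All sums run in ordinary double precision; at plate scale (≲ 400 points
  per curve) compensated summation is unnecessary, which the oracle
  comparisons confirm.
* Missing OD cells abort ingestion; grid reconciliation is explicit
  (`align_time_grids()`, strict by default, linear interpolation on request)
  and linear interpolation is exact for the piecewise-linear curves the
  metrics operate on.

## What the synthetic generator emulates — and what it does not

The generators exist so that every metric and property is testable without
any measured data. Defaults mirror a long co-incubation assay with a
slow-growing host: 0–96 h sampled every 15 min (385 points), initial OD 0.1.
`logistic_curve()` supplies the canonical uninfected control;
`lysis_regrowth_curve()` produces the non-canonical treated shapes —
logistic growth to a lysis onset, exponential decay, and optional logistic
regrowth of resistant cells toward a fraction of the original carrying
capacity, continuous at the junctions. Regrowth is phenomenological: the
package scores curves, it does not simulate phage–host kinetics, so there
are no phage-population ODEs, no MOI dependence, no evolved resistance
dynamics. Noise is additive Gaussian truncated at zero; real plate readers
also show multiplicative error, drift, and edge-well artifacts, none of
which are modeled. Passing tests therefore demonstrate the *mathematical*
behaviour of the metrics on curves with the right shapes, not robustness to
every instrumental artifact of real plates.

One generator subtlety: the regrowth segment restarts a logistic from the
OD the decay reached, so with a fast decay and a late regrowth onset the
regrowing subpopulation starts vanishingly small and visible regrowth needs
a correspondingly larger `regrow_rate`. The bundled fixture generator picks
`decay = 0.2`/h and regrowth rates of 0.4–0.8/h so that its "late regrowth"
and "early regrowth" conditions actually display the behaviour their names
promise.

## Validation scale

The shipped validation runs use: 200 random piecewise-linear curves against
the refinement-1000 oracle, 100 area-matched reflection pairs, 100
μmax-twin pairs, and 1000 random treated/control pairs for the bound, sign,
scaling and monotonicity properties — all on the default 385-point grid with
fixed seeds, completing in well under a minute on one core.

## Known limitations

* CI's time coordinate depends on the time origin; comparing CI values
  across experiments requires a consistent origin convention (the package
  never rezeroes silently).
* CI compresses a whole curve into one number; two different curves can in
  principle share a centroid product. It complements, rather than replaces,
  looking at the curves — which is why the CLI can plot them with their
  centroids.
* No smoothing is applied before centroid computation, by design: smoothing
  would silently move $\bar x$ and $\bar y$. Noisy data are scored as
  measured.
* Proprietary plate-reader binaries are out of scope; export to delimited
  text first.
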