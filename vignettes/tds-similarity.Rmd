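---
title: "Comparing individual TDS trials: the similarity index, the choice of R, and outlier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing individual TDS trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsim)
```

## The data model

A temporal dominance of sensations (TDS) trial records which of `q`
attribute buttons a panelist holds selected at each moment between the
start and stop of a tasting task. `tdsim` represents a trial as a
right-continuous step function on normalized time: raw second-valued
timestamps are mapped affinely onto `[0, 1]` and each button press opens
a half-open dominance segment `[onset, next onset)` that closes at the
next press (or at 1). The instants before the first press carry an
implicit `"none"` state, indexed 0. Two structural assumptions follow
from how TDS hardware works and are enforced at construction:

* exactly one attribute (possibly `"none"`) is dominant at every
  instant — simultaneous selections are not representable (that would be
  a temporal check-all-that-apply design, out of scope here);
* re-pressing the already-selected button changes nothing and is
  collapsed.

Trials with no selections at all are accepted with a warning rather than
rejected: they are legitimate degenerate data and precisely the kind of
trial an outlier screen should get to see. Whether the first press can
coincide with the start instant is left open — both are representable
(`"none"` then simply has zero duration).

The half-open, right-continuous segment convention (with `t = 1` mapped
to the final segment) is a measure-zero choice that cannot affect any
integral quantity, but fixing it makes pointwise evaluation
deterministic and therefore testable.

## Discretization and the similarity index

Analysis begins by splitting `[0, 1]` into `R` equal intervals — `R` is
the *dynamic level* — and averaging each dominance function over each
interval:

$$X_i[k] = R \int_{k/R}^{(k+1)/R} x_i(t)\, dt, \qquad k = 0, \dots, R-1.$$

Because `x_i` is piecewise constant, the integral is computed exactly as
interval-overlap arithmetic; numerical quadrature appears only as an
independent oracle in the test suite (midpoint rule on a `1e-5` grid,
compared on the integral scale where the quadrature error is bounded by
the grid step times the number of switches, comfortably below the
`1e-4` tolerance used). Each interval's values sum to 1 by construction,
and the row means over `k` recover the whole-trial dominance durations —
both conservation laws are asserted to `1e-12` in the tests.

The similarity between two discretized trials is

$$S_R(X^{(a)}, X^{(b)}) = 1 - \frac{1}{\sqrt{2}\,R} \sum_{k=0}^{R-1}
  \left\| X^{(a)}[\cdot, k] - X^{(b)}[\cdot, k] \right\|_2,$$

one minus the average per-interval Euclidean distance. Two design points
deserve emphasis:

* **Normalization.** The largest possible per-interval distance is
  `sqrt(2)`, between intervals fully dominated by different single
  attributes, so the `1/(sqrt(2) R)` factor makes the dissimilarity
  term's maximum exactly 1. The bracketed norm could conceivably be read
  without the square root over the inner sum; only the per-interval
  Euclidean-norm reading is consistent with an "average Euclidean
  distance" whose maximum is 1 under this normalization, and that is
  what is implemented.
* **The `"none"` state participates.** The sum runs over `i = 0..q`, so
  a panelist who starts selecting late genuinely differs from one who
  starts immediately. Users comparing panels with very different
  reaction times should be aware of this.

A Manhattan variant (normalized by `2R`, same maximum) is available
behind a flag for sensitivity analyses; Euclidean is the default and the
only metric used in the package's own quantitative checks. Comparisons
between discretizations at different `R` are rejected rather than
resampled — the index is only defined on a common `R`.

`R = 1` compares pure dominance-duration profiles; a trial and its
time-reversal are identical at `R = 1` and maximally separated per
interval at large `R`. This is the lever the whole package turns on.

## Dominance proportions and smoothing

The panel-mean dominance curve is computed exactly as a piecewise
constant function on the union of all trials' onsets (values are
multiples of `1/n`), and its discretization equals the element-wise mean
of the per-trial matrices — an identity the tests check exactly, since
both sides are closed-form rational arithmetic. Smoothing
(`smooth_curve()`) is a centered moving average on a uniform resampling,
with the window shrunk at the boundaries so every attribute is averaged
over the same cells and each output segment still sums to 1. The window
is a presentation choice only: every similarity and screening
computation uses the unsmoothed functions, so no kernel parameter can
leak into the statistics.

## Similarity to the centroid and the choice of R

`similarity_set()` scores each trial against the discretized panel-mean
curve, giving the set `C_R`. The scored trial is included in the
centroid by default; with `n = 51` trials its own contribution is under
2% and excluding it would change the estimand, not just the estimate. A
`leave_one_out` flag exists for users who want the held-out variant.

`correlation_grid()` computes Pearson correlations between `C_{R1}` and
`C_{R2}` over a grid of levels, matching entries by trial id. Matched
sample moments are used in numerator and denominator (plain
`stats::cor`), which keeps the coefficient in `[-1, 1]`; whether the
moments are "population" or "sample" flavored cancels in the ratio.
Zero-variance sets raise an error rather than yielding `NaN` — a silent
`NaN` would poison an entire grid.

Two heuristics translate the grid into a working `R`:

* `recommend_R()` formalizes the idea that a good level "agrees with
  everyone": it maximizes the minimum (default) or the mean off-diagonal
  correlation of its row, breaking ties toward smaller `R` for
  parsimony. On simulated strawberry-like panels this lands strictly
  between the duration-only and timing-heavy extremes of the grid.
* `R_from_min_switch_interval()` grounds `R` in behavior: panelists
  rarely switch attributes faster than about a second, so intervals
  finer than the shortest observed inter-press gap carry no signal. The
  gap statistic is a low quantile (default the 5th percentile) of all
  inter-selection gaps rather than the literal minimum, which one
  accidental double-press would otherwise control; `R` is the mean task
  duration divided by that gap, floored.

## The outlier screen

For each requested `R`, `outlier_analysis()`:

1. builds `C_R`;
2. tests it against a normal distribution with estimated mean and
   standard deviation (one-sample Kolmogorov–Smirnov);
3. if normality is not rejected (`p > 0.05`), flags trials strictly
   below `mu - 1.64 sigma` (95% coverage) or `mu - 2.33 sigma` (99%);
   otherwise falls back to a one-sided IQR rule flagging values below
   `Q1 - 1.5 IQR`.

Choices worth recording:

* The screen is **one-sided by design**: a trial with unusually *high*
  similarity resembles the panel mean unusually well, which is not a
  defect. The IQR fallback is made one-sided too, for consistency.
* The constants 1.64 and 2.33 are used verbatim (not 1.645/2.326);
  `sigma` is the `n - 1` sample standard deviation over all entries of
  `C_R`, outliers included. Both choices follow the screening procedure
  this package operationalizes; users wanting contamination-resistant
  location/scale can set `robust = TRUE`.
* A value exactly at the threshold is an inlier (the acceptance region
  is the closed ray `[mu - k sigma, Inf)`).
* The KS gate defaults to plugging the estimated parameters into the
  standard test, the most literal reading of the procedure. Estimating
  parameters from the sample makes that test conservative (too-large
  p-values), so a Lilliefors-corrected mode (`ks_mode = "lilliefors"`,
  via `nortest`) is provided and is statistically preferable; the
  default stays with the literal procedure and the choice is surfaced
  rather than resolved.
* Quartiles use R's default linear-interpolation convention (type 7).
* The robust option is a univariate analog of the minimum covariance
  determinant, appropriate because `C_R` is one-dimensional: the
  `ceiling((n+1)/2)`-point contiguous window of order statistics with
  the smallest variance supplies location and scale, the latter rescaled
  by the factor (`~2.65`) that makes it consistent for normal data.
  Full multivariate MCD is deliberately out of scope.
* No multiple-testing correction is applied across `R` values; the
  per-R flag matrix is a descriptive instrument, and which levels flag a
  trial is itself the diagnostic (duration-level versus timing-level
  deviation).

Under the null, the 95% screen flags about 5% of entries — verified
empirically in the acceptance suite over 10,000 simulated draws — and
99% flags are always a subset of 95% flags.

## The synthetic panel generator

No public machine-readable TDS trial archive accompanies the strawberry
panel this methodology is motivated by, so the package ships a
first-class simulator rather than a frozen fixture. Trials are drawn
from a semi-Markov chain: states are attributes, sojourn times have
explicit per-attribute distributions (gamma by default, lognormal as an
option — button-press gaps are right-skewed), and transitions carry a
zero diagonal. Temporal structure comes from a *phase schedule*: separate
transition matrices for the early, middle and late thirds of elapsed
task time. A time-homogeneous chain cannot make an attribute peak
mid-task, which is exactly the signature real TDS curves show; the phase
schedule is the smallest mechanism that can.

The `strawberry_spec()` preset encodes a strawberry-like panel with
eight attributes (sweet, sour, fruity, green, watery, juicy, aromatic,
light) whose realized curves show sweet/juicy/fruity/watery dominating
early, aromatic peaking in the middle, and sour rising mid-task and
staying dominant to the end with light as a late aftertaste. Its
defaults, chosen once as field-realistic and then left alone:

| parameter | default | rationale |
|---|---|---|
| panels × replicates | 17 × 3 = 51 trials | typical panel-study size |
| task duration | gamma, mean 30 s, sd 5 s | a strawberry eat is about half a minute |
| sojourns | gamma, mean 3 s, sd 1.5 s | ~10 selections per trial; switch gaps ≳ 1 s |
| `"none"` lead-in | gamma, mean 1 s, sd 0.5 s | reaction time to the first press |
| phase weights | see `strawberry_spec()` | early sweet/juicy/fruity/watery, mid sour/aromatic, late sour/light |

The final sojourn is truncated at the stop time (rather than the trial
being rejected and redrawn), which keeps the duration marginal exactly
the drawn one. Seeds are mandatory everywhere; child seeds for panel
members are derived deterministically from the master seed and no global
RNG state leaks. Per-panelist random effects on sojourn means exist as
an option but are off by default — the real panel's between-panelist
heterogeneity is unknown, and inventing a magnitude would imply
knowledge the data do not support.

What the simulator does *not* emulate: attribute-selection habits that
differ systematically by panelist, sample-to-sample (fruit-to-fruit)
variation, learning across replicates, or any dependence between trials.
Passing tests on simulated panels therefore demonstrate that the
pipeline recovers structure *of the kind the generator produces*; they
cannot certify behavior on real panels with richer heterogeneity.

### Planted outlier archetypes

`inject_outlier()` replaces one trial with a behavioral archetype,
leaving every other trial bit-identical:

* **single_attribute** — one button held for the whole task. Its
  dominance-duration profile is degenerate, so it stands out already at
  `R = 1`.
* **rare_attributes** — a trial wandering among the attributes the
  spec's transition weights visit least, at every phase.
* **time_shifted** — the trial's own selection sequence reversed in time
  (the `"none"` lead stays in place), preserving every whole-trial
  duration exactly while maximally disturbing timing: invisible at
  `R = 1`, conspicuous at large `R`.

One subtlety: reversing a trial that happens to be nearly
time-symmetric (a single long dwell, say) plants no timing shift at
all. Quantitative recovery experiments therefore plant the reversal on
the trial whose discretized matrix moves farthest under column
reversal — the trial for which the archetype actually produces the
deviation it is named for. With that construction, the acceptance suite
measures recovery power over 100 independently seeded 51-trial panels:
the single-attribute plant is flagged at `R = 1` and the reversed plant
at `R = 100` (but not at `R = 1`), each in at least 80% of panels.

## Numerical choices and degenerate inputs

* Conservation identities (column sums, duration sums, curve/discretize
  commutation) hold to `1e-12`; they are exact rational arithmetic up to
  floating-point rounding.
* Ties in `recommend_R()` break toward smaller `R`; order statistics use
  `type = 7` quantiles; flag comparisons are strict (`<` the threshold).
* Degenerate inputs fail loudly and specifically: zero-variance
  similarity sets raise errors from correlation and the KS gate; an
  all-identical panel yields an empty flag set with a warning rather
  than an error, since "no outliers" is the correct answer there.
* Problem sizes in the shipped test suite — 1,000 random trials for the
  quadrature cross-check, 100 seeded panels for the power experiments,
  10,000 draws for the null flag rate — were chosen to make Monte-Carlo
  error small relative to the margins being asserted while keeping the
  default test run comfortably fast.

## Known limitations

* All attributes are weighted equally in the index; weighting or
  restricting to essential attributes may be more practical for some
  studies and is not implemented.
* Probability-based distances and hierarchical clustering on the
  similarity matrix are natural extensions left out of scope.
* The screen detects that a trial deviates, not *why*; interpreting a
  flag still requires looking at the trial (e.g. via `autoplot()` on its
  curve) before deciding on removal, and the package deliberately never
  auto-removes trials.
* Proprietary sensory-software export dialects (TimeSens, Fizz) are not
  parsed; the documented CSV/JSON formats are the interchange surface.
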