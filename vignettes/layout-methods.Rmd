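---
title: "Methods: geometry, ordering and missingness in pcptiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, ordering and missingness in pcptiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcptiles)
```

## What the package computes

`pcptiles` treats exploratory graphics as *geometry problems*. Both
engines consume a `typed_table` — a validated container holding one
vector per column, a per-column role (numeric, categorical, boolean,
identifier, tooltip), a level ordering for categorical columns, and an
explicit `n × k` missingness mask — and emit a layout object whose every
coordinate is testable before any rendering happens. The SVG and HTML
renderers are thin, deterministic serialisers of that geometry.

## Typing rules and their rationale

Type inference operates on raw strings. Cells matching the NA tokens
(default `""`, `"NA"`, `"na"`, `"NaN"`; configurable because CSV dialects
disagree) are masked first. The remaining values decide the role:

* boolean, if every value is a `TRUE`/`FALSE` synonym;
* numeric, if every value parses as a finite number — *unless* all values
  are integers with at most `max_levels` (default 5) distinct values,
  which we read as a categorical code (ward numbers, survival classes,
  Likert items). Measurements with genuine decimal variation always stay
  numeric;
* categorical otherwise, including all-missing columns, which keep zero
  levels and render as fully-glyphed tracks — degenerate input must still
  visualise its missingness.

The `max_levels = 5` threshold is this package's own choice, not a
reproduction of any reference implementation; user overrides always win,
and identifier/tooltip roles are never inferred (automatic column
dropping would be surprising). Categorical level order is first
appearance, so round-tripping a table through CSV with the same overrides
reproduces roles, levels and the mask exactly — a tested invariant.

## Axis normalisation

Three maps onto a shared `[0,1]` vertical scale:

| method   | definition | default? | when to prefer |
|----------|------------|----------|----------------|
| `minmax` | linear, min to 0, max to 1 | yes | the standard PCP reading; preserves distribution shape |
| `rank`   | average ranks, equally spaced | | heavy tails/outliers; invariant under strictly increasing transforms |
| `zscore` | standardise, clip at ±3 sd, rescale | | approximately Gaussian axes with rare extremes |

Constant columns map every observed value to 0.5 under *all* methods
(there is no information to spread, and 0.5 keeps the polyline visible);
missing stays missing. `minmax` is the default because it matches common
parallel-coordinates practice; nothing in the engines depends on the
choice, since crossing counts are invariant under any strictly monotone
per-axis map.

## Crossing counting and axis ordering

The crossing count between two axes is the inversion count of one axis's
height sequence after sorting by the other:
`|{(i,j): i<j, (a_i−a_j)(b_i−b_j) < 0}|`. Ties contribute nothing (the
polylines touch, they do not cross), and pairs with a missing value on
either axis are excluded. The implementation sorts by `(a, b)` and
merge-counts strict inversions in `b` — `O(n log n)` — but the test suite
holds it to the quadratic pairwise definition on hundreds of seeded
instances, ties and missing values included.

Crossing counts are computed on *pairwise-complete* rows per axis pair,
not listwise across all plotted axes, so an unrelated column's
missingness cannot perturb the ordering.

Axis ordering minimises the sum of crossing counts over adjacent pairs —
an open-path problem over the symmetric crossing matrix. Design choices:

* **k ≤ 8: exact.** All `k!` orderings are enumerated (40 320 at k = 8,
  well under a second). Exactness where it is cheap gives the tests a
  hard optimality oracle.
* **k > 8: greedy + 2-opt.** Nearest-neighbour paths from every start,
  keep the best, then 2-opt segment reversals to a local optimum. The
  identity (input) order competes as a candidate, so the result is never
  worse than not reordering — the guarantee the tests assert in the
  heuristic regime.
* **Ties.** Among equal-cost orderings the lexicographically smallest by
  original axis position wins, and since a path and its reversal always
  tie, the one whose first axis has the smaller original position is
  returned. No randomness anywhere in the engine.

## Mutual-information ranking

When a categorical feature of interest exists, axes can instead be ranked
by dependence on it. The estimator is deliberately plain: equal-frequency
binning of the feature (type-7 quantile edges, duplicates merged, so the
effective bin count can drop on discrete data), then plug-in MI on the
bin-by-label contingency table, in bits. Default
`n_bins = min(10, ceiling(sqrt(n)))` balances resolution against the
plug-in estimator's positive bias; the acceptance suite checks that bias
empirically (median below 0.05 bits for independent draws at n = 1000,
4 bins) and checks the closed forms exactly: 0 for a constant feature,
1 bit for balanced, perfectly separated classes under a 2-bin split.
Degenerate inputs (under 2 usable rows, or a single label level) return
0 with a warning rather than erroring — a ranking that cannot be
computed should not kill a plot.

## Missing data: two deliberate policies

In the PCP, rows missing on any plotted axis are **dropped and
reported** (`dropped_rows`, plus a per-axis count log under
`drop_and_report`). No NA sentinel tick is drawn: an invented coordinate
would fabricate geometry.

The tiled layout is the missingness instrument. Every cell missing in the
mask gets a `!` glyph over a neutral background tile (neutral so the
glyph reads on any palette); glyphs and missing cells coincide one-to-one
by construction, an invariant the tests check exhaustively on random
fixtures. Bars are minmax-scaled per track with the baseline at the track
minimum (a uniform `[0,1]` cell contract; zero-anchoring is a renderer
concern, not a geometry one). Default sample order is input order —
least surprise — and the multivariate missingness patterns emerge when
the user sorts by the conditioning variables.

At `n ≥ 1000` rows the layout records a warning (surfaced on stderr by
the CLI) but proceeds: the size limit is guidance about readability, not
a correctness bound.

## The synthetic world

The generators *are* the package's stated test world:

* `gen_lazy_birdwatcher(n = 120, seed, p_skip = 1)` — two observers
  (Morgan, Poisson rate 9; Robin, rate 4) assigned uniformly to outings
  on weekdays/weekends (uniform 50/50). With probability `p_skip` the
  magpie count is missing exactly where Robin meets a weekend — a
  missing-at-random mechanism depending jointly on two observed
  categorical variables, and on nothing else. Counts are drawn *before*
  masking, so missingness is conditionally independent of the magnitude
  given (observer, day) — tested by comparing same-seed draws at
  `p_skip = 0` and `1`. Defaults (n = 120, p_skip = 1) are fixture
  choices: small enough to read as a tiled plot, deterministic enough
  that the glyph block is unmistakable.
* `gen_class_mixture` — balanced classes; informative features shift
  class means by `separation` standard deviations over unit noise; noise
  features ignore the class; column order shuffles per seed so ordering
  tests cannot key on position. At `separation = 3` and n = 500 the MI
  ranking must put the informative features on top in ≥ 95% of seeds.
* `gen_correlated_numeric` — multivariate normal via the symmetric
  eigendecomposition square root, so singular correlation matrices
  (ρ = ±1, used by the crossing-count edge cases) are accepted.

What the generators do **not** emulate: real measurement error structure,
mixed missingness mechanisms, class imbalance, heavy-tailed features, or
anything about actual bird behaviour. A green test therefore establishes
that the engines honour their geometric and statistical contracts on the
stated mechanisms — not that any particular real dataset will look like
the fixtures.

## Numerical and degenerate-input choices

* Crossing totals are accumulated as doubles (exact up to 2^53, far
  beyond any C(n,2) here).
* SVG coordinates print at two decimals via `sprintf`, making renders
  byte-deterministic; identical layout + options ⇒ byte-identical files,
  which the CLI determinism tests assert.
* Stable radix sorting everywhere in sample ordering; missing values sort
  last under both directions. Rows tied on *every* sort key keep input
  order — consequently the "re-sort a permuted table" canonicalisation
  property holds exactly when the keys totally order the rows, and the
  property test uses a spanning key set.
* An all-rows-dropped PCP still renders valid axes with zero polylines
  (plus a logged warning); an identifier-only table refuses to build a
  tiled layout, because nothing is plottable.

## Known limitations

* The heuristic ordering regime (k > 8) is a local optimum; no
  approximation ratio is claimed beyond "never worse than the input".
* Plug-in MI is biased upward at small n; rankings are still usable
  (bias is shared across axes) but reported bit values should not be
  read as precise dependence measures.
* Interactivity is tooltips and hover emphasis only — no brushing, axis
  dragging or linked selection.
* No streaming reader: tables are materialised in memory.
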