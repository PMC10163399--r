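---
title: "Methods: similarity-based TCM formula visualization"
author: "tcmviz authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based TCM formula visualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmviz)
```

## The problem

A category of traditional Chinese medicine (TCM) formulas — say the tonic
formulas — is a collection of named herb sets. Each formula flags one or
more herbs as *principal* (Junyao), the herbs playing the major role against
the targeted syndrome. Each herb additionally carries a 23-dimensional
binary attribute vector: 5 Siqi property flags (cold, hot, warm, cool,
calm), 7 Wuwei flavor flags (pungent, sweet, sour, bitter, salty, tasteless,
astringent) and 11 Guijing meridian flags (liver through pericardium). Herb
identity is the exact Pinyin string; the package never merges prepared and
raw forms of a herb (`Zhigancao` and `Gancao` stay distinct), because any
merging rule would amount to invented pharmacology. Textbook data do treat
Bazhentang as the union of Sijunzitang and Siwutang, which is only true if
the two licorice forms are identified — the package documents, and keeps,
the distinction.

`tcmviz` turns such a group into three coordinated static views: an icicle
plot of the formulas whose column order and row placement reflect herb
similarity, a formula-by-formula shared-herb matrix, and a scatter of herbs
over a continuous 2D colormap derived from their attributes.

## Herb embedding and distances

Herbs are encoded as binary vectors `P` in `{0,1}^23` in a fixed schema
order (Siqi, then Wuwei, then Guijing; `attributeSchema()`). All similarity
computations operate on a 2D projection `p` of `P`, not on `P` itself:
distances between raw binary vectors concentrate on a few integer values
and discriminate herbs poorly, while distances in the projection spread out
and produce layouts that are easier to compare.

Two projectors are available in `embedHerbs()`:

* **`"pca"` (default).** The first two principal axes of the centered
  binary matrix, with a fixed sign convention (the largest-magnitude
  loading on each axis is made positive). This projector is deterministic
  across platforms and library versions, which is what every layout and
  color oracle test in the package is built on, and what the acceptance
  script uses.
* **`"umap"`.** A nonlinear UMAP embedding, delegated to the Python
  `umap-learn` package through a `python` subprocess with
  `random_state = seed` and a single thread. Defaults `n_neighbors = 5`,
  `min_dist = 0.3` were chosen once for groups of roughly 30–75 herbs
  (small neighborhoods preserve the fine cluster structure binary
  attributes produce). Deterministic for a fixed environment and seed, but
  not across library versions — hence not the test oracle.

The distance between herbs *u* and *v* is the Euclidean norm
`d(u, v) = ||p_u − p_v||`. Each formula group is embedded separately: maps
and colors are per-category tools, and sharing one embedding across
categories would couple unrelated groups.

## The similarity layout

The layout is a greedy two-step arrangement driven by a *similarity
sequence*: starting from a chosen (or seeded-random) herb, repeatedly
append the nearest unplaced herb (`orderBySimilarity()`). Ties are broken
by input order, which makes the algorithm fully reproducible; the test
suite verifies the chain against an exhaustive-enumeration oracle on all
point sets up to size 7.

**Step 1 — principal herbs** (`assignTopLevel()`, `layoutPrincipal()`).
Herbs that are the sole principal of some formula become top-level herbs
and are ordered by the similarity sequence from a seeded random start.
Each formula then resolves its own top-level herb: a sole principal is its
own top; a multi-principal formula reuses the first of its principals
already on the list (list order breaks the tie between several listed
candidates); if none is listed, one of its principals is drawn under the
seed and appended. Columns are grouped contiguously by top-level herb,
ordered within a group by ascending principal count, and each column's
remaining principals are sorted by distance to the top herb. The principal
region is padded to the *global* maximum principal count of the group, so
the top of the nonprincipal region is one common row across the entire
plot — with per-subgroup padding, columns in different subgroups would
start their nonprincipal herbs at different heights and cross-group
comparison would break. Formulas with no principal herb are legal (they
trigger a validation warning, not an error) and group last; their columns
hold only nonprincipal cells.

**Step 2 — remaining herbs** (`layoutRemaining()`). The leftmost column's
nonprincipal herbs follow the similarity sequence started at the herb
nearest the column's top-level principal. Every subsequent column first
aligns: any herb that also occurs as a nonprincipal herb of the column
immediately to the left is placed at *the same row index* as there. The
rest fill the free rows top-to-bottom, sorted by ascending minimum
distance to the left column's herb set ("minimum over the set" is the
simplest reading of closeness to a column; mean-based variants were
considered and rejected as harder to reason about). Exact-row copying can
leave blank rows inside a column — when every nonprincipal herb of a
column is aligned to rows deep in its left neighbor, the column starts
below the common boundary; that is the price of strict vertical alignment
and is intended. `compact = TRUE` instead keeps only the relative order
and closes all gaps.

`alignmentCount()` counts (adjacent column, herb) pairs sharing a row; the
suite checks it never falls below the count for the input-order baseline
layout on the bundled example and on seeded synthetic groups.

## Shared-herb matrix and statistics

`sharedHerbMatrix()` computes all pairwise intersection cardinalities via
the herb–formula incidence matrix. The diagonal stores each formula's herb
count (its self-intersection); it is excluded from pair statistics and
from the heat map's color normalization, so the darkest off-diagonal cell
is always the most-overlapping *pair*. `groupStats()` reports group-level
counts plus the mean and standard deviation of shared-herb counts over the
`n(n−1)/2` unordered pairs; the SD is the sample SD (n−1 denominator).
Both conventions (unordered pairs, sample SD) are documented rather than
fitted — no reference data exist at desk scale to distinguish them.

## Color encoding

Anchor colors of expert-chosen representative herbs are propagated to all
herbs by interpolation in a perceptually uniform space:

1. **sRGB → CIEXYZ → CIECAM02 → CAM02-UCS.** The appearance model runs
   under fixed, documented viewing conditions: D65 adopted white (the
   exact white of the sRGB primaries), adapting luminance
   `La = 64/(5π) ≈ 4.07` cd/m², background `Yb = 20`, average surround.
   The forward model is verified in the tests against the published CIE
   worked example; the inverse is analytic, so in-gamut round trips are
   exact to floating point (the suite checks ΔE < 0.5 over a 1,000-color
   lattice; observed ≈ 1e-13).
2. **Per-channel RBF interpolation.** One interpolant per UCS channel
   (J', a', b') over the anchors' embedding coordinates, *pure* RBF with
   no polynomial tail. With the default linear kernel `φ(r) = r` this
   keeps the two-anchor closed form (the field at the midpoint is the
   channel-wise average) and reproduces each anchor's color exactly at its
   point. Gaussian, cubic and thin-plate kernels are available; anchor
   exactness holds for all of them. Coincident anchors with conflicting
   colors are a singular system and raise an error naming the herbs.
3. **Back to sRGB.** Out-of-gamut results are clamped per channel — a
   simple, reproducible policy chosen over chroma-preserving gamut
   mapping. The clamped fraction of raster cells is reported by
   `rasterizeField()`. A pure linear RBF grows linearly beyond the anchor
   hull, so clamping concentrates in extrapolated corners of the map;
   with the shipped palette the fraction stays below 20% on the bundled
   example, and on synthetic embeddings that bound holds on average (a
   single unlucky embedding can exceed it — no palette can prevent
   linear extrapolation from leaving the gamut somewhere).

The shipped five-element palette (muted green, red, yellow, light gray,
dark gray) is the package's own choice — made once, to keep UCS lightness
range and chroma moderate — and is explicitly user-overridable.
`checkPalette()` warns when a palette exceeds a lightness range of 45 J'
units or a chroma of 30 M' units; the defaults admit the shipped palette
(J' range ≈ 37, max chroma ≈ 20) and reject fully saturated primaries.

## Synthetic data generator

`simulateGroup()` exists so every pipeline stage is testable without
external data. Its defaults mirror the scale reported for a tonic-formula
category: 20 formulas over a 58-herb pool, sizes 2–15 with median 7.5,
and mostly one principal herb per formula. Design choices:

* **Sizes** follow a discretized log-normal with median at `sizeMedian`
  and spread set so ≈99% of the mass lies in `[sizeMin, sizeMax]`;
  out-of-range draws are resampled. A log-normal is the simplest
  right-skewed choice matching a (min, median, max) triple.
* **Herb reuse** is preferential: a herb's sampling weight is
  `1 + overlapWeight × timesUsed`, producing the nonzero pairwise
  overlaps real formula categories show. With `overlapWeight = 0` the
  generator reduces to uniform sampling, and the expected pairwise
  overlap has the hypergeometric closed form `|A||B|/pool` that the test
  suite checks by Monte Carlo.
* **Attributes** are independent Bernoulli flags per block with at least
  one flag forced per block, since every real herb has at least one
  property, flavor and meridian.
* **Anchors** are the herbs nearest (Hamming) to five-element attribute
  archetypes built from the classical correspondences (wood:
  cool/sour/liver; fire: hot/bitter/heart; earth: calm/sweet/spleen;
  metal: pungent/lung; water: cold/salty/kidney), with near-ties (within
  two flag flips) resolved toward herbs far from already-picked anchors
  in the 2D map — experts pick representatives by looking at the map, so
  anchors should both express their element and span the embedding.

What the generator does **not** emulate: real attribute marginals and
their correlations, herb
co-occurrence driven by pharmacology rather than reuse frequency, and
naming structure. Passing tests on synthetic groups therefore demonstrate
algorithmic correctness (invariants, oracles, determinism) — not that the
views are *informative* for any particular real category; the bundled
seven-formula example covers a small real excerpt for that purpose, with
hand-built synthetic attribute flags standing in for database values.

## Rendering

All views are emitted as standalone SVG strings with fixed float
formatting and stable element order, so output is byte-identical across
runs — the end-to-end determinism test relies on this. Principal herbs are
drawn bold in blue with a soft white halo (an `feDropShadow` stands in for
the loosely specified "glow"); formula names are italic at a fixed offset
below their column, making column height a reading cue. The report's
static highlight mechanism replaces the original tool's brushing:
selected formulas get blue solid outlines, and formulas containing the
selected herbs get red dashed outlines. Herb selection uses *all*-herbs
containment by default (a lasso selection of four herbs should light up
exactly the formulas built from all four); `highlightMode = "any"` gives
union semantics.

## Problem sizes and budgets

The test suite runs the full property set — 100 random groups for the
matrix oracle and the layout invariants, 40 for the alignment comparison,
lattice round trips at 1,000 colors — in well under a minute of compute,
with synthetic groups of 4–8 formulas over pools of 14–22 herbs; the
paper-scale end-to-end check (26 formulas, 73-herb pool) renders a
complete report in a few seconds. These sizes were chosen as the smallest
that still exercise every code path several times over.

## Known limitations

* Intersections of three or more formulas are not computed or shown; the
  matrix view is strictly pairwise.
* The greedy similarity chain is not an optimal seriation; no TSP-style
  refinement is attempted.
* The icicle plot's exact-row alignment can introduce internal blank rows
  (see above); compact mode trades alignment for density.
* Gamut clamping is per-channel and can shift hue slightly for strongly
  extrapolated map regions.
* The CLI and report are static; there is no interactivity.
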