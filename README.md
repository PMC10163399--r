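# tcmviz

Similarity-based visualization of traditional Chinese medicine (TCM)
formulas for formula-composition teaching and analysis. A TCM formula is a
named set of herbs, one or more of which are flagged as *principal* herbs
(Junyao); each herb carries a 23-dimensional binary attribute vector — 5
Siqi property flags, 7 Wuwei flavor flags and 11 Guijing meridian flags.
`tcmviz` is for anyone who wants to compare the formulas of a category
(tonic, heat-clearing, ...) side by side instead of reading them as text:
students memorizing compositions, teachers preparing material, and
informaticians analyzing formula collections.

## Method

For a formula group with herb set *H*:

* each herb *u* is encoded as **P**_u ∈ {0,1}²³ and projected to the plane,
  **p**_u ∈ ℝ² (deterministic PCA projector by default; seeded UMAP via
  Python `umap-learn` optionally), with distances
  *d(u,v)* = ‖**p**_u − **p**_v‖;
* a *similarity sequence* S = (s₁, …, sₙ) orders any herb set greedily:
  s₁ is a chosen (or seeded-random) start and s_{i+1} minimizes
  *d(s_i, ·)* over the unplaced herbs;
* the **icicle plot** arranges formulas as columns in two passes — principal
  herbs first (sole principals become sorted top-level herbs, formulas group
  contiguously under them, the principal region is padded globally so all
  nonprincipal herbs start at one row), then the remaining herbs (leftmost
  column by similarity sequence; every other column aligns herbs shared with
  its left neighbor to identical rows and distance-sorts the rest);
* the **shared-herb matrix** holds |F_i ∩ F_j| for all formula pairs, with
  group statistics (mean/SD over unordered pairs);
* **herb colors** interpolate expert-chosen anchor colors with a linear RBF
  per channel of CIECAM02-UCS (through CIEXYZ, D65, average surround),
  yielding a continuous 2D colormap and per-herb colors;
* everything renders to deterministic static SVG/HTML with optional
  highlight outlines.

## Worked example

The package ships a seven-formula tonic example (with hand-built synthetic
attribute flags and a five-element anchor palette):

```r
library(tcmviz)
fx <- tonicExample()
fx$group
#> FormulaGroup 'tonic': 7 formulas, 31 herbs
#>   Bazhentang           10 herbs (2 principal)
#>   Shenlingbaizhusan    11 herbs (3 principal)
#>   Shengmaisan           3 herbs (1 principal)
#>   Sijunzitang           4 herbs (1 principal)
#>   Dabuyinwan            4 herbs (2 principal)
#>   Siwutang              4 herbs (1 principal)
#>   Dihuangyinzi         15 herbs (4 principal)

pts <- embedHerbs(encodeAttributes(fx$attributes))
lay <- buildIcicle(fx$group, pts, seed = 42)
lay
#> IcicleLayout: 7 columns, principal region 4 row(s), 51 cells
#>   column order: Shengmaisan, Sijunzitang, Bazhentang, Shenlingbaizhusan,
#>   Siwutang, Dabuyinwan, Dihuangyinzi
```

The column order groups the Renshen-led formulas, then the
Shudihuang-led ones, each subgroup ordered by increasing principal count;
the 4-row principal region is set by Dihuangyinzi's four principal herbs.
The similarity layout vertically aligns more shared herbs than the raw
input order (8 vs 5 aligned pairs here):

```r
alignmentCount(lay)                         # 8
alignmentCount(inputOrderLayout(fx$group))  # 5
```

Overlaps and the classic decomposition of Bazhentang:

```r
M <- sharedHerbMatrix(fx$group)
sharedCounts(M)["Bazhentang", "Siwutang"]
#> [1] 4
resolveHerbHighlights(fx$group,
  c("Shudihuang", "Baishao", "Chuanxiong", "Danggui"))
#> [1] "Bazhentang" "Siwutang"
```

Selecting Siwutang's four non-ginseng herbs lights up exactly Bazhentang
and Siwutang — Bazhentang contains Sijunzitang's herbs plus these four.
Colors and the full report:

```r
field <- fitColorField(fx$anchors, pts)   # exact at the 5 anchors
renderReport(fx$group, lay, M, field, pts,
             highlightHerbs = c("Shudihuang", "Baishao", "Chuanxiong", "Danggui"),
             path = "tonic-report.html")
```

A command-line front end wrapping the same functions lives at
`system.file("cli", "formulaviz.R", package = "tcmviz")` with subcommands
`render`, `stats`, `matrix`, `layout`, `colors` and `simulate`.

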