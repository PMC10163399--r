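#' @import methods
NULL

#' FormulaGroup: a named collection of herbal medicine formulas
#'
#' A `FormulaGroup` holds an ordered list of formulas, each an ordered,
#' duplicate-free list of herb identifiers with a subset flagged as principal
#' herbs (Junyao). Herb identity is exact string equality on the Pinyin id; no
#' normalization of prepared vs. raw herb names is performed (e.g. `Gancao`
#' and `Zhigancao` are distinct).
#'
#' @slot name Single string naming the group (e.g. a formula category).
#' @slot formulas Named list; each element is a `list(herbs =, principal =)`
#'   where `herbs` is an ordered character vector of herb ids and `principal`
#'   is the subset of `herbs` flagged as principal, in `herbs` order.
#'
#' @seealso [readFormulas()], [validateGroup()], [sharedHerbMatrix()],
#'   [buildIcicle()]
#' @export
setClass("FormulaGroup",
  representation(name = "character", formulas = "list"))

setValidity("FormulaGroup", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single string")
  fn <- names(object@formulas)
  if (length(object@formulas) && (is.null(fn) || anyDuplicated(fn) || any(!nzchar(fn))))
    msg <- c(msg, "formula names must be unique non-empty strings")
  for (nm in fn) {
    f <- object@formulas[[nm]]
    if (!is.list(f) || !all(c("herbs", "principal") %in% names(f))) {
      msg <- c(msg, sprintf("formula '%s' lacks herbs/principal fields", nm))
      next
    }
    h <- f$herbs; p <- f$principal
    if (length(h) == 0L || any(!nzchar(h)))
      msg <- c(msg, sprintf("formula '%s' has an empty herb list or empty ids", nm))
    if (anyDuplicated(h))
      msg <- c(msg, sprintf("formula '%s' lists duplicate herbs: %s", nm,
                            paste(unique(h[duplicated(h)]), collapse = ", ")))
    if (!all(p %in% h))
      msg <- c(msg, sprintf("formula '%s': principal herbs not in herb list: %s",
                            nm, paste(setdiff(p, h), collapse = ", ")))
    if (!identical(p, h[h %in% p]))
      msg <- c(msg, sprintf("formula '%s': principal flags must preserve herb order", nm))
  }
  if (length(msg)) msg else TRUE
})

#' IcicleLayout: a column-per-formula icicle-plot grid
#'
#' Result of the similarity-based layout. Each formula occupies one column of
#' cells; rows `0 .. principalRows-1` form the padded principal region and
#' nonprincipal herbs start at row `principalRows` in every column, so the top
#' of all nonprincipal herbs is aligned across the plot. `PAD` positions are
#' simply absent from `cells` (a cell data.frame row exists only where a herb
#' is placed).
#'
#' @slot cells data.frame with columns `formula`, `row` (0-based integer),
#'   `herb`, `principal` (logical), `level` (integer depth within the
#'   principal region, `NA` for nonprincipal cells).
#' @slot principalRows Integer; height of the padded principal region
#'   (global maximum principal-herb count in the group).
#' @slot topLevel Named character; maps each formula to its top-level
#'   principal herb (`NA` for formulas without principal herbs, grouped last).
#' @slot formulaOrder Character; left-to-right column order.
#'
#' @seealso [buildIcicle()], [renderIcicle()], [alignmentCount()]
#' @export
setClass("IcicleLayout",
  representation(cells = "data.frame", principalRows = "integer",
                 topLevel = "character", formulaOrder = "character"))

setValidity("IcicleLayout", function(object) {
  msg <- character()
  cl <- object@cells
  need <- c("formula", "row", "herb", "principal", "level")
  if (!all(need %in% names(cl)))
    return(paste("cells must have columns", paste(need, collapse = ", ")))
  if (length(object@principalRows) != 1L || object@principalRows < 0L)
    msg <- c(msg, "principalRows must be a single nonnegative integer")
  if (!setequal(unique(cl$formula), object@formulaOrder))
    msg <- c(msg, "cells and formulaOrder disagree on the formula set")
  pr <- object@principalRows
  if (nrow(cl)) {
    if (any(cl$principal & cl$row >= pr))
      msg <- c(msg, "principal cells must lie above the principal region boundary")
    if (any(!cl$principal & cl$row < pr))
      msg <- c(msg, "nonprincipal cells must lie below the principal region")
    bad <- stats::aggregate(row ~ formula, cl, function(r) anyDuplicated(r) > 0L)
    if (any(bad$row)) msg <- c(msg, "a column holds two cells in one row")
  }
  if (!identical(names(object@topLevel), object@formulaOrder) &&
      !setequal(names(object@topLevel), object@formulaOrder))
    msg <- c(msg, "topLevel must be named by the formulas")
  if (length(msg)) msg else TRUE
})

#' SharedHerbMatrix: pairwise shared-herb counts between formulas
#'
#' Symmetric integer matrix indexed by formula name; off-diagonal entries are
#' pairwise herb-set intersection cardinalities and the diagonal holds each
#' formula's herb count (self-intersection). The diagonal is excluded from
#' pair statistics and from heat-map color normalization.
#'
#' @slot counts Integer matrix with identical row/column formula names.
#' @slot sizes Named integer vector of formula sizes (equals `diag(counts)`).
#'
#' @seealso [sharedHerbMatrix()], [groupStats()], [renderMatrix()]
#' @export
setClass("SharedHerbMatrix",
  representation(counts = "matrix", sizes = "integer"))

setValidity("SharedHerbMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "counts must be square with matching dimnames")
  if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "counts must be symmetric")
  if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
  if (nrow(m)) {
    sz <- diag(m)
    bound <- outer(sz, sz, pmin)
    if (any(m > bound)) msg <- c(msg, "an intersection exceeds min(|F_i|,|F_j|)")
    if (!identical(as.integer(sz), as.integer(object@sizes)))
      msg <- c(msg, "diagonal must equal the formula sizes")
  }
  if (length(msg)) msg else TRUE
})

#' ColorField2D: an RBF color interpolant over the herb embedding plane
#'
#' Per-channel radial-basis-function interpolant of anchor colors in
#' CIECAM02-UCS over 2D embedding coordinates. The field reproduces every
#' anchor's color exactly at the anchor's point (up to linear-solver
#' round-off) and defines a continuous 2D colormap over the plane.
#'
#' @slot anchors data.frame with columns `herb`, `element`, `srgb` (hex),
#'   `x`, `y` and the anchor UCS coordinates `Jp`, `ap`, `bp`.
#' @slot kernel Kernel name: one of `"linear"`, `"gaussian"`, `"cubic"`,
#'   `"thinplate"`.
#' @slot epsilon Shape parameter for the gaussian kernel (ignored otherwise).
#' @slot weights Numeric matrix (anchors x 3) of RBF weights for the
#'   J', a', b' channels.
#' @slot bbox Numeric length-4 `(xmin, xmax, ymin, ymax)` bounding box of the
#'   embedding the field was fitted for.
#'
#' @seealso [fitColorField()], [fieldUcs()], [rasterizeField()],
#'   [assignHerbColors()]
#' @export
setClass("ColorField2D",
  representation(anchors = "data.frame", kernel = "character",
                 epsilon = "numeric", weights = "matrix", bbox = "numeric"))

setValidity("ColorField2D", function(object) {
  msg <- character()
  need <- c("herb", "element", "srgb", "x", "y", "Jp", "ap", "bp")
  if (!all(need %in% names(object@anchors)))
    msg <- c(msg, paste("anchors must have columns", paste(need, collapse = ", ")))
  if (!object@kernel %in% c("linear", "gaussian", "cubic", "thinplate"))
    msg <- c(msg, "unknown kernel")
  if (nrow(object@weights) != nrow(object@anchors) || ncol(object@weights) != 3L)
    msg <- c(msg, "weights must be anchors x 3")
  if (length(object@bbox) != 4L || any(!is.finite(object@bbox)))
    msg <- c(msg, "bbox must be 4 finite numbers")
  if (length(msg)) msg else TRUE
})
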