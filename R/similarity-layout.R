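#' Order herbs by greedy nearest-neighbor chaining
#'
#' Builds the similarity sequence of a herb set: starting from a chosen (or
#' seeded-random) herb, repeatedly appends the unplaced herb closest to the
#' previously placed one. Ties are broken by input order.
#'
#' @param herbs Character vector of herb ids (the set H, in input order).
#' @param d Distance matrix covering all `herbs` (see [pairwiseDistance()]).
#' @param start Start herb: a herb id or an integer index into `herbs`. If
#'   `NULL`, the start index t is drawn uniformly from `1:length(herbs)`
#'   under `seed`.
#' @param seed Integer seed for the random start (only used when `start` is
#'   `NULL`).
#' @return Character vector: a permutation of `herbs`.
#' @examples
#' pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 0))
#' orderBySimilarity(c("a", "b", "c"), pairwiseDistance(pts), start = "a")
#' @export
orderBySimilarity <- function(herbs, d, start = NULL, seed = 1L) {
  n <- length(herbs)
  if (n == 0L) return(character(0))
  if (anyDuplicated(herbs)) stop("duplicate herb ids")
  if (!all(herbs %in% rownames(d))) stop("distance matrix does not cover all herbs")
  if (is.null(start)) {
    t <- withSeed(seed, sample.int(n, 1L))
  } else if (is.character(start)) {
    t <- match(start, herbs)
    if (is.na(t)) stop(sprintf("start herb '%s' is not in the herb set", start))
  } else {
    t <- as.integer(start)
    if (t < 1L || t > n) stop("start index out of range")
  }
  placed <- logical(n)
  seq_out <- integer(n)
  seq_out[1L] <- t; placed[t] <- TRUE
  for (i in seq_len(n - 1L)) {
    prev <- herbs[seq_out[i]]
    cand <- which(!placed)
    nxt <- cand[which.min(d[prev, herbs[cand]])]  # which.min = first min -> input-order tie-break
    seq_out[i + 1L] <- nxt; placed[nxt] <- TRUE
  }
  herbs[seq_out]
}

#' Assign a top-level principal herb to every formula
#'
#' First pass of the icicle layout. Herbs that are the sole principal of some
#' formula are collected and ordered by [orderBySimilarity()] (seeded random
#' start). Each formula is then resolved in input order: a sole principal is
#' its own top herb; a multi-principal formula reuses the first of its
#' principals already on the list (list order breaks ties), otherwise one of
#' its principals is drawn at random under the seed and appended to the list.
#' Formulas with no principal herb map to `NA` and are grouped last.
#'
#' @param group A [FormulaGroup-class].
#' @param d Distance matrix covering at least all principal herbs.
#' @param seed Integer seed controlling the random start and any random top
#'   picks; fixed seed gives identical assignments.
#' @return List with `topLevel` (named character, `NA` for zero-principal
#'   formulas) and `topOrder` (the ordered top-level herb list).
#' @export
assignTopLevel <- function(group, d, seed = 42L) {
  stopifnot(is(group, "FormulaGroup"))
  prin <- principalHerbs(group)
  allPrin <- unique(unlist(prin, use.names = FALSE))
  if (length(allPrin) && !all(allPrin %in% rownames(d)))
    stop("distance matrix does not cover all principal herbs")
  withSeed(seed, {
    sole <- unique(unlist(prin[lengths(prin) == 1L], use.names = FALSE))
    topOrder <- if (length(sole) > 1L) {
      orderBySimilarity(sole, d, start = sample.int(length(sole), 1L))
    } else sole
    top <- stats::setNames(rep(NA_character_, length(group)), formulaNames(group))
    for (nm in formulaNames(group)) {
      p <- prin[[nm]]
      if (length(p) == 0L) next
      listed <- topOrder[topOrder %in% p]
      if (length(listed)) {
        top[nm] <- listed[1L]
      } else {
        pick <- p[sample.int(length(p), 1L)]
        top[nm] <- pick
        topOrder <- c(topOrder, pick)
      }
    }
    list(topLevel = top, topOrder = topOrder)
  })
}

#' Lay out the principal region of the icicle plot
#'
#' Second pass, principal herbs only. Columns are grouped contiguously by
#' top-level herb, groups follow the ordered top-herb list, and within a
#' group columns are sorted by ascending principal-herb count (input order on
#' ties). In each column the top herb sits on row 0 and the remaining
#' principals follow sorted by distance to the top herb. The principal region
#' is padded to the global maximum principal count so that nonprincipal herbs
#' of all columns start at one common row.
#'
#' @param group A [FormulaGroup-class].
#' @param top Result of [assignTopLevel()].
#' @param d Distance matrix covering all principal herbs.
#' @return A partial [IcicleLayout-class] holding only principal cells.
#' @export
layoutPrincipal <- function(group, top, d) {
  stopifnot(is(group, "FormulaGroup"))
  prin <- principalHerbs(group)
  nPrin <- lengths(prin)
  principalRows <- if (length(nPrin)) max(nPrin) else 0L
  nms <- formulaNames(group)

  colOrder <- character(0)
  for (th in top$topOrder) {
    members <- nms[!is.na(top$topLevel[nms]) & top$topLevel[nms] == th]
    members <- members[order(nPrin[members])]      # stable: ties keep input order
    colOrder <- c(colOrder, members)
  }
  colOrder <- c(colOrder, nms[is.na(top$topLevel[nms])])

  cells <- lapply(colOrder, function(nm) {
    p <- prin[[nm]]
    if (length(p) == 0L) return(NULL)
    th <- top$topLevel[[nm]]
    rest <- setdiff(p, th)
    rest <- rest[order(d[th, rest])]               # stable sort, input-order ties
    herbsOrdered <- c(th, rest)
    data.frame(formula = nm, row = seq_along(herbsOrdered) - 1L,
               herb = herbsOrdered, principal = TRUE,
               level = seq_along(herbsOrdered) - 1L)
  })
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  if (is.null(cells))
    cells <- data.frame(formula = character(), row = integer(), herb = character(),
                        principal = logical(), level = integer())
  new("IcicleLayout", cells = cells, principalRows = as.integer(principalRows),
      topLevel = top$topLevel[colOrder], formulaOrder = colOrder)
}

#' Lay out the nonprincipal herbs of the icicle plot
#'
#' Final pass. The leftmost column's nonprincipal herbs are ordered by the
#' greedy similarity sequence started at the herb nearest the column's
#' top-level principal. In every subsequent column, herbs that also occur as
#' nonprincipal herbs of the column immediately to the left are aligned to
#' the same row first; the remaining herbs fill the free rows top-to-bottom,
#' sorted by ascending minimum distance to the left column's herb set.
#' Alignment copies exact row indices, so blank (PAD) rows may appear inside
#' a column; `compact = TRUE` instead keeps only the relative order and
#' closes all gaps.
#'
#' @param partial Partial [IcicleLayout-class] from [layoutPrincipal()].
#' @param group The [FormulaGroup-class] that produced `partial`.
#' @param d Distance matrix covering all herbs of the group.
#' @param compact Logical; close vertical gaps instead of exact-row
#'   alignment.
#' @return A complete [IcicleLayout-class].
#' @export
layoutRemaining <- function(partial, group, d, compact = FALSE) {
  stopifnot(is(partial, "IcicleLayout"), is(group, "FormulaGroup"))
  if (!all(herbUniverse(group) %in% rownames(d)))
    stop("distance matrix does not cover all herbs")
  pr <- principalRows(partial)
  cells <- layoutCells(partial)
  leftRows <- NULL    # herb -> row map of previous column's nonprincipal cells
  leftHerbs <- NULL   # previous column's full herb set
  for (nm in formulaOrder(partial)) {
    herbs <- formulaHerbs(group, nm)
    nonprin <- setdiff(herbs, principalHerbs(group, nm))
    if (length(nonprin) == 0L) { leftRows <- integer(0); leftHerbs <- herbs; next }
    if (is.null(leftRows)) {                       # leftmost column
      th <- topLevel(partial)[[nm]]
      startHerb <- if (!is.na(th)) nonprin[which.min(d[th, nonprin])] else nonprin[1L]
      ordered <- orderBySimilarity(nonprin, d, start = startHerb)
      rows <- stats::setNames(pr + seq_along(ordered) - 1L, ordered)
    } else {
      shared <- nonprin[nonprin %in% names(leftRows)]
      rows <- stats::setNames(unname(leftRows[shared]), shared)
      rest <- setdiff(nonprin, shared)
      if (length(rest)) {
        key <- vapply(rest, function(h) min(d[h, leftHerbs]), numeric(1))
        rest <- rest[order(key)]                   # stable: input-order ties
        cand <- pr:(max(c(rows, pr)) + length(rest))
        free <- setdiff(cand, unname(rows))
        rows <- c(rows, stats::setNames(free[seq_along(rest)], rest))
      }
    }
    cells <- rbind(cells, data.frame(
      formula = nm, row = as.integer(unname(rows[nonprin])), herb = nonprin,
      principal = FALSE, level = NA_integer_))
    leftRows <- rows
    leftHerbs <- herbs
  }
  if (compact && nrow(cells)) {
    for (nm in unique(cells$formula)) {
      i <- which(cells$formula == nm & !cells$principal)
      if (length(i))
        cells$row[i] <- pr + rank(cells$row[i], ties.method = "first") - 1L
    }
  }
  cells <- cells[order(match(cells$formula, formulaOrder(partial)), cells$row), ]
  rownames(cells) <- NULL
  new("IcicleLayout", cells = cells, principalRows = pr,
      topLevel = topLevel(partial), formulaOrder = formulaOrder(partial))
}

#' Build the full similarity-based icicle layout
#'
#' Pipeline of [assignTopLevel()], [layoutPrincipal()] and
#' [layoutRemaining()]: distances are taken from the 2D herb embedding and
#' the layout is deterministic for a fixed `(group, points, seed)`.
#'
#' @param group A [FormulaGroup-class].
#' @param points Herb embedding from [embedHerbs()] covering all herbs of the
#'   group.
#' @param seed Integer seed (random start / random top-herb picks).
#' @param compact Passed to [layoutRemaining()].
#' @return An [IcicleLayout-class].
#' @examples
#' fx <- tonicExample()
#' pts <- embedHerbs(encodeAttributes(fx$attributes))
#' lay <- buildIcicle(fx$group, pts, seed = 42)
#' principalRows(lay)
#' @export
buildIcicle <- function(group, points, seed = 42L, compact = FALSE) {
  if (length(group) == 0L)
    return(new("IcicleLayout",
               cells = data.frame(formula = character(), row = integer(),
                                  herb = character(), principal = logical(),
                                  level = integer()),
               principalRows = 0L, topLevel = character(0),
               formulaOrder = character(0)))
  miss <- setdiff(herbUniverse(group), rownames(points))
  if (length(miss))
    stop("no embedded point for herbs: ", paste(miss, collapse = ", "))
  d <- pairwiseDistance(points)
  top <- assignTopLevel(group, d, seed = seed)
  partial <- layoutPrincipal(group, top, d)
  layoutRemaining(partial, group, d, compact = compact)
}

#' Baseline layout in input order
#'
#' Reference layout without similarity ordering: columns follow the group's
#' input order and each column stacks its principal then nonprincipal herbs
#' in formula order (principal region padded globally as in the similarity
#' layout). Used to quantify how much vertical alignment the similarity
#' layout gains.
#'
#' @param group A [FormulaGroup-class].
#' @return An [IcicleLayout-class].
#' @export
inputOrderLayout <- function(group) {
  prin <- principalHerbs(group)
  pr <- if (length(prin)) max(lengths(prin)) else 0L
  nms <- formulaNames(group)
  cells <- lapply(nms, function(nm) {
    p <- prin[[nm]]
    np <- setdiff(formulaHerbs(group, nm), p)
    data.frame(formula = nm,
               row = c(seq_along(p) - 1L, pr + seq_along(np) - 1L),
               herb = c(p, np),
               principal = rep(c(TRUE, FALSE), c(length(p), length(np))),
               level = c(seq_along(p) - 1L, rep(NA_integer_, length(np))))
  })
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  top <- vapply(prin, function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  new("IcicleLayout", cells = cells, principalRows = as.integer(pr),
      topLevel = stats::setNames(top, nms), formulaOrder = nms)
}

#' Count vertically aligned shared-herb pairs
#'
#' Number of (adjacent column pair, herb) combinations where the same herb
#' occupies the same row in both columns — the quantity the similarity layout
#' maximizes greedily. Higher is better for visual comparison.
#'
#' @param layout An [IcicleLayout-class].
#' @return Integer count.
#' @export
alignmentCount <- function(layout) {
  ord <- formulaOrder(layout)
  cl <- layoutCells(layout)
  if (length(ord) < 2L) return(0L)
  total <- 0L
  for (i in seq_len(length(ord) - 1L)) {
    a <- cl[cl$formula == ord[i], ]
    b <- cl[cl$formula == ord[i + 1L], ]
    m <- merge(a[, c("herb", "row")], b[, c("herb", "row")], by = "herb")
    total <- total + sum(m$row.x == m$row.y)
  }
  as.integer(total)
}

#' Export an icicle layout as JSON
#'
#' Writes the grid including explicit PAD cells (herb `null`) so the file
#' fully describes the plot: for each column, rows `0` to the column's lowest
#' occupied row.
#'
#' @param layout An [IcicleLayout-class].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
layoutToJson <- function(layout, path = NULL) {
  cl <- layoutCells(layout)
  cols <- lapply(formulaOrder(layout), function(nm) {
    sub <- cl[cl$formula == nm, ]
    maxRow <- if (nrow(sub)) max(sub$row) else -1L
    cellList <- lapply(0:maxRow, function(r) {
      i <- which(sub$row == r)
      if (length(i)) {
        list(row = r, herb = sub$herb[i], principal = sub$principal[i],
             level = if (is.na(sub$level[i])) NULL else sub$level[i])
      } else list(row = r, herb = NULL, principal = FALSE, level = NULL)
    })
    list(formula = nm, cells = cellList)
  })
  obj <- list(columns = cols, principal_rows = principalRows(layout))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
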