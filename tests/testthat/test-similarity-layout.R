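test_that("greedy similarity sequences follow the nearest-neighbor chain", {
  pts <- collinearPoints()   # x = 0, 1, 3
  d <- pairwiseDistance(pts)
  expect_equal(orderBySimilarity(rownames(pts), d, start = "p0"),
               c("p0", "p1", "p3"))
  expect_equal(orderBySimilarity(rownames(pts), d, start = 1L),
               c("p0", "p1", "p3"))
  expect_equal(orderBySimilarity(character(0), d), character(0))
  expect_equal(orderBySimilarity("p1", d, start = "p1"), "p1")
  # determinism: same seed, same random start, same sequence
  s1 <- orderBySimilarity(rownames(pts), d, seed = 9L)
  s2 <- orderBySimilarity(rownames(pts), d, seed = 9L)
  expect_identical(s1, s2)
})

test_that("greedy chain matches the exhaustive-enumeration oracle (n <= 7)", {
  for (rep in 1:6) {
    set.seed(200 + rep)
    n <- sample(2:7, 1)
    pts <- matrix(rnorm(2 * n), n, 2,
                  dimnames = list(sprintf("h%d", seq_len(n)), NULL))
    d <- pairwiseDistance(pts)
    herbs <- rownames(pts)
    for (t in seq_len(n)) {
      expect_equal(orderBySimilarity(herbs, d, start = t),
                   greedyByEnumeration(herbs, d, t),
                   info = sprintf("rep %d, n %d, start %d", rep, n, t))
    }
  }
})

fx <- tonicExample()
pts <- embedHerbs(encodeAttributes(fx$attributes))
d <- pairwiseDistance(pts)

test_that("top-level assignment follows the sole-principal rule on the example", {
  top <- assignTopLevel(fx$group, d, seed = 42)
  # Renshen is sole principal of Shengmaisan and Sijunzitang -> must be listed
  expect_true("Renshen" %in% top$topOrder)
  expect_equal(top$topLevel[["Shengmaisan"]], "Renshen")
  expect_equal(top$topLevel[["Sijunzitang"]], "Renshen")
  expect_equal(top$topLevel[["Siwutang"]], "Shudihuang")
  # Bazhentang's principals Renshen and Shudihuang are both listed; the
  # earlier one in the ordered list wins
  both <- c("Renshen", "Shudihuang")
  expect_equal(top$topLevel[["Bazhentang"]],
               both[which.min(match(both, top$topOrder))])
  # Shenlingbaizhusan reuses listed Renshen rather than adding Baizhu/Fuling
  expect_equal(top$topLevel[["Shenlingbaizhusan"]], "Renshen")
  # determinism
  expect_identical(top, assignTopLevel(fx$group, d, seed = 42))
})

test_that("a formula whose principals occur nowhere else gets a seeded pick", {
  g <- FormulaGroup("g", data.frame(
    formula = c("F1", "F1", "F1", "F2"),
    herb = c("A", "B", "C", "Z"),
    is_principal = c(1, 1, 1, 1)))
  set.seed(77)
  pp <- matrix(rnorm(8), 4, 2, dimnames = list(c("A", "B", "C", "Z"), NULL))
  dd <- pairwiseDistance(pp)
  t1 <- assignTopLevel(g, dd, seed = 5)
  t2 <- assignTopLevel(g, dd, seed = 5)
  expect_identical(t1, t2)
  expect_true(t1$topLevel[["F1"]] %in% c("A", "B", "C"))
  expect_true(t1$topLevel[["F1"]] %in% t1$topOrder)
})

test_that("principal region groups, orders and pads columns correctly", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  # global pad = largest principal count in the group (Dihuangyinzi, 4)
  expect_equal(principalRows(lay), 4L)
  ord <- formulaOrder(lay)
  tl <- topLevel(lay)[ord]
  # contiguity of top-level groups
  expect_false(anyDuplicated(rle(ifelse(is.na(tl), ".none", tl))$values) > 0)
  # within the Renshen subgroup: 1-principal columns, then 2, then 3
  renshen <- ord[tl == "Renshen"]
  expect_equal(renshen,
               c("Shengmaisan", "Sijunzitang", "Bazhentang", "Shenlingbaizhusan"))
  # top herb occupies row 0 of its column
  cl <- layoutCells(lay)
  for (nm in ord) {
    r0 <- cl[cl$formula == nm & cl$row == 0L, ]
    expect_equal(r0$herb, tl[[nm]])
    expect_true(r0$principal)
  }
  # remaining principals sorted by distance to the top herb
  bz <- cl[cl$formula == "Shenlingbaizhusan" & cl$principal, ]
  bz <- bz[order(bz$row), ]
  dists <- d["Renshen", bz$herb[-1]]
  expect_true(all(diff(dists) >= 0))
})

test_that("single-principal groups need no padding", {
  g <- FormulaGroup("g", data.frame(
    formula = c("F1", "F1", "F2", "F2"),
    herb = c("A", "B", "B", "C"),
    is_principal = c(1, 0, 1, 0)))
  pp <- matrix(c(0, 1, 2, 0, 0, 0), 3, 2,
               dimnames = list(c("A", "B", "C"), NULL))
  lay <- buildIcicle(g, pp, seed = 1)
  expect_equal(principalRows(lay), 1L)
  cl <- layoutCells(lay)
  expect_true(all(cl$row[!cl$principal] >= 1L))
})

test_that("identical adjacent columns align perfectly", {
  g <- FormulaGroup("g", data.frame(
    formula = rep(c("F1", "F2"), each = 4),
    herb = rep(c("A", "B", "C", "D"), 2),
    is_principal = rep(c(1, 0, 0, 0), 2)))
  set.seed(12)
  pp <- matrix(rnorm(8), 4, 2, dimnames = list(c("A", "B", "C", "D"), NULL))
  lay <- buildIcicle(g, pp, seed = 1)
  cl <- layoutCells(lay)
  a <- cl[cl$formula == "F1", c("herb", "row")]
  b <- cl[cl$formula == "F2", c("herb", "row")]
  m <- merge(a, b, by = "herb")
  expect_equal(m$row.x, m$row.y)
})

test_that("shared nonprincipal herbs of adjacent fixture columns share rows", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  cl <- layoutCells(lay)
  ord <- formulaOrder(lay)
  i <- match("Sijunzitang", ord)
  expect_equal(ord[i + 1L], "Bazhentang")
  for (h in c("Baizhu", "Fuling")) {   # nonprincipal in both columns
    ra <- cl$row[cl$formula == "Sijunzitang" & cl$herb == h]
    rb <- cl$row[cl$formula == "Bazhentang" & cl$herb == h]
    expect_equal(ra, rb, info = h)
  }
})

test_that("a disjoint right column is sorted by distance to the left set", {
  g <- FormulaGroup("g", data.frame(
    formula = c("F1", "F1", "F2", "F2", "F2"),
    herb = c("L1", "L2", "R1", "R2", "R3"),
    is_principal = c(1, 0, 1, 0, 0)))
  pp <- rbind(L1 = c(0, 0), L2 = c(0, 1),
              R1 = c(5, 0), R2 = c(0, 1.4), R3 = c(0, 30))
  dd <- pairwiseDistance(pp)
  lay <- buildIcicle(g, pp, seed = 1)
  cl <- layoutCells(lay)
  r2 <- cl[cl$formula == "F2" & !cl$principal, ]
  r2 <- r2[order(r2$row), "herb"]
  # brute-force key: min distance to {L1, L2}
  key <- sapply(c("R2", "R3"), function(h) min(dd[h, c("L1", "L2")]))
  expect_equal(r2, names(sort(key)))
})

test_that("layout invariants hold on the example and under permutation", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  expect_length(layoutViolations(lay, fx$group), 0L)
  # permuted formula input order: invariants still hold, column content same
  perm <- rev(formulaNames(fx$group))
  gp <- FormulaGroup("tonic-rev", do.call(rbind, lapply(perm, function(nm)
    data.frame(formula = nm, herb = formulaHerbs(fx$group, nm),
               is_principal = as.integer(formulaHerbs(fx$group, nm) %in%
                                           principalHerbs(fx$group, nm))))))
  lay2 <- buildIcicle(gp, pts, seed = 42)
  expect_length(layoutViolations(lay2, gp), 0L)
  expect_equal(principalRows(lay2), principalRows(lay))
})

test_that("icicle building is deterministic and handles the empty group", {
  l1 <- buildIcicle(fx$group, pts, seed = 42)
  l2 <- buildIcicle(fx$group, pts, seed = 42)
  expect_equal(layoutCells(l1), layoutCells(l2))
  expect_identical(formulaOrder(l1), formulaOrder(l2))
  empty <- new("FormulaGroup", name = "none", formulas = list())
  le <- buildIcicle(empty, pts, seed = 1)
  expect_equal(nrow(layoutCells(le)), 0L)
  expect_length(formulaOrder(le), 0L)
})

test_that("the similarity layout aligns at least as much as input order", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  expect_gte(alignmentCount(lay), alignmentCount(inputOrderLayout(fx$group)))
})

test_that("compact mode closes gaps while preserving relative order", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  cmp <- buildIcicle(fx$group, pts, seed = 42, compact = TRUE)
  pr <- principalRows(cmp)
  cle <- layoutCells(lay); clc <- layoutCells(cmp)
  for (nm in formulaOrder(cmp)) {
    npc <- clc[clc$formula == nm & !clc$principal, ]
    npe <- cle[cle$formula == nm & !cle$principal, ]
    if (!nrow(npc)) next
    expect_equal(sort(npc$row), pr + seq_len(nrow(npc)) - 1L)  # no gaps
    expect_equal(npc$herb[order(npc$row)], npe$herb[order(npe$row)])  # order kept
  }
})

test_that("layout JSON export captures the grid including PAD cells", {
  lay <- buildIcicle(fx$group, pts, seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  layoutToJson(lay, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(parsed$principal_rows, principalRows(lay))
  expect_length(parsed$columns, length(formulaOrder(lay)))
  col1 <- parsed$columns[[1]]
  expect_equal(col1$formula, formulaOrder(lay)[1])
  nonPad <- sum(!sapply(col1$cells, function(c) is.null(c$herb)))
  expect_equal(nonPad, length(formulaHerbs(fx$group, col1$formula)))
})
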