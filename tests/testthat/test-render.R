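fx <- tonicExample()
pts <- embedHerbs(encodeAttributes(fx$attributes))
field <- fitColorField(fx$anchors, pts)
colors <- assignHerbColors(field, pts)
lay <- buildIcicle(fx$group, pts, seed = 42)
M <- sharedHerbMatrix(fx$group)

countMatches <- function(x, pattern) {
  sum(gregexpr(pattern, x, fixed = TRUE)[[1]] > 0)
}

test_that("a tiny layout renders one rect per herb and an italic label", {
  g <- FormulaGroup("g", data.frame(formula = c("F1", "F1"),
                                    herb = c("A", "B"),
                                    is_principal = c(1, 0)))
  pp <- rbind(A = c(0, 0), B = c(1, 0))
  tinyLay <- buildIcicle(g, pp, seed = 1)
  svg <- renderIcicle(tinyLay, c(A = "#888888", B = "#999999"))
  expect_equal(countMatches(svg, "<rect"), 2L)
  expect_equal(countMatches(svg, 'font-style="italic"'), 1L)
})

test_that("the fixture icicle has one cell per placed herb with principal styling", {
  svg <- renderIcicle(lay, colors)
  cl <- layoutCells(lay)
  expect_equal(countMatches(svg, "<rect"), nrow(cl))
  # every principal cell is bold + glow; counts match the principal cells
  expect_equal(countMatches(svg, 'filter="url(#glow)"'), sum(cl$principal))
  expect_equal(countMatches(svg, 'font-weight="bold"'), sum(cl$principal))
  # formula names in italics below each column
  expect_equal(countMatches(svg, 'font-style="italic"'), length(formulaOrder(lay)))
  expect_error(renderIcicle(lay, colors[-1, ]), "missing herb color")
})

test_that("matrix rendering normalizes to the off-diagonal maximum", {
  svg <- renderMatrix(M)
  expect_equal(countMatches(svg, "<rect"), 49L)   # 7 x 7 grid
  m <- sharedCounts(M); diag(m) <- 0L
  spec <- renderSpec()
  darkest <- tcmviz:::.seqColormap(1, spec$matrixLow, spec$matrixHigh)
  expect_equal(countMatches(svg, paste0('fill="', darkest, '"')),
               sum(m == max(m)))
  # all-zero off-diagonal: uniform background
  g0 <- FormulaGroup("g", data.frame(formula = c("F1", "F2"),
                                     herb = c("A", "B"),
                                     is_principal = c(1, 1)))
  svg0 <- renderMatrix(sharedHerbMatrix(g0))
  zero <- tcmviz:::.seqColormap(0, spec$matrixLow, spec$matrixHigh)
  expect_equal(countMatches(svg0, paste0('fill="', zero, '"')), 2L)
})

test_that("the scatter shows one correctly colored dot per herb over the map", {
  raster <- rasterizeField(field, 32L, 32L)
  svg <- renderScatter(pts, colors, raster)
  expect_equal(countMatches(svg, "<circle"), nrow(pts))
  for (h in sample(rownames(pts), 5)) {
    expect_true(grepl(paste0('fill="', colors$hex[colors$herb == h], '"'), svg))
  }
  expect_equal(countMatches(svg, "<image"), 1L)
})

test_that("the report embeds the three views and the statistics table", {
  html <- renderReport(fx$group, lay, M, field, pts)
  expect_equal(countMatches(html, "<svg"), 3L)
  expect_equal(countMatches(html, "hl-formula"), 0L)
  expect_equal(countMatches(html, "hl-herb"), 0L)
  expect_true(grepl("n_formulas", html) && grepl("<td>7</td>", html))
})

test_that("herb highlighting outlines exactly the containing formulas", {
  sel <- c("Shudihuang", "Baishao", "Chuanxiong", "Danggui")
  expect_setequal(resolveHerbHighlights(fx$group, sel, mode = "all"),
                  c("Bazhentang", "Siwutang"))
  # any-mode adds every formula containing at least one selected herb
  anyHit <- resolveHerbHighlights(fx$group, sel, mode = "any")
  expect_true(all(c("Bazhentang", "Siwutang", "Dabuyinwan", "Dihuangyinzi")
                  %in% anyHit))
  html <- renderReport(fx$group, lay, M, field, pts, highlightHerbs = sel)
  expect_equal(countMatches(html, "hl-herb"), 2L)
  html2 <- renderReport(fx$group, lay, M, field, pts,
                        highlightFormulas = "Shengmaisan")
  expect_equal(countMatches(html2, "hl-formula"), 1L)
  expect_error(renderReport(fx$group, lay, M, field, pts,
                            highlightFormulas = "Nope"), "Nope")
  expect_error(renderReport(fx$group, lay, M, field, pts,
                            highlightHerbs = "NotAHerb"), "NotAHerb")
})

test_that("rendering is byte-deterministic", {
  svg1 <- renderIcicle(lay, colors)
  svg2 <- renderIcicle(lay, colors)
  expect_identical(svg1, svg2)
  h1 <- renderReport(fx$group, lay, M, field, pts)
  h2 <- renderReport(fx$group, lay, M, field, pts)
  expect_identical(h1, h2)
})
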