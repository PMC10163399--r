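test_that("the appearance model reproduces the published worked example", {
  # CIE test case: sample XYZ (19.01, 20, 21.78), white (95.05, 100, 108.88),
  # La = 318.31 cd/m2, Yb = 20, average surround.
  vc <- cam02Conditions(La = 318.31, Yb = 20, XYZw = c(95.05, 100, 108.88))
  cam <- tcmviz:::.xyzToCam02(c(19.01, 20.00, 21.78), vc)
  expect_equal(unname(cam[1, "J"]), 41.73, tolerance = 1e-3)
  expect_equal(unname(cam[1, "C"]), 0.1047, tolerance = 1e-2)
  expect_equal(unname(cam[1, "h"]), 219.05, tolerance = 1e-3)
  # analytic inverse returns the input XYZ
  xyz <- tcmviz:::.cam02ToXyz(cam[, c("J", "C", "h"), drop = FALSE], vc)
  expect_equal(unname(xyz[1, ]), c(19.01, 20.00, 21.78), tolerance = 1e-9)
})

test_that("black and white are fixed points of the UCS transform", {
  black <- srgbToUcs(c(0, 0, 0))
  expect_equal(unname(black[1, ]), c(0, 0, 0), tolerance = 1e-9)
  rt <- ucsToSrgb(black)
  expect_equal(unname(rt[1, ]), c(0, 0, 0), tolerance = 1e-9)
  white <- srgbToUcs(c(1, 1, 1))
  expect_equal(unname(white[1, "Jp"]), 100, tolerance = 1e-9)
  rtw <- ucsToSrgb(white)
  expect_equal(unname(rtw[1, ]), c(1, 1, 1), tolerance = 1e-9)
})

test_that("the sRGB to XYZ stage agrees with the grDevices colorimetry", {
  set.seed(21)
  cols <- matrix(runif(3 * 40), ncol = 3)
  mine <- tcmviz:::.srgbLinearize(cols) %*% t(tcmviz:::.M_RGB2XYZ)
  ref <- grDevices::convertColor(cols, from = "sRGB", to = "XYZ")
  expect_lt(max(abs(mine - ref)), 0.006)
})

test_that("round trips over an sRGB lattice stay far below 0.5 dE", {
  g <- seq(0.05, 0.95, length.out = 10)
  lattice <- as.matrix(expand.grid(r = g, g = g, b = g))
  u <- srgbToUcs(lattice)
  back <- ucsToSrgb(u)
  expect_false(any(attr(back, "clamped")))
  u2 <- srgbToUcs(back)
  expect_lt(max(ucsDeltaE(u, u2)), 0.5)
})

test_that("non-finite colors are rejected", {
  expect_error(srgbToUcs(c(0.5, NA, 0.2)), "finite")
  expect_error(srgbToUcs(c(1.5, 0, 0)), "0,1")
  expect_error(ucsToSrgb(c(Inf, 0, 0)), "finite")
})

fx <- tonicExample()
pts <- embedHerbs(encodeAttributes(fx$attributes))

test_that("every kernel reproduces anchor colors exactly at anchor points", {
  for (k in c("linear", "gaussian", "cubic", "thinplate")) {
    field <- fitColorField(fx$anchors, pts, kernel = k)
    a <- fieldAnchors(field)
    got <- fieldUcs(field, as.matrix(a[, c("x", "y")]))
    expect_lt(max(abs(got - as.matrix(a[, c("Jp", "ap", "bp")]))), 1e-8)
  }
})

test_that("a two-anchor linear field averages colors at the midpoint", {
  anchors <- data.frame(herb = c("A", "B"), element = c("fire", "water"),
                        srgb = c("#C0716B", "#5A5F66"))
  pp <- rbind(A = c(0, 0), B = c(2, 0))
  field <- fitColorField(anchors, pp, kernel = "linear")
  mid <- fieldUcs(field, c(1, 0))
  avg <- colMeans(srgbToUcs(hexToRgb(anchors$srgb)))
  expect_equal(unname(mid[1, ]), unname(avg), tolerance = 1e-9)
})

test_that("dE to an anchor grows monotonically along the two-anchor segment", {
  anchors <- data.frame(herb = c("A", "B"), element = c("earth", "water"),
                        srgb = c("#C2A968", "#5A5F66"))
  pp <- rbind(A = c(0, 0), B = c(4, 0))
  field <- fitColorField(anchors, pp, kernel = "linear")
  s <- seq(0, 4, length.out = 21)
  u <- fieldUcs(field, cbind(s, 0))
  uA <- srgbToUcs(hexToRgb(anchors$srgb[1]))
  de <- ucsDeltaE(u, matrix(uA, 21, 3, byrow = TRUE))
  expect_true(all(diff(de) >= -1e-9))
})

test_that("degenerate anchor configurations behave as documented", {
  one <- fx$anchors[3, , drop = FALSE]
  field <- fitColorField(one, pts)
  u <- fieldUcs(field, rbind(c(-5, 2), c(8, -3), c(0, 0)))
  expect_equal(u[1, ], u[2, ])
  expect_equal(u[2, ], u[3, ])
  # coincident anchors with different colors name the offenders
  two <- data.frame(herb = c("A", "B"), element = c("fire", "water"),
                    srgb = c("#C0716B", "#5A5F66"))
  pp <- rbind(A = c(1, 1), B = c(1, 1))
  expect_error(fitColorField(two, pp), "coincident.*A.*B")
})

test_that("rasterization samples the field on the expanded bounding box", {
  field <- fitColorField(fx$anchors, pts)
  r1 <- rasterizeField(field, 1L, 1L, margin = 0.05)
  ctr <- c(mean(r1$bbox[1:2]), mean(r1$bbox[3:4]))
  direct <- ucsToSrgb(fieldUcs(field, ctr))
  expect_equal(as.numeric(r1$rgb[1, 1, ]), unname(direct[1, ]), tolerance = 1e-9)
  # doubling resolution leaves colors at anchor locations about unchanged
  r64 <- rasterizeField(field, 64L, 64L)
  r128 <- rasterizeField(field, 128L, 128L)
  lookup <- function(r, xy) {
    i <- which.min(abs(r$ys - xy[2])); j <- which.min(abs(r$xs - xy[1]))
    as.numeric(r$rgb[length(r$ys) - i + 1L, j, ])
  }
  a <- fieldAnchors(field)
  for (k in seq_len(nrow(a))) {
    xy <- c(a$x[k], a$y[k])
    expect_lt(max(abs(lookup(r64, xy) - lookup(r128, xy))), 0.15)
  }
})

test_that("a two-anchor raster varies monotonically along the anchor axis", {
  anchors <- data.frame(herb = c("A", "B"), element = c("metal", "water"),
                        srgb = c("#BFBFB8", "#5A5F66"))
  pp <- rbind(A = c(0, 0), B = c(10, 0))
  field <- fitColorField(anchors, pp, kernel = "linear")
  r <- rasterizeField(field, 32L, 3L, margin = 0)
  sel <- r$xs >= 0 & r$xs <= 10  # between the anchors the 1D field is linear
  mid <- r$rgb[2, sel, 1]        # red channel along the axis row
  expect_true(all(diff(mid) <= 1e-9) || all(diff(mid) >= -1e-9))
})

test_that("herb colors are pointwise field evaluations", {
  field <- fitColorField(fx$anchors, pts)
  hc <- assignHerbColors(field, pts)
  expect_setequal(hc$herb, rownames(pts))
  # representative herbs get their own anchor color back
  for (k in seq_len(nrow(fx$anchors))) {
    got <- hc$hex[hc$herb == fx$anchors$herb[k]]
    expect_equal(toupper(got), toupper(fx$anchors$srgb[k]))
  }
  # coincident points get identical colors
  pts2 <- rbind(pts, twin = pts["Fuling", ])
  hc2 <- assignHerbColors(field, pts2)
  expect_equal(hc2$hex[hc2$herb == "twin"], hc2$hex[hc2$herb == "Fuling"])
  # pointwise colors agree with a raster lookup at the same location
  r <- rasterizeField(field, 256L, 256L)
  for (h in fx$anchors$herb) {
    xy <- pts[h, ]
    i <- which.min(abs(r$ys - xy[2])); j <- which.min(abs(r$xs - xy[1]))
    cell <- as.numeric(r$rgb[length(r$ys) - i + 1L, j, ])
    expect_lt(max(abs(cell - hexToRgb(hc$hex[hc$herb == h])[1, ])), 0.12)
  }
  expect_error(assignHerbColors(field, pts, herbs = "Nosuch"), "Nosuch")
})

test_that("palette guidance flags saturated or uneven palettes", {
  same <- data.frame(herb = c("A", "B"), element = c("fire", "water"),
                     srgb = c("#888888", "#888888"))
  expect_silent(res <- checkPalette(same))
  expect_equal(res$lightnessRange, 0, tolerance = 1e-9)
  red <- data.frame(herb = c("A", "B"), element = c("fire", "water"),
                    srgb = c("#FF0000", "#888888"))
  expect_warning(checkPalette(red), "chroma")
  expect_silent(res2 <- checkPalette(tonicExample()$anchors))
  expect_true(res2$lightnessOk && res2$chromaOk)
})

test_that("gamut clamping stays modest on the default palette", {
  r <- rasterizeField(fitColorField(fx$anchors, pts), 64L, 64L)
  expect_lt(r$clampFraction, 0.2)
  # linear extrapolation beyond the anchor hull can clamp heavily for an
  # unlucky embedding, so the guarantee for random data is on the average
  fracs <- vapply(1:10, function(s) {
    sim <- simulateGroup(simConfig(nFormulas = 8, herbPool = 30, seed = s))
    spts <- embedHerbs(encodeAttributes(sim$attributes))
    rasterizeField(fitColorField(sim$anchors, spts), 48L, 48L)$clampFraction
  }, numeric(1))
  expect_lt(mean(fracs), 0.2)
})
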