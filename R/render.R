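#' Rendering style parameters
#'
#' Geometry and styling for the static views: cell size, fonts, the
#' principal-herb style (blue, bold, soft white glow), the italic formula
#' label with its fixed vertical offset, the sequential heat-map endpoints,
#' and highlight stroke styles (blue solid for selected formulas, red dashed
#' for formulas containing selected herbs).
#'
#' @param cellWidth,cellHeight Icicle cell size in px.
#' @param colGap Horizontal gap between columns in px.
#' @param fontSize Base font size in px.
#' @param fontFamily CSS font stack.
#' @param principalColor Text color for principal herbs.
#' @param labelOffset Vertical offset (px) of the formula name below its
#'   column's lowest cell.
#' @param matrixLow,matrixHigh Sequential colormap endpoints for the
#'   shared-herb heat map.
#' @param matrixCell Heat-map cell size in px.
#' @return List of rendering parameters.
#' @export
renderSpec <- function(cellWidth = 92, cellHeight = 20, colGap = 4,
                       fontSize = 11, fontFamily = "Helvetica, Arial, sans-serif",
                       principalColor = "#1f4e9c", labelOffset = 16,
                       matrixLow = "#f7fbff", matrixHigh = "#08306b",
                       matrixCell = 34) {
  stopifnot(cellWidth > 0, cellHeight > 0, matrixCell > 0, fontSize > 0)
  as.list(environment())
}

.svgOpen <- function(w, h) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
                 'viewBox="0 0 %s %s">'), fmtNum(w), fmtNum(h), fmtNum(w), fmtNum(h))
}

.glowFilter <- paste0(
  '<filter id="glow" x="-30%" y="-30%" width="160%" height="160%">',
  '<feDropShadow dx="0" dy="0" stdDeviation="1.6" flood-color="#ffffff" flood-opacity="0.9"/>',
  '</filter>')

.textColorFor <- function(hex) {
  lum <- colSums(grDevices::col2rgb(hex) * c(0.299, 0.587, 0.114)) / 255
  ifelse(lum < 0.45, "#ffffff", "#111111")
}

.herbColorVector <- function(herbColors) {
  if (is.data.frame(herbColors)) stats::setNames(herbColors$hex, herbColors$herb)
  else herbColors
}

#' Resolve a herb highlight to formulas
#'
#' Which formulas a set of selected herbs lights up: by default the formulas
#' containing *all* selected herbs (the lasso reading); `mode = "any"` uses
#' union semantics.
#'
#' @param group A [FormulaGroup-class].
#' @param herbs Character vector of herb ids (must all occur in the group).
#' @param mode `"all"` or `"any"` containment.
#' @return Character vector of formula names.
#' @export
resolveHerbHighlights <- function(group, herbs, mode = c("all", "any")) {
  mode <- match.arg(mode)
  bad <- setdiff(herbs, herbUniverse(group))
  if (length(bad)) stop("highlight herbs not in group: ", paste(bad, collapse = ", "))
  sel <- vapply(formulaNames(group), function(nm) {
    hs <- formulaHerbs(group, nm)
    if (mode == "all") all(herbs %in% hs) else any(herbs %in% hs)
  }, logical(1))
  formulaNames(group)[sel]
}

#' Render the icicle plot of a formula group
#'
#' One rectangle plus label per placed herb at its (column, row) grid
#' position, filled with the herb's color. Principal herbs are emphasized
#' (blue bold text with a soft white glow); each formula name is placed in
#' italics at a fixed offset below its column's lowest cell, so column height
#' doubles as a reading cue. Optional highlight outlines: blue solid for
#' `highlightFormulas`, red dashed for formulas containing all (or any) of
#' `highlightHerbs`.
#'
#' @param layout An [IcicleLayout-class].
#' @param herbColors Named hex vector or the data.frame from
#'   [assignHerbColors()]; must cover every placed herb.
#' @param spec Style list from [renderSpec()].
#' @param group The source [FormulaGroup-class]; required when herb
#'   highlights are requested.
#' @param highlightFormulas,highlightHerbs Character vectors to outline.
#' @param highlightMode Containment semantics for herb highlights.
#' @return Single SVG string (byte-deterministic for fixed inputs).
#' @export
renderIcicle <- function(layout, herbColors, spec = renderSpec(), group = NULL,
                         highlightFormulas = character(0),
                         highlightHerbs = character(0),
                         highlightMode = c("all", "any")) {
  highlightMode <- match.arg(highlightMode)
  cols <- .herbColorVector(herbColors)
  cl <- layoutCells(layout)
  miss <- setdiff(cl$herb, names(cols))
  if (length(miss)) stop("missing herb color for: ", paste(miss, collapse = ", "))
  ord <- formulaOrder(layout)
  herbHit <- character(0)
  if (length(highlightHerbs)) {
    if (is.null(group)) stop("herb highlighting requires 'group'")
    herbHit <- resolveHerbHighlights(group, highlightHerbs, highlightMode)
  }
  if (length(highlightFormulas)) {
    bad <- setdiff(highlightFormulas, ord)
    if (length(bad)) stop("highlight formulas not in group: ", paste(bad, collapse = ", "))
  }
  pad <- 6
  cw <- spec$cellWidth; ch <- spec$cellHeight; gap <- spec$colGap
  maxRow <- if (nrow(cl)) max(cl$row) else 0L
  w <- pad * 2 + length(ord) * (cw + gap) - gap
  h <- pad * 2 + (maxRow + 1) * ch + spec$labelOffset + spec$fontSize + 4
  out <- c(.svgOpen(w, h), "<defs>", .glowFilter, "</defs>")
  for (i in seq_along(ord)) {
    nm <- ord[i]
    sub <- cl[cl$formula == nm, , drop = FALSE]
    x <- pad + (i - 1) * (cw + gap)
    out <- c(out, sprintf('<g data-formula="%s">', xmlEscape(nm)))
    for (j in seq_len(nrow(sub))) {
      y <- pad + sub$row[j] * ch
      fill <- unname(cols[sub$herb[j]])
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#ffffff" stroke-width="1.00"/>',
        fmtNum(x), fmtNum(y), fmtNum(cw), fmtNum(ch), fill))
      if (sub$principal[j]) {
        out <- c(out, sprintf(
          '<text x="%s" y="%s" font-family="%s" font-size="%s" font-weight="bold" fill="%s" filter="url(#glow)" text-anchor="middle">%s</text>',
          fmtNum(x + cw / 2), fmtNum(y + ch / 2 + spec$fontSize * 0.35),
          spec$fontFamily, fmtNum(spec$fontSize), spec$principalColor,
          xmlEscape(sub$herb[j])))
      } else {
        out <- c(out, sprintf(
          '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="%s" text-anchor="middle">%s</text>',
          fmtNum(x + cw / 2), fmtNum(y + ch / 2 + spec$fontSize * 0.35),
          spec$fontFamily, fmtNum(spec$fontSize), .textColorFor(fill),
          xmlEscape(sub$herb[j])))
      }
    }
    lowest <- if (nrow(sub)) max(sub$row) else -1L
    labY <- pad + (lowest + 1) * ch + spec$labelOffset
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" font-style="italic" fill="#111111" text-anchor="middle">%s</text>',
      fmtNum(x + cw / 2), fmtNum(labY), spec$fontFamily, fmtNum(spec$fontSize),
      xmlEscape(nm)))
    outline <- NULL
    if (nm %in% highlightFormulas)
      outline <- '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#1f4e9c" stroke-width="2.00" class="hl-formula"/>'
    else if (nm %in% herbHit)
      outline <- '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#c0392b" stroke-width="2.00" stroke-dasharray="6,3" class="hl-herb"/>'
    if (!is.null(outline) && nrow(sub))
      out <- c(out, sprintf(outline,
        fmtNum(x - 1), fmtNum(pad + min(sub$row) * ch - 1),
        fmtNum(cw + 2), fmtNum((lowest - min(sub$row) + 1) * ch + 2)))
    out <- c(out, "</g>")
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

.seqColormap <- function(v, low, high) {
  # linear interpolation between endpoints in sRGB; v in [0,1]
  lo <- grDevices::col2rgb(low) / 255
  hi <- grDevices::col2rgb(high) / 255
  grDevices::rgb(t(lo %*% t(1 - v) + hi %*% t(v)))
}

#' Render the shared-herb matrix heat map
#'
#' n x n grid with a sequential colormap scaled to the off-diagonal maximum,
#' so the most-overlapping formula pair receives the darkest color. Diagonal
#' cells (formula sizes) are drawn neutrally and excluded from the scale.
#'
#' @param M A [SharedHerbMatrix-class].
#' @param spec Style list from [renderSpec()].
#' @return Single SVG string.
#' @export
renderMatrix <- function(M, spec = renderSpec()) {
  m <- sharedCounts(M)
  n <- nrow(m)
  cs <- spec$matrixCell
  labelSpace <- 110
  w <- labelSpace + n * cs + 8
  h <- labelSpace + n * cs + 8
  off <- m; diag(off) <- 0L
  top <- max(off, 0L)
  out <- .svgOpen(w, h)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- labelSpace + (j - 1) * cs
    y <- labelSpace + (i - 1) * cs
    if (i == j) {
      fill <- "#e8e8e8"
    } else {
      v <- if (top > 0) m[i, j] / top else 0
      fill <- .seqColormap(v, spec$matrixLow, spec$matrixHigh)
    }
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#ffffff" stroke-width="1.00"/>',
      fmtNum(x), fmtNum(y), fmtNum(cs), fmtNum(cs), fill))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="%s" text-anchor="middle">%d</text>',
      fmtNum(x + cs / 2), fmtNum(y + cs / 2 + spec$fontSize * 0.35),
      spec$fontFamily, fmtNum(spec$fontSize),
      if (i == j) "#666666" else .textColorFor(fill), m[i, j]))
  }
  for (i in seq_len(n)) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="#111111" text-anchor="end">%s</text>',
      fmtNum(labelSpace - 6), fmtNum(labelSpace + (i - 0.5) * cs + spec$fontSize * 0.35),
      spec$fontFamily, fmtNum(spec$fontSize), xmlEscape(rownames(m)[i])))
    xT <- labelSpace + (i - 0.5) * cs
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="#111111" text-anchor="start" transform="rotate(-60 %s %s)">%s</text>',
      fmtNum(xT), fmtNum(labelSpace - 6), spec$fontFamily, fmtNum(spec$fontSize),
      fmtNum(xT), fmtNum(labelSpace - 6), xmlEscape(colnames(m)[i])))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render the herb scatter over the continuous colormap
#'
#' Embeds the rasterized 2D colormap as a background image (base64 PNG) and
#' draws one labeled dot per herb at its embedded location, filled with the
#' herb's assigned color.
#'
#' @param points Herb embedding from [embedHerbs()].
#' @param herbColors Named hex vector or [assignHerbColors()] data.frame.
#' @param raster Result of [rasterizeField()] (background colormap); `NULL`
#'   for a plain background.
#' @param spec Style list from [renderSpec()].
#' @param labels Draw herb id labels next to the dots.
#' @param size Viewport size in px (square).
#' @return Single SVG string.
#' @export
renderScatter <- function(points, herbColors, raster = NULL,
                          spec = renderSpec(), labels = TRUE, size = 480) {
  cols <- .herbColorVector(herbColors)
  miss <- setdiff(rownames(points), names(cols))
  if (length(miss)) stop("missing herb color for: ", paste(miss, collapse = ", "))
  if (!is.null(raster)) {
    bb <- raster$bbox
  } else {
    bb <- c(min(points[, 1]), max(points[, 1]), min(points[, 2]), max(points[, 2]))
    ex <- 0.05 * c(bb[2] - bb[1], bb[4] - bb[3])
    ex[ex == 0] <- 0.5
    bb <- bb + c(-ex[1], ex[1], -ex[2], ex[2])
  }
  px <- function(x) (x - bb[1]) / (bb[2] - bb[1]) * size
  py <- function(y) (bb[4] - y) / (bb[4] - bb[3]) * size
  out <- .svgOpen(size, size)
  if (!is.null(raster)) {
    b64 <- jsonlite::base64_enc(png::writePNG(raster$rgb))
    b64 <- gsub("[\r\n]", "", b64)
    out <- c(out, sprintf(
      '<image x="0.00" y="0.00" width="%s" height="%s" preserveAspectRatio="none" href="data:image/png;base64,%s"/>',
      fmtNum(size), fmtNum(size), b64))
  }
  for (h in rownames(points)) {
    cx <- px(points[h, 1]); cy <- py(points[h, 2])
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="4.50" fill="%s" stroke="#333333" stroke-width="1.00"/>',
      fmtNum(cx), fmtNum(cy), unname(cols[h])))
    if (labels)
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="#111111">%s</text>',
        fmtNum(cx + 6), fmtNum(cy + 3), spec$fontFamily,
        fmtNum(spec$fontSize * 0.9), xmlEscape(h)))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render the combined static HTML report
#'
#' Single self-contained HTML document embedding the three linked views —
#' formula icicle plot, shared-herb matrix, herb scatter over the continuous
#' colormap — plus the group summary statistics. Optional static
#' highlighting: formulas in `highlightFormulas` are outlined with blue solid
#' lines; formulas containing the `highlightHerbs` selection (all-herbs
#' containment by default) are outlined with red dashed lines.
#'
#' @param group A [FormulaGroup-class].
#' @param layout An [IcicleLayout-class] of the group.
#' @param M A [SharedHerbMatrix-class] of the group.
#' @param field A [ColorField2D-class].
#' @param points Herb embedding covering the group.
#' @param spec Style list from [renderSpec()].
#' @param highlightFormulas,highlightHerbs Character vectors (must exist in
#'   the group; unknown names raise an error listing them).
#' @param highlightMode `"all"` or `"any"` herb containment.
#' @param rasterSize Raster resolution for the background colormap.
#' @param vc Viewing conditions.
#' @param path Optional output file; when given, the HTML is written there.
#' @return The HTML string (invisibly when `path` is given).
#' @export
renderReport <- function(group, layout, M, field, points, spec = renderSpec(),
                         highlightFormulas = character(0),
                         highlightHerbs = character(0),
                         highlightMode = c("all", "any"),
                         rasterSize = 96L, vc = cam02Conditions(),
                         path = NULL) {
  highlightMode <- match.arg(highlightMode)
  badF <- setdiff(highlightFormulas, formulaNames(group))
  badH <- setdiff(highlightHerbs, herbUniverse(group))
  if (length(badF) || length(badH))
    stop("unknown highlight names: ", paste(c(badF, badH), collapse = ", "))
  colors <- assignHerbColors(field, points, vc = vc)
  raster <- rasterizeField(field, rasterSize, rasterSize, vc = vc)
  svgIc <- renderIcicle(layout, colors, spec, group = group,
                        highlightFormulas = highlightFormulas,
                        highlightHerbs = highlightHerbs,
                        highlightMode = highlightMode)
  svgMx <- renderMatrix(M, spec)
  svgSc <- renderScatter(points, colors, raster, spec)
  st <- groupStats(group)
  statRows <- paste(vapply(names(st), function(k) sprintf(
    "<tr><td>%s</td><td>%s</td></tr>", xmlEscape(k),
    if (is.na(st[[k]])) "NA" else format(st[[k]], digits = 6)), character(1)),
    collapse = "\n")
  html <- paste(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", xmlEscape(groupName(group))),
    "<style>body{font-family:Helvetica,Arial,sans-serif;margin:20px}",
    "h2{margin:24px 0 8px 0}table{border-collapse:collapse}",
    "td{border:1px solid #ccc;padding:3px 10px}</style></head><body>",
    sprintf("<h1>Formula group: %s</h1>", xmlEscape(groupName(group))),
    "<h2>Group statistics</h2>", "<table>", statRows, "</table>",
    "<h2>Formula view (similarity-based icicle plot)</h2>", svgIc,
    "<h2>Shared-herb matrix</h2>", svgMx,
    "<h2>Herb view (2D attribute embedding)</h2>", svgSc,
    sprintf("<p>Colormap clamp fraction: %s</p>", fmtNum(raster$clampFraction)),
    "</body></html>", sep = "\n")
  if (!is.null(path)) {
    writeLines(html, path, useBytes = TRUE)
    return(invisible(html))
  }
  html
}
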