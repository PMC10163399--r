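#' Read an anchor-color file
#'
#' Anchors map representative herbs (identified by domain experts, one per
#' five-element category) to sRGB colors. JSON format:
#' `[{"herb": ..., "element": ..., "srgb": "#RRGGBB"}, ...]`.
#'
#' @param path Path to the JSON file.
#' @return data.frame with columns `herb`, `element`, `srgb`.
#' @export
readAnchors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(jsonlite::fromJSON(path))
  need <- c("herb", "element", "srgb")
  if (!all(need %in% names(df)))
    stop("anchor file must provide fields: ", paste(need, collapse = ", "))
  ok <- grepl("^#[0-9a-fA-F]{6}$", df$srgb)
  if (!all(ok))
    stop("invalid sRGB hex for anchors: ", paste(df$herb[!ok], collapse = ", "))
  if (anyDuplicated(df$herb))
    stop("duplicate anchor herb: ", paste(df$herb[duplicated(df$herb)], collapse = ", "))
  df[, need]
}

#' Default five-element anchor palette
#'
#' Muted colors for the five-element categories (wood/green, fire/red,
#' earth/yellow, metal/white-gray, water/black-gray), hand-picked so that
#' lightness does not vary excessively and chroma stays moderate (see
#' [checkPalette()]). Users are expected to override them with their own
#' anchors.
#'
#' @return Named character vector of hex colors, one per element.
#' @export
defaultElementColors <- function() {
  c(wood = "#7A9B6D", fire = "#C0716B", earth = "#C2A968",
    metal = "#BFBFB8", water = "#5A5F66")
}

.rbfKernel <- function(r, kernel, epsilon) {
  switch(kernel,
    linear = r,
    gaussian = exp(-(epsilon * r)^2),
    cubic = r^3,
    thinplate = ifelse(r > 0, r^2 * log(r), 0))
}

#' Fit an RBF color field over the herb embedding
#'
#' Converts each anchor's sRGB color to CIECAM02-UCS and fits one
#' radial-basis-function interpolant per UCS channel (J', a', b') over the
#' anchors' 2D embedding coordinates. Pure RBF with no polynomial tail, so
#' with the default linear kernel the field midway between two anchors is
#' exactly the channel-wise average of their colors, and every anchor's color
#' is reproduced exactly at its own point. A single anchor yields a constant
#' field.
#'
#' @param anchors data.frame with columns `herb`, `element`, `srgb` (see
#'   [readAnchors()]).
#' @param points Herb embedding from [embedHerbs()]; must cover all anchor
#'   herbs (its bounding box becomes the field's domain).
#' @param kernel `"linear"` (default), `"gaussian"`, `"cubic"`, or
#'   `"thinplate"`.
#' @param epsilon Gaussian shape parameter.
#' @param vc Viewing conditions from [cam02Conditions()].
#' @return A [ColorField2D-class].
#' @examples
#' fx <- tonicExample()
#' pts <- embedHerbs(encodeAttributes(fx$attributes))
#' field <- fitColorField(fx$anchors, pts)
#' fieldUcs(field, pts["Gancao", ])  # the earth anchor's own color
#' @export
fitColorField <- function(anchors, points,
                          kernel = c("linear", "gaussian", "cubic", "thinplate"),
                          epsilon = 1, vc = cam02Conditions()) {
  kernel <- match.arg(kernel)
  miss <- setdiff(anchors$herb, rownames(points))
  if (length(miss))
    stop("anchor herbs without embedded point: ", paste(miss, collapse = ", "))
  xy <- points[anchors$herb, , drop = FALSE]
  ucs <- srgbToUcs(hexToRgb(anchors$srgb), vc)
  dup <- duplicated(round(xy, 12))
  if (any(dup)) {
    for (i in which(dup)) {
      j <- which(colSums(abs(t(xy) - xy[i, ])) < 1e-12)[1L]
      if (max(abs(ucs[i, ] - ucs[j, ])) > 1e-9)
        stop(sprintf("coincident anchor points with different colors: %s, %s",
                     anchors$herb[j], anchors$herb[i]))
    }
    keep <- !dup
    anchors <- anchors[keep, , drop = FALSE]
    xy <- xy[keep, , drop = FALSE]
    ucs <- ucs[keep, , drop = FALSE]
  }
  n <- nrow(xy)
  w <- if (n == 1L) {
    matrix(ucs, 1, 3)            # constant field: weight is the color itself
  } else {
    A <- .rbfKernel(as.matrix(stats::dist(xy)), kernel, epsilon)
    sol <- tryCatch(solve(A, ucs), error = function(e)
      stop("singular RBF system for anchors: ",
           paste(anchors$herb, collapse = ", ")))
    sol
  }
  anchorDf <- data.frame(herb = anchors$herb, element = anchors$element,
                         srgb = anchors$srgb, x = xy[, 1], y = xy[, 2],
                         Jp = ucs[, 1], ap = ucs[, 2], bp = ucs[, 3])
  bbox <- c(min(points[, 1]), max(points[, 1]), min(points[, 2]), max(points[, 2]))
  new("ColorField2D", anchors = anchorDf, kernel = kernel,
      epsilon = epsilon, weights = unname(w), bbox = bbox)
}

#' @rdname fieldUcs
#' @export
setMethod("fieldUcs", "ColorField2D", function(object, xy) {
  xy <- rbind(xy)
  stopifnot(ncol(xy) == 2L, all(is.finite(xy)))
  centers <- as.matrix(object@anchors[, c("x", "y")])
  if (nrow(centers) == 1L) {
    out <- matrix(object@weights, nrow(xy), 3, byrow = TRUE)
  } else {
    r <- sqrt(outer(xy[, 1], centers[, 1], `-`)^2 +
              outer(xy[, 2], centers[, 2], `-`)^2)
    out <- .rbfKernel(r, object@kernel, object@epsilon) %*% object@weights
  }
  colnames(out) <- c("Jp", "ap", "bp")
  rownames(out) <- rownames(xy)
  out
})

#' Rasterize a color field into a continuous 2D colormap
#'
#' Evaluates the field on a regular grid over the (margin-expanded) bounding
#' box and converts to sRGB. The fraction of grid cells whose color fell
#' outside the sRGB gamut and was clamped is reported.
#'
#' @param field A [ColorField2D-class].
#' @param width,height Raster resolution in cells.
#' @param margin Fractional bbox expansion on each side.
#' @param vc Viewing conditions.
#' @return List with `rgb` (height x width x 3 array, row 1 = top = maximal
#'   y), `xs`, `ys` (cell-center coordinates), `bbox`, and `clampFraction`.
#' @export
rasterizeField <- function(field, width = 128L, height = 128L, margin = 0.05,
                           vc = cam02Conditions()) {
  bb <- field@bbox
  dx <- (bb[2] - bb[1]) * margin; dy <- (bb[4] - bb[3]) * margin
  if (dx == 0) dx <- 0.5
  if (dy == 0) dy <- 0.5
  bb <- bb + c(-dx, dx, -dy, dy)
  xs <- bb[1] + (seq_len(width) - 0.5) / width * (bb[2] - bb[1])
  ys <- bb[3] + (seq_len(height) - 0.5) / height * (bb[4] - bb[3])
  grid <- cbind(rep(xs, times = height), rep(rev(ys), each = width))
  srgb <- ucsToSrgb(fieldUcs(field, grid), vc)
  arr <- array(0, c(height, width, 3))
  for (k in 1:3) arr[, , k] <- matrix(srgb[, k], height, width, byrow = TRUE)
  list(rgb = arr, xs = xs, ys = ys, bbox = bb,
       clampFraction = mean(attr(srgb, "clamped")))
}

#' Assign colors to herbs from a color field
#'
#' Evaluates the field at each herb's embedded location (pointwise, no
#' rasterization involved) and converts to display sRGB.
#'
#' @param field A [ColorField2D-class].
#' @param points Herb embedding covering all herbs to color.
#' @param herbs Optional character vector restricting which herbs to color
#'   (default: all rows of `points`).
#' @param vc Viewing conditions.
#' @return data.frame with columns `herb`, `hex`, `Jp`, `ap`, `bp`,
#'   `clamped`.
#' @export
assignHerbColors <- function(field, points, herbs = rownames(points),
                             vc = cam02Conditions()) {
  miss <- setdiff(herbs, rownames(points))
  if (length(miss))
    stop("no embedded point for herbs: ", paste(miss, collapse = ", "))
  ucs <- fieldUcs(field, points[herbs, , drop = FALSE])
  srgb <- ucsToSrgb(ucs, vc)
  data.frame(herb = herbs, hex = rgbToHex(srgb),
             Jp = ucs[, 1], ap = ucs[, 2], bp = ucs[, 3],
             clamped = attr(srgb, "clamped"), row.names = NULL)
}

#' Check an anchor palette against perceptual design guidance
#'
#' Representative colors should not vary too much in luminance and should
#' avoid high saturation. Reports the UCS lightness (J') range and maximum
#' colorfulness (M') of the palette and warns when either exceeds its bound.
#'
#' @param anchors data.frame with an `srgb` column of hex colors.
#' @param maxLightnessRange Upper bound on `max(J') - min(J')`.
#' @param maxChroma Upper bound on the UCS colorfulness M'.
#' @param vc Viewing conditions.
#' @return List with `lightnessRange`, `maxChroma`, `lightnessOk`,
#'   `chromaOk`, and per-anchor `detail` data.frame.
#' @export
checkPalette <- function(anchors, maxLightnessRange = 45, maxChroma = 30,
                         vc = cam02Conditions()) {
  if (nrow(anchors) < 2L) stop("need at least 2 anchors to assess a palette")
  ucs <- srgbToUcs(hexToRgb(anchors$srgb), vc)
  chroma <- sqrt(ucs[, 2]^2 + ucs[, 3]^2)
  lr <- max(ucs[, 1]) - min(ucs[, 1])
  res <- list(lightnessRange = lr, maxChroma = max(chroma),
              lightnessOk = lr <= maxLightnessRange,
              chromaOk = max(chroma) <= maxChroma,
              detail = data.frame(herb = anchors$herb, srgb = anchors$srgb,
                                  Jp = ucs[, 1], chroma = chroma))
  if (!res$lightnessOk)
    warning(sprintf("palette lightness range %.1f exceeds %.1f", lr, maxLightnessRange))
  if (!res$chromaOk)
    warning(sprintf("palette max chroma %.1f exceeds %.1f", max(chroma), maxChroma))
  res
}

#' Write a raster colormap to PNG / herb colors to CSV
#'
#' @param raster Result of [rasterizeField()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRasterPng <- function(raster, path) {
  png::writePNG(raster$rgb, path)
  invisible(path)
}

#' @rdname writeRasterPng
#' @param colors Result of [assignHerbColors()].
#' @export
writeHerbColors <- function(colors, path) {
  utils::write.csv(colors[, c("herb", "hex")], path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
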