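# sRGB <-> CIEXYZ <-> CIECAM02 <-> CAM02-UCS conversions.
#
# Forward model follows the published CIECAM02 equations (CAT02 chromatic
# adaptation, Hunt-Pointer-Estevez cone space, post-adaptation compression,
# opponent decomposition, lightness/chroma/hue correlates) and the CAM02-UCS
# reparameterization J' = 1.7J/(1+0.007J), M' = ln(1+0.0228M)/0.0228,
# a' = M' cos h, b' = M' sin h. The inverse is analytic, so the round trip is
# exact to floating-point for in-gamut colors.

.M_CAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                     -0.7036, 1.6975, 0.0061,
                     0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
.M_HPE <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0.00000, 0.00000, 1.00000), 3, 3, byrow = TRUE)
# linear sRGB -> XYZ (D65), Y in [0,1]
.M_RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

#' CIECAM02 viewing conditions
#'
#' Fixed parameter set describing the assumed viewing environment. The
#' package default models an sRGB display in an average surround: D65 adopted
#' white (the exact white of the sRGB primaries matrix), adapting luminance
#' `La = 64/(5*pi)` cd/m2 (dim ambient, ~20% of a 64 cd/m2 reference),
#' background relative luminance `Yb = 20`, surround parameters
#' `F = 1, c = 0.69, Nc = 1`. All derived constants are precomputed.
#'
#' @param La Adapting field luminance (cd/m2).
#' @param Yb Relative background luminance (0-100 scale).
#' @param surround `"average"`, `"dim"`, or `"dark"`.
#' @param XYZw Adopted white point on the 0-100 scale (default: sRGB D65).
#' @return List of viewing-condition constants, for use with the conversion
#'   functions.
#' @export
cam02Conditions <- function(La = 64 / (5 * pi), Yb = 20,
                            surround = c("average", "dim", "dark"),
                            XYZw = NULL) {
  surround <- match.arg(surround)
  sp <- switch(surround,
    average = c(F = 1.0, c = 0.690, Nc = 1.0),
    dim = c(F = 0.9, c = 0.590, Nc = 0.9),
    dark = c(F = 0.8, c = 0.525, Nc = 0.8))
  if (is.null(XYZw)) XYZw <- as.numeric(.M_RGB2XYZ %*% c(1, 1, 1)) * 100
  k <- 1 / (5 * La + 1)
  Fl <- 0.2 * k^4 * (5 * La) + 0.1 * (1 - k^4)^2 * (5 * La)^(1 / 3)
  n <- Yb / XYZw[2]
  Nbb <- 0.725 * (1 / n)^0.2
  z <- 1.48 + sqrt(n)
  D <- min(max(sp["F"] * (1 - (1 / 3.6) * exp((-La - 42) / 92)), 0), 1)
  RGBw <- as.numeric(.M_CAT02 %*% XYZw)
  Dgain <- XYZw[2] * D / RGBw + 1 - D      # per-channel adaptation gain
  RGBwc <- Dgain * RGBw
  RGBwp <- as.numeric(.M_HPE %*% solve(.M_CAT02) %*% RGBwc)
  RGBwa <- .cam02Compress(RGBwp, Fl)
  Aw <- (2 * RGBwa[1] + RGBwa[2] + RGBwa[3] / 20 - 0.305) * Nbb
  list(La = La, Yb = Yb, surround = surround, XYZw = XYZw,
       F = unname(sp["F"]), c = unname(sp["c"]), Nc = unname(sp["Nc"]),
       Fl = Fl, n = n, Nbb = Nbb, Ncb = Nbb, z = z, D = D,
       Dgain = Dgain, Aw = Aw)
}

.cam02Compress <- function(x, Fl) {
  y <- (Fl * abs(x) / 100)^0.42
  sign(x) * 400 * y / (y + 27.13) + 0.1
}

.cam02Expand <- function(xa, Fl) {
  t <- xa - 0.1
  y <- 27.13 * abs(t) / pmax(400 - abs(t), 1e-12)
  sign(t) * (100 / Fl) * y^(1 / 0.42)
}

# XYZ (0-100, rows) -> CIECAM02 correlates J, C, h (deg), M
.xyzToCam02 <- function(xyz, vc) {
  xyz <- rbind(xyz)
  rgb <- xyz %*% t(.M_CAT02)
  rgbc <- sweep(rgb, 2, vc$Dgain, `*`)
  Mh <- .M_HPE %*% solve(.M_CAT02)
  rgbp <- rgbc %*% t(Mh)
  rgba <- .cam02Compress(rgbp, vc$Fl)
  Ra <- rgba[, 1]; Ga <- rgba[, 2]; Ba <- rgba[, 3]
  a <- Ra - 12 * Ga / 11 + Ba / 11
  b <- (Ra + Ga - 2 * Ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  A <- (2 * Ra + Ga + Ba / 20 - 0.305) * vc$Nbb
  J <- 100 * pmax(A / vc$Aw, 0)^(vc$c * vc$z)
  t <- (50000 / 13) * vc$Nc * vc$Ncb * et * sqrt(a^2 + b^2) /
    (Ra + Ga + 21 / 20 * Ba)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^vc$n)^0.73
  cbind(J = J, C = C, h = h, M = C * vc$Fl^0.25)
}

# CIECAM02 J, C, h (rows) -> XYZ (0-100)
.cam02ToXyz <- function(JCh, vc) {
  JCh <- rbind(JCh)
  J <- JCh[, 1]; C <- JCh[, 2]; h <- JCh[, 3]
  n <- length(J)
  t <- ifelse(J > 0, (C / (sqrt(pmax(J, 1e-12) / 100) *
                             (1.64 - 0.29^vc$n)^0.73))^(1 / 0.9), 0)
  hr <- h * pi / 180
  et <- 0.25 * (cos(hr + 2) + 3.8)
  A <- vc$Aw * (pmax(J, 0) / 100)^(1 / (vc$c * vc$z))
  p2 <- A / vc$Nbb + 0.305
  p3 <- 21 / 20
  a <- numeric(n); b <- numeric(n)
  pos <- t > 1e-12
  if (any(pos)) {
    p1 <- (50000 / 13) * vc$Nc * vc$Ncb * et[pos] / t[pos]
    sh <- sin(hr[pos]); ch <- cos(hr[pos])
    num <- p2[pos] * (2 + p3) * (460 / 1403)
    useSin <- abs(sh) >= abs(ch)
    bpos <- numeric(sum(pos)); apos <- numeric(sum(pos))
    if (any(useSin)) {
      i <- useSin
      p4 <- p1[i] / sh[i]
      bpos[i] <- num[i] / (p4 + (2 + p3) * (220 / 1403) * (ch[i] / sh[i]) -
                             27 / 1403 + p3 * 6300 / 1403)
      apos[i] <- bpos[i] * ch[i] / sh[i]
    }
    if (any(!useSin)) {
      i <- !useSin
      p5 <- p1[i] / ch[i]
      apos[i] <- num[i] / (p5 + (2 + p3) * (220 / 1403) -
                             (27 / 1403 - p3 * 6300 / 1403) * (sh[i] / ch[i]))
      bpos[i] <- apos[i] * sh[i] / ch[i]
    }
    a[pos] <- apos; b[pos] <- bpos
  }
  Ra <- (460 * p2 + 451 * a + 288 * b) / 1403
  Ga <- (460 * p2 - 891 * a - 261 * b) / 1403
  Ba <- (460 * p2 - 220 * a - 6300 * b) / 1403
  rgbp <- cbind(.cam02Expand(Ra, vc$Fl), .cam02Expand(Ga, vc$Fl),
                .cam02Expand(Ba, vc$Fl))
  Mh <- .M_CAT02 %*% solve(.M_HPE)
  rgbc <- rgbp %*% t(Mh)
  rgb <- sweep(rgbc, 2, vc$Dgain, `/`)
  rgb %*% t(solve(.M_CAT02))
}

.srgbLinearize <- function(c) ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
.srgbDelinearize <- function(c) {
  c <- pmax(c, 0)
  ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
}

#' Convert between sRGB and CIECAM02-UCS
#'
#' `srgbToUcs` maps sRGB triples through CIEXYZ (D65) and the CIECAM02
#' appearance model into the CAM02-UCS uniform space, where Euclidean
#' distance approximates perceived color difference (ΔE). `ucsToSrgb` is the
#' analytic inverse; out-of-gamut results are clamped per channel to `[0,1]`
#' and flagged.
#'
#' @param srgb Numeric matrix (n x 3) or length-3 vector with components in
#'   `[0,1]`.
#' @param ucs Numeric matrix (n x 3) or length-3 vector of `(J', a', b')`.
#' @param vc Viewing conditions from [cam02Conditions()].
#' @return `srgbToUcs`: numeric matrix (n x 3) with columns `Jp`, `ap`, `bp`.
#'   `ucsToSrgb`: numeric matrix (n x 3) in `[0,1]` with a logical attribute
#'   `"clamped"` marking rows that left the sRGB gamut.
#' @examples
#' srgbToUcs(c(0, 0, 0))            # black: J' = 0
#' u <- srgbToUcs(c(0.2, 0.5, 0.3))
#' ucsToSrgb(u)                     # round trip
#' @export
srgbToUcs <- function(srgb, vc = cam02Conditions()) {
  srgb <- rbind(srgb)
  if (any(!is.finite(srgb)) || any(srgb < -1e-9) || any(srgb > 1 + 1e-9))
    stop("sRGB components must be finite and in [0,1]")
  xyz <- .srgbLinearize(srgb) %*% t(.M_RGB2XYZ) * 100
  cam <- .xyzToCam02(xyz, vc)
  camToUcs(cam)
}

#' @rdname srgbToUcs
#' @export
ucsToSrgb <- function(ucs, vc = cam02Conditions()) {
  ucs <- rbind(ucs)
  if (any(!is.finite(ucs))) stop("UCS coordinates must be finite")
  cam <- ucsToCam(ucs, vc)
  xyz <- .cam02ToXyz(cam[, c("J", "C", "h"), drop = FALSE], vc)
  lin <- xyz %*% t(solve(.M_RGB2XYZ)) / 100
  out <- .srgbDelinearize(lin)
  clamped <- apply(out < -1e-9 | out > 1 + 1e-9, 1, any) | apply(lin < -1e-9, 1, any)
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("r", "g", "b")
  attr(out, "clamped") <- unname(clamped)
  out
}

#' @rdname srgbToUcs
#' @param cam Matrix with columns `J`, `M`, `h` (appearance correlates).
#' @export
camToUcs <- function(cam) {
  cam <- rbind(cam)
  J <- cam[, "J"]; M <- cam[, "M"]; h <- cam[, "h"]
  Jp <- 1.7 * J / (1 + 0.007 * J)
  Mp <- log(1 + 0.0228 * M) / 0.0228
  cbind(Jp = Jp, ap = Mp * cos(h * pi / 180), bp = Mp * sin(h * pi / 180))
}

#' @rdname srgbToUcs
#' @export
ucsToCam <- function(ucs, vc = cam02Conditions()) {
  ucs <- rbind(ucs)
  Jp <- ucs[, 1]; ap <- ucs[, 2]; bp <- ucs[, 3]
  J <- Jp / (1.7 - 0.007 * Jp)
  Mp <- sqrt(ap^2 + bp^2)
  M <- (exp(0.0228 * Mp) - 1) / 0.0228
  h <- (atan2(bp, ap) * 180 / pi) %% 360
  cbind(J = J, C = M / vc$Fl^0.25, h = h, M = M)
}

#' Perceptual color difference in CAM02-UCS
#'
#' Euclidean distance between UCS coordinates (ΔE).
#'
#' @param u,v Numeric matrices (n x 3) or length-3 vectors of UCS
#'   coordinates.
#' @return Numeric vector of distances.
#' @export
ucsDeltaE <- function(u, v) {
  u <- rbind(u); v <- rbind(v)
  sqrt(rowSums((u - v)^2))
}
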