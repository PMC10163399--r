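# Run code with a locally seeded RNG, restoring global state afterwards.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# sprintf-style number formatting shared by all SVG emitters so output is
# byte-stable across platforms.
fmtNum <- function(x) sprintf("%.2f", x)

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Convert sRGB triples to hex strings and back
#'
#' @param srgb Numeric matrix (n x 3) or length-3 vector in `[0,1]`.
#' @return `rgbToHex`: character vector of `#RRGGBB` strings.
#' @export
rgbToHex <- function(srgb) {
  m <- rbind(srgb)
  grDevices::rgb(m[, 1], m[, 2], m[, 3])
}

#' @rdname rgbToHex
#' @param hex Character vector of `#RRGGBB` strings.
#' @return `hexToRgb`: numeric matrix (n x 3) in `[0,1]`.
#' @export
hexToRgb <- function(hex) {
  t(grDevices::col2rgb(hex)) / 255
}
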