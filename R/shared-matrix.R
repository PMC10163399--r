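#' Pairwise shared-herb counts between formulas
#'
#' Computes the formula-by-formula co-occurrence matrix: entry (i, j) is the
#' number of herbs the two formulas share (exact string identity), and the
#' diagonal holds each formula's herb count. Implemented as the cross-product
#' of the herb-formula incidence matrix.
#'
#' @param group A [FormulaGroup-class].
#' @return A [SharedHerbMatrix-class].
#' @examples
#' fx <- tonicExample()
#' M <- sharedHerbMatrix(fx$group)
#' sharedCounts(M)["Bazhentang", "Siwutang"]  # 4
#' @export
sharedHerbMatrix <- function(group) {
  stopifnot(is(group, "FormulaGroup"))
  nms <- formulaNames(group)
  univ <- herbUniverse(group)
  B <- matrix(0L, length(univ), length(nms), dimnames = list(univ, nms))
  for (nm in nms) B[formulaHerbs(group, nm), nm] <- 1L
  M <- crossprod(B)
  storage.mode(M) <- "integer"
  new("SharedHerbMatrix", counts = M,
      sizes = stats::setNames(diag(M), nms))
}

#' Summary statistics of a formula group
#'
#' Group-level counts and the distribution of pairwise overlap: number of
#' formulas, herb universe size, number of distinct principal herbs,
#' min/median/max herbs per formula, median principal herbs per formula, and
#' mean/sample-SD of the shared-herb counts over all unordered formula pairs
#' (diagonal excluded). Pairwise statistics are `NA` for single-formula
#' groups; the SD is `NA` when only one pair exists.
#'
#' @param group A [FormulaGroup-class].
#' @return Named list of statistics.
#' @examples
#' fx <- tonicExample()
#' groupStats(fx$group)$max_herbs_per_formula  # 15
#' @export
groupStats <- function(group) {
  stopifnot(is(group, "FormulaGroup"))
  sizes <- lengths(formulaHerbs(group))
  nPrin <- lengths(principalHerbs(group))
  M <- sharedCounts(sharedHerbMatrix(group))
  pairs <- M[upper.tri(M)]
  list(
    n_formulas = length(group),
    n_herbs = length(herbUniverse(group)),
    n_principal = length(unique(unlist(principalHerbs(group), use.names = FALSE))),
    min_herbs_per_formula = min(sizes),
    median_herbs_per_formula = stats::median(sizes),
    max_herbs_per_formula = max(sizes),
    median_principal_per_formula = stats::median(nPrin),
    mean_shared = if (length(pairs)) mean(pairs) else NA_real_,
    sd_shared = if (length(pairs) > 1L) stats::sd(pairs) else NA_real_)
}

#' Export a shared-herb matrix as CSV / group stats as JSON
#'
#' @param M A [SharedHerbMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSharedMatrix <- function(M, path) {
  utils::write.csv(as.data.frame(sharedCounts(M)), path, quote = FALSE)
  invisible(path)
}

#' @rdname writeSharedMatrix
#' @param stats Result of [groupStats()].
#' @export
writeGroupStats <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
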