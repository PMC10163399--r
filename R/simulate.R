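#' Configuration for the synthetic formula-group generator
#'
#' Defaults emulate the scale of a tonic-formula category from a classical
#' formula textbook: 20 formulas over a pool of 58 herbs, 2-15 herbs per
#' formula with median 7.5, mostly one principal herb per formula. Formula
#' sizes follow a discretized log-normal matched to (min, median, max);
#' attribute flags are independent Bernoulli draws per block with at least
#' one flag forced per block (every real herb has at least one property,
#' flavor and meridian).
#'
#' @param nFormulas Number of formulas.
#' @param herbPool Herb pool size (must be >= `sizeMax`).
#' @param sizeMin,sizeMedian,sizeMax Herbs-per-formula distribution targets.
#' @param principalProbs Probabilities of 1, 2, 3, ... principal herbs per
#'   formula (median 1 with the default).
#' @param attrProbs Per-block Bernoulli flag probabilities
#'   (`siqi`, `wuwei`, `guijing`).
#' @param overlapWeight Preferential-reuse weight: sampling weight of a herb
#'   is `1 + overlapWeight * timesUsed`, so some herbs recur across formulas
#'   and pairwise overlaps are nonzero. `0` gives uniform sampling.
#' @param seed Integer seed; the whole generator is deterministic given the
#'   config.
#' @return List of class `simConfig`.
#' @export
simConfig <- function(nFormulas = 20L, herbPool = 58L, sizeMin = 2L,
                      sizeMedian = 7.5, sizeMax = 15L,
                      principalProbs = c(0.7, 0.2, 0.1),
                      attrProbs = c(siqi = 0.2, wuwei = 0.2, guijing = 0.22),
                      overlapWeight = 1, seed = 42L) {
  stopifnot(sizeMin >= 2L, sizeMin <= sizeMedian, sizeMedian <= sizeMax,
            all(attrProbs >= 0 & attrProbs <= 1), overlapWeight >= 0)
  if (herbPool < sizeMax)
    stop("herbPool must be at least the maximum formula size")
  structure(as.list(environment()), class = "simConfig")
}

#' Generate a synthetic formula group with attributes and anchors
#'
#' Draws a seeded random formula group with the statistical shape configured
#' in [simConfig()]: log-normal formula sizes truncated to
#' `[sizeMin, sizeMax]` (resampling out-of-range draws), herbs sampled
#' without replacement within a formula but with preferential reuse across
#' formulas, at least one principal herb per formula, and a 23-column binary
#' attribute table with at least one flag per Siqi/Wuwei/Guijing block. Five
#' anchors are picked as the herbs nearest (Hamming distance) to the
#' five-element attribute archetypes (wood: cool/sour/liver-gallbladder,
#' fire: hot/bitter/heart-small intestine, earth: calm/sweet/spleen-stomach,
#' metal: pungent/lung-large intestine, water: cold/salty/kidney-bladder)
#' and colored with [defaultElementColors()].
#'
#' @param cfg A [simConfig()] list.
#' @return List with `group` ([FormulaGroup-class]), `attributes`
#'   (data.frame as from [readAttributes()]) and `anchors` (data.frame as
#'   from [readAnchors()]).
#' @examples
#' sim <- simulateGroup(simConfig(nFormulas = 5, herbPool = 20, seed = 1))
#' length(sim$group)
#' @export
simulateGroup <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "simConfig"))
  schema <- attributeSchema()
  withSeed(cfg$seed, {
    pool <- sprintf("H%03d", seq_len(cfg$herbPool))
    sdlog <- .sizeSdlog(cfg)
    sizes <- integer(cfg$nFormulas)
    for (i in seq_len(cfg$nFormulas)) {
      repeat {
        s <- round(stats::rlnorm(1, meanlog = log(cfg$sizeMedian), sdlog = sdlog))
        if (s >= cfg$sizeMin && s <= cfg$sizeMax) { sizes[i] <- s; break }
      }
    }
    used <- stats::setNames(numeric(cfg$herbPool), pool)
    formulas <- list()
    for (i in seq_len(cfg$nFormulas)) {
      wts <- 1 + cfg$overlapWeight * used
      herbs <- sample(pool, sizes[i], prob = wts)
      used[herbs] <- used[herbs] + 1
      nP <- min(sample.int(length(cfg$principalProbs), 1L,
                           prob = cfg$principalProbs), sizes[i])
      principal <- herbs[sort(sample.int(sizes[i], nP))]
      formulas[[sprintf("F%02d", i)]] <- list(herbs = herbs, principal = principal)
    }
    group <- new("FormulaGroup", name = sprintf("sim-%d", cfg$seed),
                 formulas = formulas)
    herbsUsed <- herbUniverse(group)
    attr <- matrix(0L, length(herbsUsed), 23,
                   dimnames = list(herbsUsed, schema$columns))
    blocks <- list(siqi = schema$siqi, wuwei = schema$wuwei, guijing = schema$guijing)
    for (h in herbsUsed) {
      for (b in names(blocks)) {
        cols <- blocks[[b]]
        flags <- stats::rbinom(length(cols), 1L, cfg$attrProbs[[b]])
        if (sum(flags) == 0L) flags[sample.int(length(cols), 1L)] <- 1L
        attr[h, cols] <- flags
      }
    }
    attributes <- data.frame(herb = herbsUsed, attr, row.names = NULL,
                             check.names = FALSE)
    anchors <- .pickAnchors(attr, .embedPca(attr))
    list(group = group, attributes = attributes, anchors = anchors)
  })
}

# sdlog tuned so ~99% of the log-normal mass falls within [sizeMin, sizeMax];
# out-of-range draws are resampled.
.sizeSdlog <- function(cfg) {
  span <- min(log(cfg$sizeMax / cfg$sizeMedian),
              log(cfg$sizeMedian / max(cfg$sizeMin - 0.5, 1)))
  max(span / 2.58, 0.05)
}

#' Five-element attribute archetypes
#'
#' Idealized 23-d binary vectors expressing the classical element-property
#' correspondences used to pick representative anchor herbs in synthetic
#' data.
#'
#' @return Integer matrix (5 elements x 23 attributes).
#' @export
elementArchetypes <- function() {
  schema <- attributeSchema()
  arch <- matrix(0L, 5, 23, dimnames = list(
    c("wood", "fire", "earth", "metal", "water"), schema$columns))
  arch["wood", c("cool", "sour", "liver", "gallbladder")] <- 1L
  arch["fire", c("hot", "bitter", "heart", "small_intestine")] <- 1L
  arch["earth", c("calm", "sweet", "spleen", "stomach")] <- 1L
  arch["metal", c("pungent", "lung", "large_intestine")] <- 1L
  arch["water", c("cold", "salty", "kidney", "bladder")] <- 1L
  arch
}

# Representative herbs are identified per element: smallest Hamming distance
# to the element archetype, with near-ties (within one flag flip) resolved
# toward herbs far from already-picked anchors in the 2D map. Experts pick
# representatives by looking at the herb map, so anchors should both express
# the element and span the embedding; spread also keeps the interpolated
# colormap mostly inside the sRGB gamut.
.pickAnchors <- function(attr, pts) {
  arch <- elementArchetypes()
  cols <- defaultElementColors()
  chosen <- character(0)
  out <- data.frame(herb = character(), element = character(), srgb = character())
  for (el in rownames(arch)) {
    dist <- colSums(abs(t(attr) - arch[el, ]))
    dist[chosen] <- Inf
    near <- names(dist)[dist <= min(dist) + 2]
    pick <- if (length(chosen) && length(near) > 1L) {
      spread <- vapply(near, function(h) {
        min(sqrt(rowSums((pts[chosen, , drop = FALSE] -
                            matrix(pts[h, ], length(chosen), 2,
                                   byrow = TRUE))^2)))
      }, numeric(1))
      near[which.max(spread)]
    } else near[1L]
    chosen <- c(chosen, pick)
    out <- rbind(out, data.frame(herb = pick, element = el,
                                 srgb = unname(cols[el])))
  }
  out
}

#' Write a simulated data set to disk
#'
#' Emits `formulas.tsv`, `attributes.tsv` and `anchors.json` in the formats
#' read by [readFormulas()], [readAttributes()] and [readAnchors()].
#'
#' @param sim Result of [simulateGroup()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeSimulated <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFormulas(sim$group, file.path(dir, "formulas.tsv"))
  utils::write.table(sim$attributes, file.path(dir, "attributes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$anchors, file.path(dir, "anchors.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
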