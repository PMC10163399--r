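# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own computation paths.

# All-pairs shared-herb counts by explicit double loop over formulas and
# element-by-element membership tests.
bruteSharedMatrix <- function(group) {
  nms <- formulaNames(group)
  m <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      a <- formulaHerbs(group, nms[i])
      b <- formulaHerbs(group, nms[j])
      cnt <- 0L
      for (h in a) if (any(b == h)) cnt <- cnt + 1L
      m[i, j] <- cnt
    }
  }
  m
}

# All permutations of 1:n (n <= 7 in the tests).
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Exhaustive-enumeration oracle for the greedy similarity sequence: among all
# permutations starting at index t, the greedy chain is the lexicographic
# minimum of the successive-distance vector, with exact distance ties broken
# by the index sequence.
greedyByEnumeration <- function(herbs, d, t) {
  n <- length(herbs)
  if (n == 1L) return(herbs)
  best <- NULL; bestDv <- NULL
  for (perm in allPermutations(n)) {
    p <- unlist(perm)
    if (p[1L] != t) next
    dv <- sapply(seq_len(n - 1L), function(i) d[herbs[p[i]], herbs[p[i + 1L]]])
    if (is.null(best)) { best <- p; bestDv <- dv; next }
    for (i in seq_len(n - 1L)) {
      if (dv[i] < bestDv[i]) { best <- p; bestDv <- dv; break }
      if (dv[i] > bestDv[i]) break
      if (dv[i] == bestDv[i] && i == n - 1L) {
        # full distance tie: prefer smaller index sequence
        for (k in seq_len(n)) {
          if (p[k] < best[k]) { best <- p; bestDv <- dv; break }
          if (p[k] > best[k]) break
        }
      }
    }
  }
  herbs[best]
}

# Small random synthetic group for property suites.
randomSimGroup <- function(i) {
  simulateGroup(simConfig(
    nFormulas = 4L + (i %% 4L), herbPool = 14L + (i %% 8L),
    sizeMin = 2L, sizeMedian = 4, sizeMax = 8L,
    overlapWeight = 1 + (i %% 3L), seed = 1000L + i))
}

# Check all IcicleLayout invariants against its source group; returns a
# character vector of violations (empty = all good).
layoutViolations <- function(layout, group) {
  bad <- character(0)
  cl <- layoutCells(layout)
  pr <- principalRows(layout)
  ord <- formulaOrder(layout)
  if (!setequal(ord, formulaNames(group))) bad <- c(bad, "column set mismatch")
  for (i in seq_along(ord)) {
    nm <- ord[i]
    sub <- cl[cl$formula == nm, ]
    if (!setequal(sub$herb, formulaHerbs(group, nm)) ||
        anyDuplicated(sub$herb)) bad <- c(bad, paste("bijection:", nm))
    np <- sub[!sub$principal, ]
    if (nrow(np) && min(np$row) != pr) {
      # a deeper start is legal only when every nonprincipal herb is
      # row-aligned to the preceding column (exact-row alignment gaps)
      ok <- FALSE
      if (i > 1L) {
        prev <- cl[cl$formula == ord[i - 1L] & !cl$principal, ]
        rowsMatch <- vapply(seq_len(nrow(np)), function(k) {
          j <- which(prev$herb == np$herb[k])
          length(j) == 1L && prev$row[j] == np$row[k]
        }, logical(1))
        ok <- all(rowsMatch)
      }
      if (!ok) bad <- c(bad, paste("nonprincipal top row misaligned:", nm))
    }
    if (any(sub$principal & sub$row >= pr) || any(!sub$principal & sub$row < pr))
      bad <- c(bad, paste("region violation:", nm))
    if (!setequal(sub$herb[sub$principal], principalHerbs(group, nm)))
      bad <- c(bad, paste("principal set mismatch:", nm))
  }
  tl <- topLevel(layout)[ord]
  key <- ifelse(is.na(tl), ".none", tl)
  runs <- rle(key)$values
  if (anyDuplicated(runs)) bad <- c(bad, "top-level groups not contiguous")
  # shared nonprincipal herbs of adjacent columns sit on equal rows
  for (i in seq_len(length(ord) - 1L)) {
    a <- cl[cl$formula == ord[i] & !cl$principal, ]
    b <- cl[cl$formula == ord[i + 1L] & !cl$principal, ]
    shared <- intersect(a$herb, b$herb)
    for (h in shared) {
      if (a$row[a$herb == h] != b$row[b$herb == h])
        bad <- c(bad, paste("shared herb misaligned:", h, "between",
                            ord[i], "and", ord[i + 1L]))
    }
  }
  bad
}

# 3 collinear points at x = 0, 1, 3 (the worked greedy example).
collinearPoints <- function() {
  rbind(p0 = c(0, 0), p1 = c(1, 0), p3 = c(3, 0))
}

toyGroupDf <- function() {
  data.frame(
    formula = c("F1", "F1", "F1", "F2", "F2", "F2"),
    herb = c("A", "B", "C", "B", "C", "D"),
    is_principal = c(1, 0, 0, 1, 0, 0))
}
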