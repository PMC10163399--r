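#' Construct a FormulaGroup
#'
#' @param name Group name.
#' @param formulas Named list of `list(herbs =, principal =)` entries, or a
#'   long-format data.frame with columns `formula`, `herb`, `is_principal`.
#' @return A [FormulaGroup-class] object.
#' @examples
#' g <- FormulaGroup("toy", data.frame(
#'   formula = c("F1", "F1"), herb = c("A", "B"), is_principal = c(1, 0)))
#' formulaNames(g)
#' @export
FormulaGroup <- function(name, formulas) {
  if (is.data.frame(formulas)) formulas <- .formulasFromLong(formulas)
  new("FormulaGroup", name = as.character(name), formulas = formulas)
}

.formulasFromLong <- function(df) {
  stopifnot(all(c("formula", "herb", "is_principal") %in% names(df)))
  key <- paste(df$formula, df$herb, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (formula, herb) row: (%s, %s)", dup$formula, dup$herb))
  }
  flag <- df$is_principal
  if (!all(flag %in% c(0, 1, FALSE, TRUE)))
    stop("is_principal must be 0/1")
  out <- list()
  for (nm in unique(df$formula)) {
    sub <- df[df$formula == nm, , drop = FALSE]
    out[[nm]] <- list(herbs = as.character(sub$herb),
                      principal = as.character(sub$herb[as.logical(sub$is_principal)]))
  }
  out
}

.groupToLong <- function(group) {
  rows <- lapply(formulaNames(group), function(nm) {
    f <- group@formulas[[nm]]
    data.frame(formula = nm, herb = f$herbs,
               is_principal = as.integer(f$herbs %in% f$principal))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname FormulaGroup-class
#' @export
setMethod("groupName", "FormulaGroup", function(object) object@name)

#' @rdname FormulaGroup-class
#' @export
setMethod("formulaNames", "FormulaGroup", function(object) names(object@formulas))

#' @rdname FormulaGroup-class
#' @export
setMethod("formulaHerbs", "FormulaGroup", function(object, formula) {
  if (missing(formula)) return(lapply(object@formulas, `[[`, "herbs"))
  .checkFormula(object, formula)
  object@formulas[[formula]]$herbs
})

#' @rdname FormulaGroup-class
#' @export
setMethod("principalHerbs", "FormulaGroup", function(object, formula) {
  if (missing(formula)) return(lapply(object@formulas, `[[`, "principal"))
  .checkFormula(object, formula)
  object@formulas[[formula]]$principal
})

#' @rdname FormulaGroup-class
#' @export
setMethod("herbUniverse", "FormulaGroup", function(object) {
  unique(unlist(lapply(object@formulas, `[[`, "herbs"), use.names = FALSE))
})

#' @rdname FormulaGroup-class
#' @export
setMethod("length", "FormulaGroup", function(x) length(x@formulas))

.checkFormula <- function(group, formula) {
  if (!formula %in% names(group@formulas))
    stop(sprintf("no formula named '%s' in group '%s'", formula, group@name))
}

setMethod("show", "FormulaGroup", function(object) {
  sizes <- lengths(formulaHerbs(object))
  cat(sprintf("FormulaGroup '%s': %d formulas, %d herbs\n",
              object@name, length(object), length(herbUniverse(object))))
  for (nm in formulaNames(object)) {
    f <- object@formulas[[nm]]
    cat(sprintf("  %-20s %2d herbs (%d principal)\n",
                nm, length(f$herbs), length(f$principal)))
  }
  invisible(NULL)
})

#' @rdname IcicleLayout-class
#' @export
setMethod("layoutCells", "IcicleLayout", function(object) object@cells)

#' @rdname IcicleLayout-class
#' @export
setMethod("principalRows", "IcicleLayout", function(object) object@principalRows)

#' @rdname IcicleLayout-class
#' @export
setMethod("topLevel", "IcicleLayout", function(object) object@topLevel)

#' @rdname IcicleLayout-class
#' @export
setMethod("formulaOrder", "IcicleLayout", function(object) object@formulaOrder)

setMethod("show", "IcicleLayout", function(object) {
  cat(sprintf("IcicleLayout: %d columns, principal region %d row(s), %d cells\n",
              length(object@formulaOrder), object@principalRows, nrow(object@cells)))
  cat("  column order:", paste(object@formulaOrder, collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname SharedHerbMatrix-class
#' @export
setMethod("sharedCounts", "SharedHerbMatrix", function(object) object@counts)

#' @rdname SharedHerbMatrix-class
#' @param x A `SharedHerbMatrix`.
#' @param ... Ignored.
#' @export
setMethod("as.matrix", "SharedHerbMatrix", function(x, ...) x@counts)

setMethod("show", "SharedHerbMatrix", function(object) {
  n <- nrow(object@counts)
  off <- object@counts[upper.tri(object@counts)]
  cat(sprintf("SharedHerbMatrix: %d formulas; off-diagonal max %s\n",
              n, if (length(off)) max(off) else "NA"))
  print(object@counts)
  invisible(NULL)
})

#' @rdname ColorField2D-class
#' @export
setMethod("fieldAnchors", "ColorField2D", function(object) object@anchors)

setMethod("show", "ColorField2D", function(object) {
  cat(sprintf("ColorField2D: %d anchors, %s kernel, bbox [%.3g, %.3g] x [%.3g, %.3g]\n",
              nrow(object@anchors), object@kernel,
              object@bbox[1], object@bbox[2], object@bbox[3], object@bbox[4]))
  print(object@anchors[, c("herb", "element", "srgb")])
  invisible(NULL)
})
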