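#' @rdname FormulaGroup-class
#' @param object,x A `FormulaGroup`.
#' @export
setGeneric("groupName", function(object) standardGeneric("groupName"))

#' @rdname FormulaGroup-class
#' @export
setGeneric("formulaNames", function(object) standardGeneric("formulaNames"))

#' @rdname FormulaGroup-class
#' @param formula Formula name; if missing, values for all formulas.
#' @export
setGeneric("formulaHerbs", function(object, formula) standardGeneric("formulaHerbs"))

#' @rdname FormulaGroup-class
#' @export
setGeneric("principalHerbs", function(object, formula) standardGeneric("principalHerbs"))

#' @rdname FormulaGroup-class
#' @export
setGeneric("herbUniverse", function(object) standardGeneric("herbUniverse"))

#' @rdname IcicleLayout-class
#' @param object An `IcicleLayout`.
#' @export
setGeneric("layoutCells", function(object) standardGeneric("layoutCells"))

#' @rdname IcicleLayout-class
#' @export
setGeneric("principalRows", function(object) standardGeneric("principalRows"))

#' @rdname IcicleLayout-class
#' @export
setGeneric("topLevel", function(object) standardGeneric("topLevel"))

#' @rdname IcicleLayout-class
#' @export
setGeneric("formulaOrder", function(object) standardGeneric("formulaOrder"))

#' @rdname SharedHerbMatrix-class
#' @param object A `SharedHerbMatrix`.
#' @export
setGeneric("sharedCounts", function(object) standardGeneric("sharedCounts"))

#' @rdname ColorField2D-class
#' @param object A `ColorField2D`.
#' @export
setGeneric("fieldAnchors", function(object) standardGeneric("fieldAnchors"))

#' Evaluate a color field at 2D locations
#'
#' Evaluates the fitted per-channel RBF interpolant at arbitrary points of the
#' embedding plane, returning CIECAM02-UCS coordinates.
#'
#' @param object A [ColorField2D-class] object.
#' @param xy Numeric matrix (n x 2) of embedding coordinates (a single point
#'   may be given as a length-2 vector).
#' @return Numeric matrix (n x 3) with columns `Jp`, `ap`, `bp`.
#' @seealso [fitColorField()], [ucsToSrgb()]
#' @export
setGeneric("fieldUcs", function(object, xy) standardGeneric("fieldUcs"))
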