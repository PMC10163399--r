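#' Read a formula table
#'
#' Reads a long-format formula table — one record per (formula, herb) pair
#' with a 0/1 principal-herb flag — into a [FormulaGroup-class]. Herb order
#' within each formula follows file row order; herb matching is exact string
#' equality on the Pinyin id.
#'
#' @param source Path to the file.
#' @param format `"tsv"` (canonical), `"csv"`, or `"json"` (an array of
#'   objects with the same three fields). Guessed from the file extension by
#'   default.
#' @param name Group name; defaults to the file name without extension.
#' @return A [FormulaGroup-class].
#' @examples
#' path <- system.file("extdata", "tonic_formulas.tsv", package = "tcmviz")
#' g <- readFormulas(path, name = "tonic")
#' length(g)
#' @export
readFormulas <- function(source, format = c("auto", "tsv", "csv", "json"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("file not found: ", source)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(source)),
                     json = "json", csv = "csv", "tsv")
  df <- switch(format,
    tsv = utils::read.delim(source, stringsAsFactors = FALSE, sep = "\t"),
    csv = utils::read.csv(source, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(source)))
  need <- c("formula", "herb", "is_principal")
  if (!all(need %in% names(df)))
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  if (nrow(df) == 0L) stop("empty formula table: ", source)
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(source))
  FormulaGroup(name, df)
}

#' Write a formula table
#'
#' Writes the long-format (formula, herb, is_principal) representation; the
#' round trip through [readFormulas()] reproduces the same records.
#'
#' @param group A [FormulaGroup-class].
#' @param path Output file path.
#' @param format `"tsv"`, `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
writeFormulas <- function(group, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  df <- .groupToLong(group)
  switch(format,
    tsv = utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    csv = utils::write.csv(df, path, quote = FALSE, row.names = FALSE),
    json = jsonlite::write_json(df, path, dataframe = "rows"))
  invisible(path)
}

#' The 23-column herb attribute schema
#'
#' Fixed column order of the binary herb-attribute encoding: 5 Siqi property
#' flags, then 7 Wuwei flavor flags, then 11 Guijing meridian flags.
#'
#' @return Named list with character vectors `siqi`, `wuwei`, `guijing` and
#'   the flat 23-element `columns` vector.
#' @examples
#' length(attributeSchema()$columns)
#' @export
attributeSchema <- function() {
  siqi <- c("cold", "hot", "warm", "cool", "calm")
  wuwei <- c("pungent", "sweet", "sour", "bitter", "salty", "tasteless", "astringent")
  guijing <- c("liver", "heart", "spleen", "lung", "kidney", "bladder",
               "large_intestine", "small_intestine", "stomach", "gallbladder",
               "pericardium")
  list(siqi = siqi, wuwei = wuwei, guijing = guijing,
       columns = c(siqi, wuwei, guijing))
}

#' Read a herb-attribute table
#'
#' Reads a table with a `herb` id column followed by the 23 binary attribute
#' columns of [attributeSchema()], in that order.
#'
#' @param source Path to a TSV/CSV file.
#' @return data.frame with column `herb` and the 23 schema columns (integer
#'   0/1).
#' @examples
#' path <- system.file("extdata", "tonic_attributes_synthetic.tsv", package = "tcmviz")
#' head(readAttributes(path))
#' @export
readAttributes <- function(source) {
  if (!file.exists(source)) stop("file not found: ", source)
  sep <- if (tolower(tools::file_ext(source)) == "csv") "," else "\t"
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  schema <- attributeSchema()$columns
  if (!identical(names(df), c("herb", schema)))
    stop(sprintf(
      "attribute schema mismatch: expected 'herb' plus %d columns (%s...), got %d columns",
      length(schema), paste(utils::head(schema, 3), collapse = ", "),
      ncol(df) - 1L))
  if (any(is.na(df$herb)) || any(!nzchar(df$herb)))
    stop("missing herb id in attribute table")
  if (anyDuplicated(df$herb))
    stop("duplicated herb id in attribute table: ",
         paste(unique(df$herb[duplicated(df$herb)]), collapse = ", "))
  for (cn in schema) {
    v <- df[[cn]]
    bad <- which(!(v %in% c(0L, 1L)))
    if (length(bad))
      stop(sprintf("non-binary attribute value at row %d, column '%s': %s",
                   bad[1L], cn, v[bad[1L]]))
    df[[cn]] <- as.integer(v)
  }
  df
}

#' Cross-check a formula group against an attribute table
#'
#' Reports inconsistencies without failing: herbs used in formulas that lack
#' an attribute record (`missing_attribute`, error-level) and formulas with no
#' principal herb (`no_principal`, warning-level; legal, but unusual for TCM
#' formula data where every formula names at least one Junyao).
#'
#' @param group A [FormulaGroup-class].
#' @param attributes data.frame from [readAttributes()].
#' @return data.frame with columns `level` (`"error"`/`"warning"`), `type`,
#'   `item`, `message`; zero rows iff the inputs are fully consistent.
#' @export
validateGroup <- function(group, attributes) {
  stopifnot(is(group, "FormulaGroup"))
  rep <- data.frame(level = character(), type = character(),
                    item = character(), message = character())
  missing <- setdiff(herbUniverse(group), attributes$herb)
  for (h in missing)
    rep <- rbind(rep, data.frame(
      level = "error", type = "missing_attribute", item = h,
      message = sprintf("herb '%s' appears in formulas but has no attribute record", h)))
  for (nm in formulaNames(group))
    if (length(principalHerbs(group, nm)) == 0L)
      rep <- rbind(rep, data.frame(
        level = "warning", type = "no_principal", item = nm,
        message = sprintf("formula '%s' flags no principal herb", nm)))
  rep
}

#' Bundled tonic-formula example data
#'
#' Loads the bundled seven-formula tonic example (Bazhentang,
#' Shenlingbaizhusan, Shengmaisan, Sijunzitang, Dabuyinwan, Siwutang,
#' Dihuangyinzi) together with a hand-built synthetic attribute table for its
#' 31 herbs and a five-element anchor palette. The formula records transcribe
#' a published textbook excerpt; the attribute flags are synthetic (plausible
#' Siqi/Wuwei/Guijing assignments, not database values) and are shipped so the
#' full pipeline runs self-contained.
#'
#' @return List with elements `group` ([FormulaGroup-class]), `attributes`
#'   (data.frame), `anchors` (data.frame with `herb`, `element`, `srgb`).
#' @examples
#' fx <- tonicExample()
#' formulaNames(fx$group)
#' @export
tonicExample <- function() {
  dir <- system.file("extdata", package = "tcmviz")
  list(
    group = readFormulas(file.path(dir, "tonic_formulas.tsv"), name = "tonic"),
    attributes = readAttributes(file.path(dir, "tonic_attributes_synthetic.tsv")),
    anchors = readAnchors(file.path(dir, "tonic_anchors.json")))
}
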