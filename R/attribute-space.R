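#' Encode herb attribute records as binary vectors
#'
#' Flattens Siqi (5), Wuwei (7) and Guijing (11) flags into one binary vector
#' of length M = 23 per herb, in the fixed [attributeSchema()] column order.
#'
#' @param records data.frame from [readAttributes()] (column `herb` plus the
#'   23 schema columns).
#' @return Integer matrix (herbs x 23) with herb ids as row names.
#' @examples
#' fx <- tonicExample()
#' P <- encodeAttributes(fx$attributes)
#' dim(P)
#' @export
encodeAttributes <- function(records) {
  schema <- attributeSchema()$columns
  if (!all(c("herb", schema) %in% names(records)))
    stop("records do not follow the 23-column attribute schema")
  m <- as.matrix(records[, schema])
  if (!all(m %in% c(0L, 1L))) stop("attribute flags must be 0/1")
  storage.mode(m) <- "integer"
  rownames(m) <- records$herb
  m
}

#' Project herb attribute vectors to 2D
#'
#' Reduces the 23-dimensional binary attribute vectors to one 2D point per
#' herb. Two methods are available:
#'
#' * `"pca"` (default): the first two principal axes of the centered binary
#'   matrix, with a fixed sign convention (the loading of largest magnitude on
#'   each axis is made positive), so results are fully deterministic and
#'   library-independent. All layout and color oracle tests use this
#'   projector.
#' * `"umap"`: nonlinear UMAP embedding, delegated to the `umap-learn` Python
#'   package through a `python` subprocess (`random_state = seed`, single
#'   threaded). Deterministic for a fixed environment and seed; requires
#'   `python` with `umap-learn` on the `PATH`.
#'
#' @param vectors Integer/numeric matrix (herbs x 23) from
#'   [encodeAttributes()]; row names are herb ids.
#' @param method `"pca"` or `"umap"`.
#' @param seed Integer seed (used by `"umap"`; `"pca"` is seed-free but the
#'   argument is accepted for a uniform interface).
#' @param nNeighbors,minDist UMAP hyperparameters (defaults 5 and 0.3, chosen
#'   for groups of roughly 30-75 herbs).
#' @return Numeric matrix (herbs x 2), row names herb ids, columns `x`, `y`.
#' @examples
#' fx <- tonicExample()
#' pts <- embedHerbs(encodeAttributes(fx$attributes))
#' head(pts)
#' @export
embedHerbs <- function(vectors, method = c("pca", "umap"), seed = 42L,
                       nNeighbors = 5L, minDist = 0.3) {
  method <- match.arg(method)
  if (is.null(rownames(vectors))) stop("'vectors' must have herb ids as row names")
  n <- nrow(vectors)
  if (n < 2L || nrow(unique(vectors)) < 2L)
    stop("need at least 2 distinct attribute vectors to embed")
  pts <- switch(method,
    pca = .embedPca(vectors),
    umap = .embedUmap(vectors, seed, nNeighbors, minDist))
  dimnames(pts) <- list(rownames(vectors), c("x", "y"))
  stopifnot(all(is.finite(pts)))
  pts
}

.embedPca <- function(vectors) {
  x <- scale(vectors, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 0, nv = 2)
  v <- sv$v
  if (ncol(v) < 2L) v <- cbind(v, 0)[, 1:2]  # rank-1 input: flat second axis
  # sign convention: dominant loading positive on each axis
  for (j in 1:2) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  x %*% v
}

.embedUmap <- function(vectors, seed, nNeighbors, minDist) {
  n <- nrow(vectors)
  if (n < 3L)
    stop("too few herbs for the nonlinear method; use method = \"pca\"")
  python <- Sys.which("python")
  if (python == "")
    stop("no 'python' on PATH; use method = \"pca\"")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(vectors, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np",
    "import umap",
    "X = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "nn = min(int(sys.argv[3]), X.shape[0] - 1)",
    "e = umap.UMAP(n_neighbors=nn, min_dist=float(sys.argv[4]),",
    "              random_state=int(sys.argv[5]), n_jobs=1).fit_transform(X)",
    "np.savetxt(sys.argv[2], e, delimiter=',')",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(script), shQuote(fin), shQuote(fout),
                              nNeighbors, minDist, as.integer(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout))
    stop("umap-learn subprocess failed; use method = \"pca\"")
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Pairwise Euclidean distances between embedded herbs
#'
#' Distance between two herbs is the L2 norm of the difference of their 2D
#' embedded coordinates (distances are computed on the projection, not on the
#' raw 23-dimensional vectors).
#'
#' @param points Numeric matrix (herbs x 2) from [embedHerbs()].
#' @return Symmetric numeric matrix with herb ids as dimnames and zero
#'   diagonal.
#' @examples
#' pairwiseDistance(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"]  # 5
#' @export
pairwiseDistance <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, all(is.finite(points)))
  d <- as.matrix(stats::dist(points, method = "euclidean"))
  dimnames(d) <- list(rownames(points), rownames(points))
  d
}
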