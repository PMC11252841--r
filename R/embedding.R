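# Low-dimensional embeddings of the cells: PCA, UMAP, or a user-supplied
# precomputed coordinate matrix, plus axis selection for plotting.

#' Principal component analysis of the count matrix
#'
#' Computes principal components of the column-mean-centered (optionally
#' unit-variance-scaled) cells x genes matrix, ordered by decreasing
#' explained variance. Exactly one of `nComponents` and `varianceFraction`
#' must be given: either a fixed number of components, or the smallest
#' number whose cumulative explained-variance fraction reaches the target
#' (with a floor of 2 components so plots remain drawable).
#'
#' No transformation is applied beyond centering/scaling: PCA runs on
#' whatever values were loaded, and any log-transformation is the caller's
#' responsibility.
#'
#' Component signs are fixed deterministically: each component is flipped so
#' that its largest-absolute gene loading is positive.
#'
#' @param cm a [CountMatrix-class].
#' @param nComponents number of components to return (>= 2,
#'   <= min(cells, genes)).
#' @param varianceFraction target cumulative explained-variance fraction in
#'   (0, 1].
#' @param scale logical; also scale genes to unit variance (default FALSE,
#'   centering only).
#' @return an [Embedding-class] with `method = "pca"`; `embeddingMeta()`
#'   carries `varianceFractions` (per returned component),
#'   `cumulativeVariance`, and `allVarianceFractions` over every computed
#'   component.
#' @export
computePCA <- function(cm, nComponents = NULL, varianceFraction = NULL,
                       scale = FALSE) {
  x <- exprValues(cm)
  if (nrow(x) < 2L)
    scStop("InsufficientDataError", "PCA needs at least 2 cells")
  if (is.null(nComponents) == is.null(varianceFraction))
    scStop("ParameterError",
           "give exactly one of nComponents or varianceFraction")
  if (!is.null(nComponents)) {
    nComponents <- assertCount(nComponents, "nComponents", min = 2L)
    if (nComponents > min(dim(x)))
      scStop("ParameterError", "nComponents exceeds min(cells, genes)")
  } else {
    if (!is.numeric(varianceFraction) || length(varianceFraction) != 1L ||
        is.na(varianceFraction) || varianceFraction <= 0 ||
        varianceFraction > 1)
      scStop("ParameterError", "varianceFraction must lie in (0, 1]")
  }
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    constant <- sds == 0
    if (any(constant)) x[, constant] <- 0   # constant genes carry no signal
    sds[constant] <- 1
    pc <- stats::prcomp(x, center = TRUE, scale. = sds)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  }
  vars <- pc$sdev^2
  fractions <- if (sum(vars) > 0) vars / sum(vars) else rep(0, length(vars))
  k <- if (!is.null(nComponents)) min(nComponents, ncol(pc$x)) else {
    max(2L, which(cumsum(fractions) >= varianceFraction - 1e-12)[1L])
  }
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-absolute loading of each component is positive
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  new("Embedding", cellIds = cellIds(cm), coords = unname(scores) ,
      method = "pca",
      meta = list(varianceFractions = fractions[seq_len(k)],
                  cumulativeVariance = sum(fractions[seq_len(k)]),
                  allVarianceFractions = fractions,
                  scaled = scale))
}

#' UMAP embedding of the cells
#'
#' Nonlinear neighbor-graph embedding into 2 or 3 dimensions. The same seed
#' with the same input yields identical coordinates (the layout is run
#' single-threaded for exact reproducibility).
#'
#' @param cm a [CountMatrix-class] with at least 4 cells.
#' @param dims output dimensionality, 2 or 3.
#' @param nNeighbors number of neighbors considered (>= 2, < number of
#'   cells).
#' @param seed integer RNG seed, recorded in `embeddingMeta()`.
#' @return an [Embedding-class] with `method = "umap"`.
#' @export
computeUMAP <- function(cm, dims = 2L, nNeighbors = 15L, seed = 42L) {
  x <- exprValues(cm)
  if (!dims %in% c(2L, 3L))
    scStop("ParameterError", "dims must be 2 or 3")
  if (nrow(x) < 4L)
    scStop("InsufficientDataError", "UMAP needs at least 4 cells")
  nNeighbors <- assertCount(nNeighbors, "nNeighbors", min = 2L)
  if (nNeighbors >= nrow(x))
    scStop("ParameterError", "nNeighbors must be smaller than the number of cells")
  seed <- assertCount(seed, "seed", min = 0L)
  set.seed(seed)
  coords <- uwot::umap(x, n_neighbors = nNeighbors, n_components = dims,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  dimnames(coords) <- NULL
  new("Embedding", cellIds = cellIds(cm), coords = coords, method = "umap",
      meta = list(nNeighbors = nNeighbors, dims = as.integer(dims),
                  seed = seed))
}

#' Load a precomputed coordinate matrix
#'
#' Reads a user-supplied CSV whose first column holds cell identifiers and
#' whose remaining (>= 2) columns hold coordinates. The cell-id set must
#' match the count matrix exactly; rows are reordered to the matrix's cell
#' order.
#'
#' @param path path to the CSV.
#' @param cm the [CountMatrix-class] the coordinates belong to.
#' @return an [Embedding-class] with `method = "precomputed"`.
#' @export
loadPrecomputedEmbedding <- function(path, cm) {
  df <- readRawTable(path, "csv")
  if (ncol(df) - 1L < 2L)
    scStop("DimensionError",
           "a precomputed coordinate matrix must have at least two dimensions")
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids))
    scStop("DuplicateIdError", "duplicate cell ids in coordinate file")
  want <- cellIds(cm)
  if (!setequal(ids, want))
    scStop("IdMismatchError", sprintf(
      "coordinate file cells do not match the count matrix (missing: %s; extra: %s)",
      paste(utils::head(setdiff(want, ids), 5), collapse = ", "),
      paste(utils::head(setdiff(ids, want), 5), collapse = ", ")))
  coords <- matrix(NA_real_, nrow = length(ids), ncol = ncol(df) - 1L)
  for (j in seq_len(ncol(coords))) {
    num <- suppressWarnings(as.numeric(trimws(df[[j + 1L]])))
    if (anyNA(num))
      scStop("ParseError", sprintf("non-numeric coordinate in column %d", j + 1L))
    coords[, j] <- num
  }
  coords <- coords[match(want, ids), , drop = FALSE]
  new("Embedding", cellIds = want, coords = coords, method = "precomputed",
      meta = list(source = path))
}

#' Restrict an embedding to chosen axes
#'
#' Selects 2 or 3 components of an embedding as plot axes, in the given
#' order — e.g. `axes = c(3, 1)` plots component 3 on x and component 1 on
#' y. Indices are 1-based, must be distinct and within the embedding's
#' dimensionality. Method metadata is preserved and the selection recorded.
#'
#' @param emb an [Embedding-class].
#' @param axes integer vector of length 2 or 3.
#' @return an [Embedding-class] restricted to the chosen components.
#' @export
selectAxes <- function(emb, axes) {
  axes <- as.integer(axes)
  d <- ncol(coordValues(emb))
  if (!length(axes) %in% c(2L, 3L))
    scStop("ParameterError", "select 2 or 3 axes")
  if (anyDuplicated(axes))
    scStop("ParameterError", "axis indices must be distinct")
  if (any(axes < 1L | axes > d))
    scStop("ParameterError", sprintf(
      "axis index out of range 1..%d", d))
  meta <- embeddingMeta(emb)
  meta$axes <- axes
  new("Embedding", cellIds = cellIds(emb),
      coords = coordValues(emb)[, axes, drop = FALSE],
      method = embeddingMethod(emb), meta = meta)
}
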