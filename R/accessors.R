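#' Accessors for the core data classes
#'
#' `cellIds()` and `geneIds()` return the ordered identifier vectors;
#' `exprValues()` the dense cells x genes matrix; `coordValues()` the
#' embedding coordinate matrix; `embeddingMethod()` and `embeddingMeta()`
#' its provenance; `categoryNames()` / `groupNames()` the metadata column
#' names of a [GeneAnnotation-class] or [PhenoData-class].
#'
#' @param x a scRadial object.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("coordValues", function(x) standardGeneric("coordValues"))
#' @rdname accessors
#' @export
setGeneric("embeddingMethod", function(x) standardGeneric("embeddingMethod"))
#' @rdname accessors
#' @export
setGeneric("embeddingMeta", function(x) standardGeneric("embeddingMeta"))
#' @rdname accessors
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))
#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname accessors
setMethod("cellIds", "CountMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "CountMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("exprValues", "CountMatrix", function(x) x@values)
#' @rdname accessors
setMethod("cellIds", "PhenoData", function(x) x@cellIds)
#' @rdname accessors
setMethod("cellIds", "Embedding", function(x) x@cellIds)
#' @rdname accessors
setMethod("geneIds", "GeneAnnotation", function(x) x@geneIds)
#' @rdname accessors
setMethod("geneIds", "FoldChangeResult", function(x) x@geneIds)
#' @rdname accessors
setMethod("coordValues", "Embedding", function(x) x@coords)
#' @rdname accessors
setMethod("embeddingMethod", "Embedding", function(x) x@method)
#' @rdname accessors
setMethod("embeddingMeta", "Embedding", function(x) x@meta)
#' @rdname accessors
setMethod("categoryNames", "GeneAnnotation", function(x) names(x@categories))
#' @rdname accessors
setMethod("categoryNames", "PhenoData", function(x) names(x@categories))
#' @rdname accessors
setMethod("groupNames", "GeneAnnotation", function(x) names(x@groups))

#' Per-gene expression vector of one cell
#'
#' Returns the named expression vector of a single cell (one row of the
#' count matrix), suitable for [computeLog2FC()] or [buildRadialChart()].
#' A [Metacell-class] is accepted anywhere such a vector is, via
#' [metacellExpr()].
#'
#' @param cm a [CountMatrix-class].
#' @param cellId a cell identifier present in `cm`.
#' @return named numeric vector over the matrix genes, in matrix order.
#' @export
cellExpr <- function(cm, cellId) {
  assertString(cellId, "cellId")
  if (!cellId %in% cellIds(cm))
    scStop("UnknownIdError", sprintf("unknown cell id '%s'", cellId))
  cm@values[cellId, ]
}

#' @rdname cellExpr
#' @param mc a [Metacell-class].
#' @export
metacellExpr <- function(mc) mc@expr

#' Fold-change values as a named vector
#' @param fc a [FoldChangeResult-class].
#' @return named numeric vector of log2 fold changes.
#' @export
log2fcValues <- function(fc) stats::setNames(fc@log2fc, fc@geneIds)

#' Colors of a ColorMap as a named vector
#' @param cmap a [ColorMap-class].
#' @return named character vector of hex colors (`NA` = uncolored).
#' @export
colorValues <- function(cmap) stats::setNames(cmap@colors, cmap@entityIds)

#' Intensities of a ColorMap as a named vector
#' @param cmap a [ColorMap-class].
#' @return named numeric vector of normalized intensities.
#' @export
intensityValues <- function(cmap) stats::setNames(cmap@intensities, cmap@entityIds)

#' Findings of a ValidationReport
#' @param report a [ValidationReport-class].
#' @return logical (`reportOk`) or a data.frame of `code`/`message` rows.
#' @export
reportOk <- function(report) report@ok
#' @rdname reportOk
#' @export
reportErrors <- function(report) report@errors
#' @rdname reportOk
#' @export
reportWarnings <- function(report) report@warnings

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d cells x %d genes\n",
              nrow(object@values), ncol(object@values)))
  cat("  cells:", paste(utils::head(cellIds(object), 3), collapse = ", "),
      if (nrow(object@values) > 3) "..." else "", "\n")
  cat("  genes:", paste(utils::head(geneIds(object), 3), collapse = ", "),
      if (ncol(object@values) > 3) "..." else "", "\n")
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes\n", length(object@geneIds)))
  cat("  categories:", paste(names(object@categories), collapse = ", "), "\n")
  cat("  groups:", paste(names(object@groups), collapse = ", "), "\n")
})

setMethod("show", "PhenoData", function(object) {
  cat(sprintf("PhenoData: %d cells\n", length(object@cellIds)))
  cat("  categories:", paste(names(object@categories), collapse = ", "), "\n")
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding (%s): %d cells x %d dims\n", object@method,
              nrow(object@coords), ncol(object@coords)))
  if (object@method == "pca")
    cat("  variance fractions:",
        paste(sprintf("%.3f", object@meta$varianceFractions), collapse = " "), "\n")
})

setMethod("show", "Metacell", function(object) {
  cat(sprintf("Metacell '%s' (%s of %d cells, category '%s'), %d genes\n",
              object@label, object@method, object@nCells,
              object@sourceCategory, length(object@expr)))
})

setMethod("show", "FoldChangeResult", function(object) {
  cat(sprintf("FoldChangeResult: %s over %s, %d genes, pseudocount %g\n",
              object@aLabel, object@bLabel, length(object@geneIds),
              object@pseudocount))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d errors, %d warnings)\n",
              if (object@ok) "OK" else "FAILED",
              nrow(object@errors), nrow(object@warnings)))
  if (nrow(object@errors))
    cat(paste0("  error [", object@errors$code, "] ",
               object@errors$message, collapse = "\n"), "\n")
  if (nrow(object@warnings))
    cat(paste0("  warning [", object@warnings$code, "] ",
               object@warnings$message, collapse = "\n"), "\n")
})

setMethod("show", "FilterChain", function(object) {
  cat(sprintf("FilterChain with %d step(s)\n", length(object@steps)))
  for (s in object@steps) cat("  -", s$kind, "\n")
})

setMethod("show", "ColorMap", function(object) {
  cat(sprintf("ColorMap (%s) over %d entities\n", object@kind,
              length(object@entityIds)))
})

setMethod("show", "RadialChartSpec", function(object) {
  cat(sprintf("RadialChartSpec for '%s': %d bars, %d chords\n",
              object@entityLabel, length(object@geneIds), nrow(object@chords)))
})
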