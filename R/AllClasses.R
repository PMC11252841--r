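#' @import methods
NULL

#' CountMatrix: cells-by-genes expression values
#'
#' Dense numeric matrix of counts (or any numeric expression values) with
#' cells as rows and genes as columns. Row names are unique cell identifiers,
#' column names unique gene identifiers; all values must be finite.
#'
#' @slot values numeric matrix, cells x genes, with dimnames.
#' @seealso [loadCountMatrix()], [cellIds()], [geneIds()], [exprValues()]
#' @export
setClass("CountMatrix", representation(values = "matrix"))

setValidity("CountMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  cn <- colnames(v); rn <- rownames(v)
  if (is.null(rn) || is.null(cn)) return("values must have cell and gene ids as dimnames")
  if (anyDuplicated(rn)) return("duplicate cell ids")
  if (anyDuplicated(cn)) return("duplicate gene ids")
  if (length(v) && any(!is.finite(v))) return("all values must be finite")
  TRUE
})

#' GeneAnnotation: per-gene metadata
#'
#' Per-gene locus tags, genomic coordinates, list-valued metadata categories
#' (GO terms, KEGG pathways, COG categories, ...) and binary gene-group
#' memberships imported from `G_`-prefixed columns.
#'
#' @slot geneIds character, unique locus tags (`Locus_Tag` column).
#' @slot start integer, 1-based gene start (bp); `NA` when absent.
#' @slot end integer, 1-based inclusive gene end (bp); `NA` when absent.
#' @slot categories named list; each element a list (one per gene) of
#'   character vectors, produced by comma-splitting the source cell.
#' @slot groups named list of logical vectors (one per gene); each group
#'   originated from a source column `G_<name>` with entries in `{1, blank}`.
#' @slot columnOrder character, original non-`Locus_Tag` column names in
#'   source order, used to reproduce the file layout on export.
#' @seealso [loadGeneAnnotation()], [exportGeneAnnotation()]
#' @export
setClass("GeneAnnotation", representation(
  geneIds = "character", start = "integer", end = "integer",
  categories = "list", groups = "list", columnOrder = "character"))

setValidity("GeneAnnotation", function(object) {
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds)) return("duplicate gene ids")
  if (length(object@start) != n || length(object@end) != n)
    return("start/end length must match geneIds")
  both <- !is.na(object@start) & !is.na(object@end)
  if (any(object@start[both] > object@end[both]))
    return("start must be <= end for every gene")
  for (nm in names(object@categories)) {
    cl <- object@categories[[nm]]
    if (length(cl) != n) return(sprintf("category '%s' has wrong length", nm))
    if (!all(vapply(cl, is.character, logical(1))))
      return(sprintf("category '%s' must hold character vectors", nm))
  }
  for (nm in names(object@groups)) {
    g <- object@groups[[nm]]
    if (!is.logical(g) || length(g) != n || anyNA(g))
      return(sprintf("group '%s' must be logical of gene length", nm))
  }
  TRUE
})

#' PhenoData: per-cell metadata
#'
#' Per-cell labels: experimental conditions, time points, batches or
#' precomputed clusters, one string label per cell and category (blank cells
#' become the empty string).
#'
#' @slot cellIds character, unique cell identifiers.
#' @slot categories named list of character vectors, one label per cell.
#' @seealso [loadPhenoData()], [exportPhenoData()], [paintGroups()]
#' @export
setClass("PhenoData", representation(cellIds = "character", categories = "list"))

setValidity("PhenoData", function(object) {
  n <- length(object@cellIds)
  if (anyDuplicated(object@cellIds)) return("duplicate cell ids")
  for (nm in names(object@categories)) {
    v <- object@categories[[nm]]
    if (!is.character(v) || length(v) != n || anyNA(v))
      return(sprintf("category '%s' must be character of cell length, no NA", nm))
  }
  TRUE
})

#' ValidationReport: cross-file consistency findings
#'
#' @slot ok logical; `TRUE` iff `errors` is empty.
#' @slot errors data.frame with columns `code`, `message`.
#' @slot warnings data.frame with columns `code`, `message`.
#' @seealso [validateDataset()]
#' @export
setClass("ValidationReport", representation(
  ok = "logical", errors = "data.frame", warnings = "data.frame"))

setValidity("ValidationReport", function(object) {
  if (!identical(object@ok, nrow(object@errors) == 0L))
    return("ok must be TRUE iff errors is empty")
  TRUE
})

#' Embedding: low-dimensional cell coordinates
#'
#' Cells-by-d coordinate matrix (d >= 2) produced by PCA, UMAP or loaded
#' from a user-supplied precomputed file, with method provenance in `meta`
#' (per-component explained-variance fractions for PCA; `n_neighbors`,
#' output dims and seed for UMAP).
#'
#' @slot cellIds character, unique cell identifiers (row order of `coords`).
#' @slot coords numeric matrix, cells x d.
#' @slot method one of `"pca"`, `"umap"`, `"precomputed"`.
#' @slot meta named list of method parameters/provenance.
#' @seealso [computePCA()], [computeUMAP()], [loadPrecomputedEmbedding()],
#'   [selectAxes()], [exportEmbedding()]
#' @export
setClass("Embedding", representation(
  cellIds = "character", coords = "matrix", method = "character",
  meta = "list"))

setValidity("Embedding", function(object) {
  if (ncol(object@coords) < 2L) return("embedding must have at least two dimensions")
  if (nrow(object@coords) != length(object@cellIds))
    return("coords rows must correspond one-to-one with cellIds")
  if (anyDuplicated(object@cellIds)) return("duplicate cell ids")
  if (!object@method %in% c("pca", "umap", "precomputed"))
    return("method must be pca, umap or precomputed")
  if (object@method == "pca") {
    vf <- object@meta$varianceFractions
    if (is.null(vf) || any(vf < 0) || sum(vf) > 1 + 1e-9)
      return("pca variance fractions must be non-negative and sum to <= 1")
  }
  TRUE
})

#' FilterChain: ordered sequence of gene-filter specifications
#'
#' Each step is a [filterSpec()] list; an empty chain is the identity filter.
#' Steps are applied left-to-right by [applyChain()], each narrowing the
#' current gene list.
#'
#' @slot steps list of filter specs.
#' @seealso [filterSpec()], [applyChain()], [filterChainToJSON()]
#' @export
setClass("FilterChain", representation(steps = "list"))

setValidity("FilterChain", function(object) {
  kinds <- c("top_expressed", "top_differential", "genomic_region",
             "metadata_category", "gene_group", "custom_set")
  for (s in object@steps) {
    if (!is.list(s) || is.null(s$kind) || !s$kind %in% kinds)
      return("every step must be a filterSpec() with a known kind")
  }
  TRUE
})

#' Metacell: aggregated expression profile of a cell cluster
#'
#' The mean or median expression of every gene over all cells carrying a
#' given label in a phenotype category. A Metacell can be used anywhere a
#' single cell's expression vector is accepted (fold changes, radial charts).
#'
#' @slot label the cluster value string.
#' @slot sourceCategory the phenotype column the label came from.
#' @slot method `"mean"` or `"median"`.
#' @slot expr named numeric, aggregated per-gene expression.
#' @slot cellIds the member cell identifiers.
#' @slot nCells number of member cells (>= 1).
#' @seealso [computeMetacell()], [computeLog2FC()], [metacellPosition()]
#' @export
setClass("Metacell", representation(
  label = "character", sourceCategory = "character", method = "character",
  expr = "numeric", cellIds = "character", nCells = "integer"))

setValidity("Metacell", function(object) {
  if (object@nCells < 1L) return("nCells must be >= 1")
  if (length(object@cellIds) != object@nCells)
    return("nCells must equal the number of member cell ids")
  if (!object@method %in% c("mean", "median")) return("method must be mean or median")
  if (is.null(names(object@expr))) return("expr must be named by gene id")
  TRUE
})

#' FoldChangeResult: per-gene log2 fold change between two profiles
#'
#' @slot geneIds ordered gene identifiers.
#' @slot log2fc per-gene log2 fold change of a over b.
#' @slot aLabel,bLabel identifiers of the compared cells/metacells.
#' @slot pseudocount the non-negative stabilizer added to both sides.
#' @seealso [computeLog2FC()], [filterTopDifferential()]
#' @export
setClass("FoldChangeResult", representation(
  geneIds = "character", log2fc = "numeric", aLabel = "character",
  bLabel = "character", pseudocount = "numeric"))

setValidity("FoldChangeResult", function(object) {
  if (length(object@log2fc) != length(object@geneIds))
    return("log2fc length must match geneIds")
  if (object@pseudocount > 0 && any(!is.finite(object@log2fc)))
    return("log2fc must be finite when pseudocount > 0")
  TRUE
})

#' ColorMap: per-entity colors for cells or genes
#'
#' Either a continuous expression heat ramp (black at zero to full red at the
#' per-gene maximum, intensities in `[0, 1]`) or a deterministic categorical
#' palette assignment. `NA` colors mean "uncolored"; renderers substitute the
#' neutral color.
#'
#' @slot entityIds cell or gene identifiers.
#' @slot colors hex color per entity; `NA` = uncolored.
#' @slot intensities normalized `[0,1]` intensities (expression maps) or `NA`.
#' @slot values assigned category value per entity (categorical maps) or `NA`.
#' @slot kind one of `"expression"`, `"category"`, `"shared_category"`.
#' @slot selected the selected entity for shared-category maps, else `NA`.
#' @seealso [colorByExpression()], [colorByCategory()],
#'   [sharedCategoryColoring()]
#' @export
setClass("ColorMap", representation(
  entityIds = "character", colors = "character", intensities = "numeric",
  values = "character", kind = "character", selected = "character"))

setValidity("ColorMap", function(object) {
  n <- length(object@entityIds)
  if (length(object@colors) != n || length(object@intensities) != n ||
      length(object@values) != n)
    return("colors, intensities and values must match entityIds in length")
  ii <- object@intensities[!is.na(object@intensities)]
  if (length(ii) && (any(ii < 0) || any(ii > 1)))
    return("intensities must lie in [0, 1]")
  TRUE
})

#' RadialChartSpec: layout of a radial gene-expression chart
#'
#' One bar per displayed gene, in descending expression order, equal angular
#' widths tiling at most 2*pi starting at 12 o'clock and proceeding
#' clockwise. Bar height is expression normalized by the per-chart maximum.
#' Chords connect the selected gene to genes sharing a metadata value with
#' it, styled by the shared value's color.
#'
#' @slot entityLabel the cell or metacell the chart describes.
#' @slot geneIds displayed genes in bar order.
#' @slot expr expression value per bar.
#' @slot heights normalized bar heights in `[0, 1]`.
#' @slot startAngles,endAngles bar angular spans in radians, clockwise from
#'   12 o'clock.
#' @slot colors bar fill colors (hex).
#' @slot chords data.frame `from`, `to`, `color`: unordered gene pairs
#'   linked by a shared category value.
#' @slot innerRadius,outerRadius drawing radii.
#' @seealso [buildRadialChart()], [exportSVG()], [exportPNG()]
#' @export
setClass("RadialChartSpec", representation(
  entityLabel = "character", geneIds = "character", expr = "numeric",
  heights = "numeric", startAngles = "numeric", endAngles = "numeric",
  colors = "character", chords = "data.frame", innerRadius = "numeric",
  outerRadius = "numeric"))

setValidity("RadialChartSpec", function(object) {
  n <- length(object@geneIds)
  if (n == 0L) return("chart must have at least one bar")
  if (any(lengths(list(object@expr, object@heights, object@startAngles,
                       object@endAngles, object@colors)) != n))
    return("per-bar slots must all match geneIds in length")
  if (any(object@heights < 0 | object@heights > 1 + 1e-12))
    return("heights must lie in [0, 1]")
  if (max(object@endAngles) > 2 * pi + 1e-9)
    return("bars must tile at most 2*pi")
  TRUE
})

#' FoldChangeChartSpec: layout of a signed fold-change bar chart
#'
#' @slot geneIds displayed genes in order.
#' @slot log2fc signed log2 fold-change values.
#' @slot lengths bar lengths, `|log2fc|` normalized by the displayed maximum.
#' @slot colors color by sign (up/down/zero).
#' @seealso [buildFoldChangeChart()]
#' @export
setClass("FoldChangeChartSpec", representation(
  geneIds = "character", log2fc = "numeric", lengths = "numeric",
  colors = "character"))

setValidity("FoldChangeChartSpec", function(object) {
  n <- length(object@geneIds)
  if (length(object@log2fc) != n || length(object@lengths) != n ||
      length(object@colors) != n)
    return("per-bar slots must match geneIds in length")
  TRUE
})

#' ScatterSpec: layout of a 2D/3D embedding scatter plot
#'
#' One point per cell at the selected embedding coordinates, plus optional
#' metacell points flagged for distinct rendering.
#'
#' @slot pointIds cell (or metacell) identifiers, cells first.
#' @slot coords numeric matrix, points x 2 or 3.
#' @slot colors hex color per point.
#' @slot isMetacell logical flag per point.
#' @seealso [buildScatter()]
#' @export
setClass("ScatterSpec", representation(
  pointIds = "character", coords = "matrix", colors = "character",
  isMetacell = "logical"))

setValidity("ScatterSpec", function(object) {
  n <- length(object@pointIds)
  if (nrow(object@coords) != n || length(object@colors) != n ||
      length(object@isMetacell) != n)
    return("coords, colors and isMetacell must match pointIds")
  if (!ncol(object@coords) %in% c(2L, 3L))
    return("scatter coordinates must be 2D or 3D")
  TRUE
})
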