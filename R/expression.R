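# Metacell aggregation, log2 fold change, gene-metadata queries, and
# cell/gene coloring. A metacell is the mean or median per-gene expression
# over all cells carrying a given label, and can be used anywhere a single
# cell's expression vector is accepted.

# Fixed 16-color categorical cycle, keyed by sorted labels; wraps with a
# warning past 16. Determinism is prioritized over aesthetics.
PALETTE16 <- c(
  "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
  "#A65628", "#F781BF", "#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3",
  "#A6D854", "#FFD92F", "#E5C494", "#B3B3B3")

paletteFor <- function(n) {
  if (n > length(PALETTE16))
    warning(sprintf("%d categories exceed the 16-color palette; colors repeat",
                    n), call. = FALSE)
  PALETTE16[((seq_len(n) - 1L) %% length(PALETTE16)) + 1L]
}

#' Aggregate a cell cluster into a metacell
#'
#' Computes the mean or median expression of every gene over all cells
#' whose label in a phenotype category equals `value` — e.g. all cells of
#' one time point, growth condition or painted cluster.
#'
#' @param cm a [CountMatrix-class].
#' @param pd a [PhenoData-class] over (at least) the matrix cells.
#' @param category a phenotype category name.
#' @param value the cluster label selecting the member cells.
#' @param method `"mean"` or `"median"`; the median of an even-sized
#'   cluster is the midpoint of the two central values.
#' @return a [Metacell-class].
#' @export
computeMetacell <- function(cm, pd, category, value,
                            method = c("mean", "median")) {
  method <- match.arg(method)
  assertString(category, "category"); assertString(value, "value")
  if (!category %in% names(pd@categories))
    scStop("UnknownCategoryError", sprintf("unknown category '%s'", category))
  labels <- stats::setNames(pd@categories[[category]], cellIds(pd))
  members <- intersect(cellIds(cm), names(labels)[labels == value])
  if (length(members) == 0L)
    scStop("EmptyClusterError", sprintf(
      "no cell has value '%s' in category '%s'", value, category))
  sub <- exprValues(cm)[members, , drop = FALSE]
  expr <- if (method == "mean") colMeans(sub)
          else apply(sub, 2L, stats::median)
  new("Metacell", label = value, sourceCategory = category, method = method,
      expr = expr, cellIds = members, nCells = length(members))
}

asExprVector <- function(x, what) {
  if (methods::is(x, "Metacell")) return(metacellExpr(x))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  scStop("ParameterError", sprintf(
    "'%s' must be a Metacell or a named numeric expression vector", what))
}

exprLabel <- function(x, default) {
  if (methods::is(x, "Metacell"))
    sprintf("%s:%s (%s)", x@sourceCategory, x@label, x@method)
  else default
}

#' Log2 fold change between two expression profiles
#'
#' Computes `log2((a + pseudocount) / (b + pseudocount))` per gene, for two
#' cells, two metacells, or any mix. The sign follows a-over-b. The
#' pseudocount stabilizes zeros (ubiquitous in scRNA-seq counts) and is
#' applied symmetrically to numerator and denominator; with
#' `pseudocount = 0`, any zero entry raises an error rather than producing
#' infinities. Fold change here is a heuristic screen for differential
#' expression, not a statistical test.
#'
#' @param a,b [Metacell-class] objects or named numeric vectors over the
#'   same ordered gene set (e.g. from [cellExpr()]).
#' @param pseudocount non-negative stabilizer, default 1.
#' @param aLabel,bLabel labels recorded in the result (defaults: metacell
#'   labels or `"a"`/`"b"`).
#' @return a [FoldChangeResult-class].
#' @export
computeLog2FC <- function(a, b, pseudocount = 1, aLabel = NULL, bLabel = NULL) {
  av <- asExprVector(a, "a"); bv <- asExprVector(b, "b")
  if (!identical(names(av), names(bv)))
    scStop("ParameterError", "a and b must cover the same ordered gene set")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    scStop("ParameterError", "pseudocount must be a non-negative number")
  if (pseudocount == 0 && (any(av == 0) || any(bv == 0)))
    scStop("ZeroDivisionPolicyError",
           "zero entries require a positive pseudocount")
  fc <- log2((av + pseudocount) / (bv + pseudocount))
  new("FoldChangeResult", geneIds = names(av), log2fc = unname(fc),
      aLabel = if (is.null(aLabel)) exprLabel(a, "a") else aLabel,
      bLabel = if (is.null(bLabel)) exprLabel(b, "b") else bLabel,
      pseudocount = pseudocount)
}

#' All annotation data of one gene
#'
#' The programmatic counterpart of a metadata-inspector query: every
#' category list, the genomic coordinates, and every group membership for
#' the gene.
#'
#' @param ga a [GeneAnnotation-class].
#' @param geneId a gene identifier present in `ga`.
#' @return a list with `geneId`, `start`, `end`, `categories` (named list
#'   of character vectors) and `groups` (named logical).
#' @export
queryGeneMetadata <- function(ga, geneId) {
  assertString(geneId, "geneId")
  i <- match(geneId, geneIds(ga))
  if (is.na(i))
    scStop("UnknownIdError", sprintf("unknown gene id '%s'", geneId))
  list(geneId = geneId, start = ga@start[i], end = ga@end[i],
       categories = lapply(ga@categories, `[[`, i),
       groups = vapply(ga@groups, `[`, logical(1), i))
}

#' Color genes by metadata shared with a selected gene
#'
#' Reproduces pathway-sharing highlight semantics: the selected gene is
#' shown in the reserved selection gray; each of its values in the chosen
#' category receives a distinct palette color; every displayed gene sharing
#' at least one of those values is colored by its first shared value (in
#' the selected gene's list order); genes sharing none stay uncolored.
#'
#' @param ga a [GeneAnnotation-class].
#' @param selectedGene the selected gene; must be among `displayedGenes`.
#' @param category the metadata category to share on (e.g. `"KEGG"`).
#' @param displayedGenes ordered genes currently displayed.
#' @return a [ColorMap-class] over `displayedGenes` (kind
#'   `"shared_category"`); `NA` colors mean uncolored.
#' @export
sharedCategoryColoring <- function(ga, selectedGene, category, displayedGenes) {
  assertString(selectedGene, "selectedGene")
  if (!category %in% names(ga@categories))
    scStop("UnknownCategoryError", sprintf("unknown category '%s'", category))
  if (!selectedGene %in% displayedGenes)
    scStop("ParameterError", "selectedGene must be among displayedGenes")
  lists <- ga@categories[[category]]
  idx <- match(displayedGenes, geneIds(ga))
  selValues <- lists[[match(selectedGene, geneIds(ga))]]
  valueColors <- stats::setNames(paletteFor(length(selValues)), selValues)
  colors <- rep(NA_character_, length(displayedGenes))
  values <- rep(NA_character_, length(displayedGenes))
  for (k in seq_along(displayedGenes)) {
    if (is.na(idx[k])) next
    shared <- selValues[selValues %in% lists[[idx[k]]]]
    if (length(shared)) {
      values[k] <- shared[1L]
      colors[k] <- valueColors[[shared[1L]]]
    }
  }
  sel <- match(selectedGene, displayedGenes)
  colors[sel] <- SELECTED_COLOR
  values[sel] <- NA_character_
  new("ColorMap", entityIds = displayedGenes, colors = colors,
      intensities = rep(NA_real_, length(displayedGenes)), values = values,
      kind = "shared_category", selected = selectedGene)
}

#' Heat-map coloring of cells by one gene's expression
#'
#' Linear intensity anchored at zero: `intensity = expr / max(expr)` over
#' cells (all zero when the maximum is zero), rendered from no expression
#' (black) to high expression (full red).
#'
#' @param cm a [CountMatrix-class].
#' @param geneId the gene to color by.
#' @return a [ColorMap-class] over cells (kind `"expression"`).
#' @export
colorByExpression <- function(cm, geneId) {
  assertString(geneId, "geneId")
  if (!geneId %in% geneIds(cm))
    scStop("UnknownIdError", sprintf("unknown gene id '%s'", geneId))
  expr <- exprValues(cm)[, geneId]
  mx <- max(expr)
  intensity <- if (mx > 0) expr / mx else rep(0, length(expr))
  colors <- grDevices::rgb(intensity, 0, 0)
  new("ColorMap", entityIds = cellIds(cm), colors = colors,
      intensities = unname(intensity),
      values = rep(NA_character_, length(expr)), kind = "expression",
      selected = NA_character_)
}

#' Categorical coloring of cells by a phenotype column
#'
#' Each distinct label receives a deterministic palette color: labels are
#' sorted lexicographically (C locale) before assignment, so the mapping
#' does not depend on cell order. Empty-string labels receive the reserved
#' neutral color.
#'
#' @param pd a [PhenoData-class].
#' @param category a phenotype category name.
#' @return a [ColorMap-class] over cells (kind `"category"`).
#' @export
colorByCategory <- function(pd, category) {
  assertString(category, "category")
  if (!category %in% names(pd@categories))
    scStop("UnknownCategoryError", sprintf("unknown category '%s'", category))
  labels <- pd@categories[[category]]
  lv <- sort(unique(labels[labels != ""]), method = "radix")
  lut <- stats::setNames(paletteFor(length(lv)), lv)
  colors <- ifelse(labels == "", NEUTRAL_COLOR, lut[labels])
  new("ColorMap", entityIds = cellIds(pd), colors = unname(colors),
      intensities = rep(NA_real_, length(labels)), values = labels,
      kind = "category", selected = NA_character_)
}
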