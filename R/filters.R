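# Modular, chainable gene filters. Filters are plain specifications applied
# left-to-right over an ordered gene universe: set filters intersect with
# the current list (preserving its order), rank filters re-rank and
# truncate within it. Any order and repetition is allowed.

#' Create one gene-filter specification
#'
#' Kinds and their parameters:
#' * `top_expressed`: `n` — keep the n most highly expressed genes.
#' * `top_differential`: `n`, `mode` in `absolute` / `up` / `down` — keep
#'   the n genes with the strongest log2 fold change.
#' * `genomic_region`: `start`, `end` (bp) — genes overlapping the region.
#' * `metadata_category`: `category`, `value` — genes whose category list
#'   contains the value.
#' * `gene_group`: `group` — members of an imported `G_` gene group.
#' * `custom_set`: `genes` — an explicit gene-id set.
#'
#' @param kind one of the six filter kinds.
#' @param ... kind-specific parameters as named arguments.
#' @return a filter spec (named list) usable in [filterChain()].
#' @export
filterSpec <- function(kind = c("top_expressed", "top_differential",
                                "genomic_region", "metadata_category",
                                "gene_group", "custom_set"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  need <- switch(kind,
    top_expressed = "n",
    top_differential = c("n", "mode"),
    genomic_region = c("start", "end"),
    metadata_category = c("category", "value"),
    gene_group = "group",
    custom_set = "genes")
  if (kind == "top_differential" && is.null(params$mode)) params$mode <- "absolute"
  missing <- setdiff(need, names(params))
  if (length(missing))
    scStop("ParameterError", sprintf(
      "filter '%s' needs parameter(s): %s", kind,
      paste(missing, collapse = ", ")))
  c(list(kind = kind), params[need])
}

#' Assemble filter specs into a chain
#'
#' @param ... filter specs from [filterSpec()]; none gives the empty chain
#'   (the identity filter).
#' @return a [FilterChain-class].
#' @export
filterChain <- function(...) new("FilterChain", steps = list(...))

#' Genes with the highest expression
#'
#' Returns the `min(n, universe size)` genes with the highest expression,
#' in descending-expression order. Ties are broken by the gene's position
#' in the vector (count-matrix gene order), so results are deterministic.
#'
#' @param expr named numeric vector of per-gene expression over the current
#'   gene universe.
#' @param n number of genes to keep (default 50, the radial chart's default
#'   display size).
#' @return ordered character vector of gene ids.
#' @export
filterTopExpressed <- function(expr, n = 50L) {
  n <- assertCount(n, "n", min = 0L)
  ord <- order(-expr, seq_along(expr))
  names(expr)[utils::head(ord, n)]
}

#' Genes with the strongest differential expression
#'
#' Ranks per-gene log2 fold changes: `absolute` by `|fc|` descending, `up`
#' by signed fc descending, `down` by signed fc ascending; stable ties as
#' in [filterTopExpressed()].
#'
#' @param fc a [FoldChangeResult-class] or a named numeric vector of log2
#'   fold changes.
#' @param n number of genes to keep.
#' @param mode `"absolute"`, `"up"` or `"down"`.
#' @return ordered character vector of gene ids.
#' @export
filterTopDifferential <- function(fc, n = 50L, mode = c("absolute", "up", "down")) {
  mode <- match.arg(mode)
  if (methods::is(fc, "FoldChangeResult")) fc <- log2fcValues(fc)
  n <- assertCount(n, "n", min = 0L)
  key <- switch(mode, absolute = -abs(fc), up = -fc, down = fc)
  ord <- order(key, seq_along(fc))
  names(fc)[utils::head(ord, n)]
}

#' Genes overlapping a genomic region
#'
#' Returns genes whose `[Start, End]` interval overlaps the query region
#' (inclusive overlap, so a gene partially inside the region counts).
#' Genes lacking coordinates are excluded with a warning.
#'
#' @param ga a [GeneAnnotation-class].
#' @param regionStart,regionEnd region bounds in bp, `regionStart <=
#'   regionEnd`.
#' @return character vector of gene ids, in annotation order.
#' @export
filterGenomicRegion <- function(ga, regionStart, regionEnd) {
  if (!is.numeric(regionStart) || !is.numeric(regionEnd) ||
      regionStart > regionEnd)
    scStop("ParameterError", "regionStart must be <= regionEnd")
  noCoord <- is.na(ga@start) | is.na(ga@end)
  if (any(noCoord))
    warning(sprintf("%d gene(s) lack Start/End and are excluded from the region filter",
                    sum(noCoord)), call. = FALSE)
  hit <- !noCoord & ga@start <= regionEnd & ga@end >= regionStart
  geneIds(ga)[hit]
}

#' Genes annotated with a metadata value
#'
#' Exact string membership in the comma-split category list (any position),
#' e.g. membership in a certain KEGG pathway.
#'
#' @param ga a [GeneAnnotation-class].
#' @param category a category name present in `ga`.
#' @param value the annotation value to match.
#' @return character vector of gene ids, in annotation order.
#' @export
filterMetadata <- function(ga, category, value) {
  assertString(category, "category"); assertString(value, "value")
  if (!category %in% names(ga@categories))
    scStop("UnknownCategoryError", sprintf("unknown category '%s'", category))
  hit <- vapply(ga@categories[[category]], function(v) value %in% v, logical(1))
  geneIds(ga)[hit]
}

#' Members of an imported gene group
#'
#' @param ga a [GeneAnnotation-class].
#' @param group a group name (without the `G_` prefix) present in `ga`.
#' @return character vector of member gene ids, in annotation order.
#' @export
filterGeneGroup <- function(ga, group) {
  assertString(group, "group")
  if (!group %in% names(ga@groups))
    scStop("UnknownGroupError", sprintf("unknown gene group '%s'", group))
  geneIds(ga)[ga@groups[[group]]]
}

#' Apply a filter chain to the gene universe
#'
#' Starts from the full count-matrix gene list (matrix order) and applies
#' each step left-to-right; every step narrows the current list. Set
#' filters (region, metadata, group, custom set) intersect with the current
#' list, preserving its order — so chains containing only set filters
#' commute. Rank filters (`top_expressed`, `top_differential`) re-rank the
#' current list and truncate, so their position in the chain matters; they
#' need their context vector (`expression` / `foldChange`) supplied.
#'
#' @param chain a [FilterChain-class]; the empty chain returns all genes.
#' @param cm a [CountMatrix-class] defining the gene universe and order.
#' @param ga a [GeneAnnotation-class] (needed by set filters).
#' @param context optional named list: `expression` (named per-gene vector
#'   for `top_expressed`) and/or `foldChange` (named vector or
#'   [FoldChangeResult-class] for `top_differential`).
#' @return ordered character vector of surviving gene ids.
#' @export
applyChain <- function(chain, cm, ga, context = list()) {
  current <- geneIds(cm)
  fcv <- context$foldChange
  if (!is.null(fcv) && methods::is(fcv, "FoldChangeResult"))
    fcv <- log2fcValues(fcv)
  for (step in chain@steps) {
    current <- switch(step$kind,
      top_expressed = {
        expr <- context$expression
        if (is.null(expr))
          scStop("MissingContextError",
                 "top_expressed needs context$expression (per-gene vector)")
        filterTopExpressed(expr[current], step$n)
      },
      top_differential = {
        if (is.null(fcv))
          scStop("MissingContextError",
                 "top_differential needs context$foldChange")
        filterTopDifferential(fcv[current], step$n, step$mode)
      },
      genomic_region =
        intersect(current, filterGenomicRegion(ga, step$start, step$end)),
      metadata_category =
        intersect(current, filterMetadata(ga, step$category, step$value)),
      gene_group = intersect(current, filterGeneGroup(ga, step$group)),
      custom_set = intersect(current, step$genes))
  }
  current
}

#' Serialize a filter chain to JSON (and back)
#'
#' The JSON form is an array of step objects (`kind` plus its parameters),
#' the format the command-line interface accepts via `--filter-chain`.
#'
#' @param chain a [FilterChain-class].
#' @return `filterChainToJSON()`: a JSON string; `filterChainFromJSON()`:
#'   a [FilterChain-class].
#' @export
filterChainToJSON <- function(chain) {
  jsonlite::toJSON(chain@steps, auto_unbox = TRUE)
}

#' @rdname filterChainToJSON
#' @param json a JSON string as produced by `filterChainToJSON()`.
#' @export
filterChainFromJSON <- function(json) {
  steps <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                              simplifyVector = TRUE)
  steps <- lapply(steps, function(s) {
    kind <- s$kind
    if (is.null(kind)) scStop("ParseError", "filter step without a kind")
    do.call(filterSpec, c(list(kind = kind), s[setdiff(names(s), "kind")]))
  })
  new("FilterChain", steps = steps)
}
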