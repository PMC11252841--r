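# Chart layout computation (radial expression charts, signed fold-change
# bar charts, embedding scatter plots) and deterministic SVG/PNG export.
# Layouts are plain data (spec objects); rendering never recomputes them,
# so identical specs always export byte-identical SVG.

UP_COLOR   <- "#D62728"
DOWN_COLOR <- "#1F77B4"

#' Build a radial gene-expression chart layout
#'
#' One bar per displayed gene. Bars are ordered by descending expression
#' (ties broken by the displayed order, which follows count-matrix gene
#' order), start at 12 o'clock and proceed clockwise with equal angular
#' widths of `2*pi / n`. Bar height is expression normalized by the
#' per-chart maximum, so every chart uses the full radial range; a
#' log-scale variant (`log2(1 + x)` normalization) is available. When a
#' shared-category [ColorMap-class] is supplied, genes sharing a value with
#' the selected gene are connected to it by chords styled by the shared
#' value's color.
#'
#' @param expr named per-gene expression vector of a cell or metacell
#'   (see [cellExpr()], [metacellExpr()]); must cover `displayedGenes`.
#' @param displayedGenes ordered non-empty gene list, typically from
#'   [applyChain()].
#' @param coloring optional [ColorMap-class] over the displayed genes.
#' @param entityLabel label of the charted cell/metacell.
#' @param innerRadius,outerRadius drawing radii.
#' @param logScale normalize on `log2(1 + x)` instead of linear values.
#' @return a [RadialChartSpec-class].
#' @export
buildRadialChart <- function(expr, displayedGenes, coloring = NULL,
                             entityLabel = "cell", innerRadius = 40,
                             outerRadius = 100, logScale = FALSE) {
  if (length(displayedGenes) == 0L)
    scStop("EmptyChartError", "no genes to display")
  if (!all(displayedGenes %in% names(expr)))
    scStop("ParameterError", "expr must cover every displayed gene")
  vals <- expr[displayedGenes]
  ord <- order(-vals, seq_along(vals))
  genes <- displayedGenes[ord]
  vals <- unname(vals[ord])
  hv <- if (logScale) log2(1 + vals) else vals
  mx <- max(hv)
  heights <- if (mx > 0) hv / mx else rep(0, length(hv))
  n <- length(genes)
  w <- 2 * pi / n
  colors <- rep(NEUTRAL_COLOR, n)
  chords <- data.frame(from = character(0), to = character(0),
                       color = character(0), stringsAsFactors = FALSE)
  if (!is.null(coloring)) {
    cv <- colorValues(coloring)[genes]
    colors[!is.na(cv)] <- cv[!is.na(cv)]
    sel <- coloring@selected
    if (coloring@kind == "shared_category" && !is.na(sel) && sel %in% genes) {
      vv <- stats::setNames(coloring@values, coloring@entityIds)[genes]
      linked <- genes[!is.na(vv) & genes != sel]
      if (length(linked))
        chords <- data.frame(from = sel, to = linked,
                             color = unname(cv[linked]),
                             stringsAsFactors = FALSE)
    }
  }
  new("RadialChartSpec", entityLabel = entityLabel, geneIds = genes,
      expr = vals, heights = heights,
      startAngles = (seq_len(n) - 1) * w, endAngles = seq_len(n) * w,
      colors = colors, chords = chords, innerRadius = innerRadius,
      outerRadius = outerRadius)
}

#' Whether two genes are linked by a chord
#'
#' Chords are unordered pairs: `a` linked to `b` implies `b` linked to `a`.
#'
#' @param spec a [RadialChartSpec-class].
#' @param a,b gene identifiers.
#' @return logical.
#' @export
chordLinked <- function(spec, a, b) {
  ch <- spec@chords
  any((ch$from == a & ch$to == b) | (ch$from == b & ch$to == a))
}

#' Build a signed fold-change bar chart layout
#'
#' Bars for the displayed genes only, signed by direction: up-regulated
#' (positive log2 fold change) and down-regulated genes get distinct
#' colors; bar lengths are `|log2fc|` normalized by the displayed maximum.
#'
#' @param fc a [FoldChangeResult-class].
#' @param displayedGenes ordered non-empty subset of `geneIds(fc)`,
#'   typically from a separate filter chain.
#' @return a [FoldChangeChartSpec-class].
#' @export
buildFoldChangeChart <- function(fc, displayedGenes) {
  if (length(displayedGenes) == 0L)
    scStop("EmptyChartError", "no genes to display")
  if (!all(displayedGenes %in% geneIds(fc)))
    scStop("ParameterError", "displayedGenes must be a subset of the fold-change genes")
  v <- log2fcValues(fc)[displayedGenes]
  mx <- max(abs(v))
  lengths <- if (mx > 0) abs(v) / mx else rep(0, length(v))
  colors <- ifelse(v > 0, UP_COLOR, ifelse(v < 0, DOWN_COLOR, NEUTRAL_COLOR))
  new("FoldChangeChartSpec", geneIds = displayedGenes, log2fc = unname(v),
      lengths = unname(lengths), colors = unname(colors))
}

#' Build an embedding scatter-plot layout
#'
#' One point per cell at the selected embedding coordinates with its color
#' from a [ColorMap-class] (expression heat ramp or categorical). Metacell
#' points, when supplied, are appended and flagged for distinct rendering.
#'
#' @param emb an [Embedding-class] (2 or 3 dims, e.g. after
#'   [selectAxes()]).
#' @param colors a [ColorMap-class] covering every cell of `emb`.
#' @param metacells optional named list `label -> coordinate vector` (see
#'   [metacellPosition()]).
#' @return a [ScatterSpec-class].
#' @export
buildScatter <- function(emb, colors, metacells = NULL) {
  coords <- coordValues(emb)
  if (!ncol(coords) %in% c(2L, 3L))
    scStop("DimensionError", "scatter needs a 2D or 3D embedding; use selectAxes()")
  cells <- cellIds(emb)
  cv <- colorValues(colors)
  missing <- setdiff(cells, names(cv))
  if (length(missing))
    scStop("IncompleteColorError", sprintf(
      "color map misses cell(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")))
  pointColors <- unname(cv[cells])
  pointColors[is.na(pointColors)] <- NEUTRAL_COLOR
  ids <- cells
  flags <- rep(FALSE, length(cells))
  if (length(metacells)) {
    mcoords <- do.call(rbind, lapply(metacells, function(p)
      as.numeric(p)[seq_len(ncol(coords))]))
    coords <- rbind(coords, mcoords)
    ids <- c(ids, names(metacells))
    pointColors <- c(pointColors, rep(SELECTED_COLOR, length(metacells)))
    flags <- c(flags, rep(TRUE, length(metacells)))
  }
  new("ScatterSpec", pointIds = ids, coords = unname(coords),
      colors = pointColors, isMetacell = flags)
}

#' Centroid position of a metacell in an embedding
#'
#' A metacell is drawn as a single distinct point placed at the centroid of
#' its member cells' coordinates in the current embedding.
#'
#' @param mc a [Metacell-class].
#' @param emb an [Embedding-class] containing the member cells.
#' @return numeric coordinate vector of length `ncol(coordValues(emb))`.
#' @export
metacellPosition <- function(mc, emb) {
  i <- match(mc@cellIds, cellIds(emb))
  if (anyNA(i))
    scStop("IdMismatchError", "metacell member cells missing from the embedding")
  colMeans(coordValues(emb)[i, , drop = FALSE])
}

# ---- SVG rendering -------------------------------------------------------

fmt <- function(x) sprintf("%.6f", x)

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# polar -> screen, angle measured clockwise from 12 o'clock
polarXY <- function(cx, cy, r, theta) {
  c(cx + r * sin(theta), cy - r * cos(theta))
}

svgHeader <- function(w, h) c(
  "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
  sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
                 "height=\"%d\" viewBox=\"0 0 %d %d\">"), w, h, w, h))

svgRadial <- function(spec) {
  pad <- 10
  size <- ceiling(2 * (spec@outerRadius + pad))
  cx <- size / 2; cy <- size / 2
  lines <- svgHeader(size, size)
  span <- spec@outerRadius - spec@innerRadius
  n <- length(spec@geneIds)
  gapFrac <- 0.05  # visual gap between bars; layout spans stay contiguous
  for (i in seq_len(n)) {
    a0 <- spec@startAngles[i]; a1 <- spec@endAngles[i]
    g <- (a1 - a0) * gapFrac / 2
    a0 <- a0 + g; a1 <- a1 - g
    r0 <- spec@innerRadius
    r1 <- spec@innerRadius + spec@heights[i] * span
    p1 <- polarXY(cx, cy, r0, a0); p2 <- polarXY(cx, cy, r1, a0)
    p3 <- polarXY(cx, cy, r1, a1); p4 <- polarXY(cx, cy, r0, a1)
    large <- if ((a1 - a0) > pi) 1L else 0L
    d <- sprintf(
      "M %s %s L %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
      fmt(p1[1]), fmt(p1[2]), fmt(p2[1]), fmt(p2[2]),
      fmt(r1), fmt(r1), large, fmt(p3[1]), fmt(p3[2]),
      fmt(p4[1]), fmt(p4[2]), fmt(r0), fmt(r0), large,
      fmt(p1[1]), fmt(p1[2]))
    lines <- c(lines, sprintf(
      "<path class=\"bar\" data-gene=\"%s\" d=\"%s\" fill=\"%s\"/>",
      xmlEscape(spec@geneIds[i]), d, spec@colors[i]))
  }
  mid <- (spec@startAngles + spec@endAngles) / 2
  anchor <- function(gene) {
    i <- match(gene, spec@geneIds)
    polarXY(cx, cy, spec@innerRadius * 0.95, mid[i])
  }
  ch <- spec@chords
  for (i in seq_len(nrow(ch))) {
    p <- anchor(ch$from[i]); q <- anchor(ch$to[i])
    lines <- c(lines, sprintf(
      paste0("<path class=\"chord\" data-from=\"%s\" data-to=\"%s\" ",
             "d=\"M %s %s Q %s %s %s %s\" stroke=\"%s\" fill=\"none\"/>"),
      xmlEscape(ch$from[i]), xmlEscape(ch$to[i]),
      fmt(p[1]), fmt(p[2]), fmt(cx), fmt(cy), fmt(q[1]), fmt(q[2]),
      ch$color[i]))
  }
  c(lines, "</svg>")
}

svgFoldChange <- function(spec) {
  n <- length(spec@geneIds)
  barH <- 12; gap <- 4; halfW <- 200; pad <- 10
  w <- 2 * (halfW + pad); h <- n * (barH + gap) + 2 * pad
  cx <- w / 2
  lines <- svgHeader(w, ceiling(h))
  lines <- c(lines, sprintf(
    "<line class=\"axis\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\"/>",
    fmt(cx), fmt(pad), fmt(cx), fmt(h - pad)))
  for (i in seq_len(n)) {
    len <- spec@lengths[i] * halfW
    y <- pad + (i - 1) * (barH + gap)
    x <- if (spec@log2fc[i] >= 0) cx else cx - len
    lines <- c(lines, sprintf(
      "<rect class=\"bar\" data-gene=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
      xmlEscape(spec@geneIds[i]), fmt(x), fmt(y), fmt(len), fmt(barH),
      spec@colors[i]))
  }
  c(lines, "</svg>")
}

# project to the first two columns (orthographic for 3D specs) and scale
# into the canvas
scatterProjection <- function(spec, size, pad) {
  xy <- spec@coords[, 1:2, drop = FALSE]
  rng <- apply(xy, 2L, range)
  spanOf <- function(j) max(rng[2, j] - rng[1, j], .Machine$double.eps)
  list(
    x = pad + (xy[, 1] - rng[1, 1]) / spanOf(1) * (size - 2 * pad),
    y = size - pad - (xy[, 2] - rng[1, 2]) / spanOf(2) * (size - 2 * pad))
}

svgScatter <- function(spec) {
  size <- 600; pad <- 30
  pr <- scatterProjection(spec, size, pad)
  lines <- svgHeader(size, size)
  for (i in seq_along(spec@pointIds)) {
    cls <- if (spec@isMetacell[i]) "metacell" else "cell"
    r <- if (spec@isMetacell[i]) 9 else 4
    stroke <- if (spec@isMetacell[i]) " stroke=\"#000000\"" else ""
    lines <- c(lines, sprintf(
      "<circle class=\"%s\" data-id=\"%s\" cx=\"%s\" cy=\"%s\" r=\"%d\" fill=\"%s\"%s/>",
      cls, xmlEscape(spec@pointIds[i]), fmt(pr$x[i]), fmt(pr$y[i]), r,
      spec@colors[i], stroke))
  }
  c(lines, "</svg>")
}

#' Export a chart spec as SVG
#'
#' Writes well-formed SVG 1.1. Rendering is a pure function of the spec:
#' exporting the same spec twice yields byte-identical files. Every bar or
#' point becomes one shape element (`path`, `rect` or `circle`) carrying
#' its gene/cell id in a `data-*` attribute; 3D scatter specs are projected
#' orthographically onto their first two selected axes.
#'
#' @param spec a [RadialChartSpec-class], [FoldChangeChartSpec-class] or
#'   [ScatterSpec-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
setGeneric("exportSVG", function(spec, path) standardGeneric("exportSVG"))

writeSVG <- function(lines, path) {
  con <- openForWrite(path)
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname exportSVG
setMethod("exportSVG", "RadialChartSpec",
          function(spec, path) writeSVG(svgRadial(spec), path))
#' @rdname exportSVG
setMethod("exportSVG", "FoldChangeChartSpec",
          function(spec, path) writeSVG(svgFoldChange(spec), path))
#' @rdname exportSVG
setMethod("exportSVG", "ScatterSpec",
          function(spec, path) writeSVG(svgScatter(spec), path))

#' Export a chart spec as PNG
#'
#' Rasterizes the same layouts as [exportSVG()] at the requested pixel
#' dimensions and resolution.
#'
#' @param spec a [RadialChartSpec-class], [FoldChangeChartSpec-class] or
#'   [ScatterSpec-class].
#' @param path output file path.
#' @param widthPx,heightPx output size in pixels.
#' @param dpi raster resolution (pixels per inch).
#' @return the path, invisibly.
#' @export
setGeneric("exportPNG",
  function(spec, path, widthPx = 800, heightPx = 800, dpi = 96)
    standardGeneric("exportPNG"))

withPngDevice <- function(path, widthPx, heightPx, dpi, draw) {
  grDevices::png(path, width = widthPx, height = heightPx, res = dpi)
  ok <- FALSE
  tryCatch({ draw(); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok) scStop("IoError", sprintf("failed to render '%s'", path))
  invisible(path)
}

arcPoints <- function(cx, cy, r, a0, a1, steps = 24L) {
  th <- seq(a0, a1, length.out = steps)
  list(x = cx + r * sin(th), y = cy - r * cos(th))
}

#' @rdname exportPNG
setMethod("exportPNG", "RadialChartSpec",
  function(spec, path, widthPx = 800, heightPx = 800, dpi = 96) {
    withPngDevice(path, widthPx, heightPx, dpi, function() {
      size <- 2 * (spec@outerRadius + 10)
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::plot.new()
      graphics::plot.window(xlim = c(0, size), ylim = c(size, 0), asp = 1)
      cx <- size / 2; cy <- size / 2
      span <- spec@outerRadius - spec@innerRadius
      mid <- (spec@startAngles + spec@endAngles) / 2
      for (i in seq_along(spec@geneIds)) {
        g <- (spec@endAngles[i] - spec@startAngles[i]) * 0.025
        outer <- arcPoints(cx, cy, spec@innerRadius + spec@heights[i] * span,
                           spec@startAngles[i] + g, spec@endAngles[i] - g)
        inner <- arcPoints(cx, cy, spec@innerRadius,
                           spec@endAngles[i] - g, spec@startAngles[i] + g)
        graphics::polygon(c(outer$x, inner$x), c(outer$y, inner$y),
                          col = spec@colors[i], border = NA)
      }
      ch <- spec@chords
      for (i in seq_len(nrow(ch))) {
        a <- mid[match(ch$from[i], spec@geneIds)]
        b <- mid[match(ch$to[i], spec@geneIds)]
        r <- spec@innerRadius * 0.95
        graphics::segments(cx + r * sin(a), cy - r * cos(a),
                           cx + r * sin(b), cy - r * cos(b),
                           col = ch$color[i])
      }
    })
  })

#' @rdname exportPNG
setMethod("exportPNG", "FoldChangeChartSpec",
  function(spec, path, widthPx = 800, heightPx = 800, dpi = 96) {
    withPngDevice(path, widthPx, heightPx, dpi, function() {
      graphics::par(mar = c(2, 4, 1, 1))
      signed <- spec@lengths * sign(spec@log2fc)
      graphics::barplot(rev(signed), horiz = TRUE, col = rev(spec@colors),
                        names.arg = rev(spec@geneIds), las = 1,
                        xlim = c(-1, 1), border = NA, cex.names = 0.6)
      graphics::abline(v = 0)
    })
  })

#' @rdname exportPNG
setMethod("exportPNG", "ScatterSpec",
  function(spec, path, widthPx = 800, heightPx = 800, dpi = 96) {
    withPngDevice(path, widthPx, heightPx, dpi, function() {
      graphics::par(mar = c(2, 2, 1, 1))
      graphics::plot(spec@coords[, 1], spec@coords[, 2],
                     col = spec@colors,
                     pch = ifelse(spec@isMetacell, 17, 16),
                     cex = ifelse(spec@isMetacell, 2, 0.8),
                     xlab = "", ylab = "")
    })
  })
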