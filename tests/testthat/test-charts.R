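test_that("radial bars are max-normalized, descending, equal-width, clockwise from noon", {
  expr <- c(gA = 5, gB = 10, gC = 1)
  spec <- buildRadialChart(expr, c("gA", "gB", "gC"))
  expect_identical(spec@geneIds, c("gB", "gA", "gC"))  # descending expression
  expect_identical(spec@heights, c(1.0, 0.5, 0.1))
  w <- 2 * pi / 3
  expect_equal(spec@startAngles, c(0, w, 2 * w), tolerance = 1e-12)
  expect_equal(spec@endAngles, c(w, 2 * w, 3 * w), tolerance = 1e-12)

  single <- buildRadialChart(c(g1 = 3), "g1")
  expect_identical(single@heights, 1)
  expect_equal(single@endAngles - single@startAngles, 2 * pi,
               tolerance = 1e-12)

  expect_error(buildRadialChart(expr, character(0)), class = "EmptyChartError")
  expect_error(buildRadialChart(expr, c("gA", "gZ")), class = "ParameterError")
})

test_that("radial heights are scale-invariant and ties keep displayed order", {
  set.seed(51)
  expr <- setNames(c(4, 4, 2, 9, 0), paste0("g", 1:5))
  spec <- buildRadialChart(expr, names(expr))
  spec2 <- buildRadialChart(expr * 1000, names(expr))
  expect_equal(spec@heights, spec2@heights, tolerance = 1e-12)
  expect_identical(spec@geneIds, spec2@geneIds)
  expect_identical(spec@geneIds[2:3], c("g1", "g2"))  # tied 4s, stable
  expect_identical(max(spec@heights), 1)

  zero <- buildRadialChart(setNames(c(0, 0), c("a", "b")), c("a", "b"))
  expect_identical(zero@heights, c(0, 0))
})

test_that("chords link the selected gene to sharers, symmetrically, in category colors", {
  ga <- geneAnnotation(c("g1", "g2", "g3"),
                       categories = list(KEGG = list(c("P1"), "P1",
                                                     character(0))))
  expr <- c(g1 = 3, g2 = 2, g3 = 1)
  cmap <- sharedCategoryColoring(ga, "g1", "KEGG", names(expr))
  spec <- buildRadialChart(expr, names(expr), coloring = cmap)
  expect_identical(nrow(spec@chords), 1L)
  expect_true(chordLinked(spec, "g1", "g2"))
  expect_true(chordLinked(spec, "g2", "g1"))  # unordered pairs
  expect_false(chordLinked(spec, "g1", "g3"))
  expect_identical(spec@chords$color,
                   unname(colorValues(cmap)["g2"]))
  expect_identical(spec@colors[match("g1", spec@geneIds)], "#808080")
  expect_identical(spec@colors[match("g3", spec@geneIds)], "#C8C8C8")
})

test_that("fold-change charts sign-color bars and normalize by max |fc|", {
  fc <- computeLog2FC(c(g1 = 8, g2 = 1), c(g1 = 2, g2 = 4), pseudocount = 0)
  spec <- buildFoldChangeChart(fc, c("g1", "g2"))
  expect_identical(spec@lengths, c(1, 1))  # +2 and -2: equal lengths
  expect_false(spec@colors[1] == spec@colors[2])

  zero <- new("FoldChangeResult", geneIds = paste0("g", 1:5),
              log2fc = rep(0, 5), aLabel = "a", bLabel = "b",
              pseudocount = 1)
  specZ <- buildFoldChangeChart(zero, paste0("g", 1:5))
  expect_identical(specZ@lengths, rep(0, 5))

  set.seed(52)
  v <- setNames(rnorm(12), paste0("g", 1:12))
  fcR <- new("FoldChangeResult", geneIds = names(v), log2fc = unname(v),
             aLabel = "a", bLabel = "b", pseudocount = 1)
  top3 <- names(v)[order(-abs(v), seq_along(v))][1:3]  # brute-force selection
  spec3 <- buildFoldChangeChart(fcR, filterTopDifferential(v, 3, "absolute"))
  expect_identical(spec3@geneIds, top3)
  expect_error(buildFoldChangeChart(fcR, character(0)),
               class = "EmptyChartError")
  expect_error(buildFoldChangeChart(fcR, "gZZ"), class = "ParameterError")
})

test_that("scatter specs carry one colored point per cell plus flagged metacells", {
  cm <- countMatrix(matrix(c(0, 5, 10), 3, 1,
                           dimnames = list(c("c1", "c2", "c3"), "g1")))
  emb <- new("Embedding", cellIds = c("c1", "c2", "c3"),
             coords = matrix(c(0, 1, 2, 0, 1, 0), 3, 2),
             method = "precomputed", meta = list())
  spec <- buildScatter(emb, colorByExpression(cm, "g1"))
  expect_identical(spec@colors, c("#000000", "#800000", "#FF0000"))

  pd <- phenoData(paste0("c", 1:3), list(tp = c("EEP", "MEP", "LEP")))
  pd4 <- phenoData(paste0("c", 1:4),
                   list(tp = c("EEP", "MEP", "LEP", "ESP")))
  emb4 <- new("Embedding", cellIds = paste0("c", 1:4),
              coords = matrix(rnorm(8), 4, 2), method = "precomputed",
              meta = list())
  spec4 <- buildScatter(emb4, colorByCategory(pd4, "tp"))
  expect_length(unique(spec4@colors), 4L)

  mcs <- list(`cluster:A` = c(0.5, 0.5), `cluster:B` = c(1.5, 0.5))
  specM <- buildScatter(emb, colorByExpression(cm, "g1"), metacells = mcs)
  expect_identical(sum(specM@isMetacell), 2L)
  expect_identical(nrow(specM@coords), 5L)

  incomplete <- new("ColorMap", entityIds = c("c1", "c2"),
                    colors = c("#000000", "#FF0000"),
                    intensities = c(0, 1), values = c(NA_character_, NA),
                    kind = "expression", selected = NA_character_)
  expect_error(buildScatter(emb, incomplete), class = "IncompleteColorError")
})

test_that("metacell scatter position is the member-cell centroid", {
  d <- randomCounts(4, 3, seed = 53)
  pd <- phenoData(cellIds(d), list(cl = c("A", "A", "B", "B")))
  emb <- new("Embedding", cellIds = cellIds(d),
             coords = matrix(1:8, 4, 2), method = "precomputed",
             meta = list())
  mc <- computeMetacell(d, pd, "cl", "A")
  expect_identical(unname(metacellPosition(mc, emb)),
                   c(mean(c(1, 2)), mean(c(5, 6))))
})

test_that("SVG export is well-formed, deterministic, and one shape per bar/point", {
  skip_if_not_installed("xml2")
  fx <- generateDataset(file.path(tempdir(), "chart-fx"), nCells = 10,
                        nGenes = 200, seed = 54)
  cm <- loadCountMatrix(fx$paths$counts)
  expr <- cellExpr(cm, cellIds(cm)[1])
  spec <- buildRadialChart(expr, filterTopExpressed(expr, 50))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  exportSVG(spec, f1); exportSVG(spec, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  doc <- xml2::read_xml(f1)
  bars <- xml2::xml_find_all(doc, "//*[local-name()='path'][@class='bar']")
  expect_length(bars, 50L)
  expect_setequal(xml2::xml_attr(bars, "data-gene"), spec@geneIds)

  fcSpec <- buildFoldChangeChart(
    new("FoldChangeResult", geneIds = paste0("g", 1:7),
        log2fc = c(-2, 1, 0, 3, -1, 2, 0.5), aLabel = "a", bLabel = "b",
        pseudocount = 1), paste0("g", 1:7))
  f3 <- tempfile(fileext = ".svg"); exportSVG(fcSpec, f3)
  rects <- xml2::xml_find_all(xml2::read_xml(f3),
                              "//*[local-name()='rect'][@class='bar']")
  expect_length(rects, 7L)
})

test_that("3D scatter SVG projects orthographically onto the first two axes", {
  skip_if_not_installed("xml2")
  set.seed(55)
  emb <- new("Embedding", cellIds = paste0("c", 1:20),
             coords = matrix(rnorm(60), 20, 3), method = "precomputed",
             meta = list())
  cmap <- new("ColorMap", entityIds = paste0("c", 1:20),
              colors = rep("#112233", 20), intensities = rep(NA_real_, 20),
              values = rep(NA_character_, 20), kind = "category",
              selected = NA_character_)
  spec <- buildScatter(emb, cmap)
  f <- tempfile(fileext = ".svg"); exportSVG(spec, f)
  pts <- xml2::xml_find_all(xml2::read_xml(f),
                            "//*[local-name()='circle']")
  expect_length(pts, 20L)
  cx <- as.numeric(xml2::xml_attr(pts, "cx"))
  cy <- as.numeric(xml2::xml_attr(pts, "cy"))
  # affine in embedding column 1 (x) and column 2 (y, flipped); column 3 ignored
  expect_gt(cor(cx, emb@coords[, 1]), 1 - 1e-10)
  expect_lt(cor(cy, emb@coords[, 2]), -(1 - 1e-10))
})

test_that("PNG export honors the requested pixel dimensions", {
  skip_if_not_installed("png")
  spec <- buildRadialChart(c(g1 = 5, g2 = 2), c("g1", "g2"))
  f <- tempfile(fileext = ".png")
  exportPNG(spec, f, widthPx = 320, heightPx = 240, dpi = 72)
  expect_identical(dim(png::readPNG(f))[1:2], c(240L, 320L))
})
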