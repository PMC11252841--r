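test_that("count matrix loads cell-for-cell, verbatim ids, file order", {
  f <- writeTmpCsv(smallCountsLines)
  cm <- loadCountMatrix(f)
  expect_identical(cellIds(cm), c("c1", "c2", "c3"))
  expect_identical(geneIds(cm), c("g1", "g2", "g3", "g4"))
  expect_identical(exprValues(cm), naiveParseCounts(f))

  one <- loadCountMatrix(writeTmpCsv(c("id,gA", "c1,7")))
  expect_identical(unname(exprValues(one)), matrix(7, 1, 1))
})

test_that("count matrix rejects duplicates, non-numeric cells, empty files", {
  expect_error(loadCountMatrix(writeTmpCsv(c("id,g1", "cell_1,1", "cell_1,2"))),
               class = "DuplicateIdError")
  expect_error(loadCountMatrix(writeTmpCsv(c("id,g1,g1", "c1,1,2"))),
               class = "DuplicateIdError")
  err <- tryCatch(
    loadCountMatrix(writeTmpCsv(c("id,g1,g2", "c1,1,2", "c2,oops,4"))),
    error = identity)
  expect_s3_class(err, "ParseError")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "g1")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(loadCountMatrix(empty), class = "ParseError")
})

test_that("gene annotation parses conventions: comma lists, G_ groups, coordinates", {
  ga <- smallAnnotation()
  expect_identical(geneIds(ga), c("g1", "g2", "g3", "g4"))
  expect_identical(ga@categories$KEGG[[1]], c("map00010", "map00020"))
  expect_identical(ga@categories$KEGG[[4]], character(0))  # blank -> empty list
  expect_identical(ga@groups$virulence, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(ga@start, c(100L, 300L, 500L, 700L))
  expect_identical(ga@end, c(200L, 400L, 650L, 900L))

  # whitespace around comma-separated entries is trimmed
  spaced <- loadGeneAnnotation(writeTmpCsv(c(
    "Locus_Tag,KEGG", "gx,\"a, b\"")))
  expect_identical(spaced@categories$KEGG[[1]], c("a", "b"))
})

test_that("gene annotation schema rules are case-sensitive and strict", {
  expect_error(loadGeneAnnotation(writeTmpCsv(c("locus_tag,Start", "g1,1"))),
               class = "SchemaError")
  expect_error(loadGeneAnnotation(writeTmpCsv(c("Locus_Tag", "g1", "g1"))),
               class = "DuplicateIdError")
  expect_error(loadGeneAnnotation(writeTmpCsv(c(
    "Locus_Tag,Start,End", "g1,12.5,20"))), class = "ParseError")
  expect_error(loadGeneAnnotation(writeTmpCsv(c(
    "Locus_Tag,G_set", "g1,yes"))), class = "ParseError")
})

test_that("GFF3 annotation maps locus_tag, coordinates, and attributes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t10\t50\t.\t+\t.\tID=gene1;locus_tag=g7;product=kinase",
    "chr1\ttest\tgene\t100\t250\t.\t-\t.\tID=gene2;locus_tag=g8"), gff)
  ga <- loadGeneAnnotation(gff, format = "gff")
  expect_identical(geneIds(ga), c("g7", "g8"))
  expect_identical(ga@start, c(10L, 100L))
  expect_identical(ga@end, c(50L, 250L))
  expect_identical(ga@categories$product[[1]], "kinase")
  expect_identical(ga@categories$product[[2]], character(0))
  expect_identical(ga@categories$ID[[1]], "gene1")  # remaining attrs kept
})

test_that("pheno data loads ids plus one category per extra column", {
  pd <- smallPheno()
  expect_identical(cellIds(pd), c("c1", "c2", "c3"))
  expect_identical(pd@categories$timepoint, c("EEP", "MEP", "EEP"))
  expect_length(pd@categories, 2L)

  idsOnly <- loadPhenoData(writeTmpCsv(c("cell", "c1", "c2")))
  expect_length(categoryNames(idsOnly), 0L)
  expect_error(loadPhenoData(writeTmpCsv(c("cell,tp", "c1,a", "c1,b"))),
               class = "DuplicateIdError")
})

test_that("growth-phase style phenotype labels load with one value per cell", {
  pd <- loadPhenoData(writeTmpCsv(c(
    "cell,timepoint", "c1,EEP", "c2,MEP", "c3,LEP", "c4,ESP")))
  expect_length(pd@categories$timepoint, 4L)
  expect_setequal(pd@categories$timepoint, c("EEP", "MEP", "LEP", "ESP"))
})

test_that("Excel files load through the same conventions as CSV", {
  cdf <- data.frame(cell = c("c1", "c2"), g1 = c(1, 2.5), g2 = c(0, 3),
                    check.names = FALSE)
  cm <- loadCountMatrix(writeXlsxFixture(cdf), format = "excel")
  expect_identical(unname(exprValues(cm)), matrix(c(1, 2.5, 0, 3), 2))

  gdf <- data.frame(Locus_Tag = "g1", Start = 100, End = 200,
                    KEGG = "map00010,map00020", `G_virulence` = "1",
                    check.names = FALSE)
  ga <- loadGeneAnnotation(writeXlsxFixture(gdf), format = "excel")
  expect_identical(ga@categories$KEGG[[1]], c("map00010", "map00020"))
  expect_true(ga@groups$virulence[1])

  pdf <- data.frame(cell = c("c1", "c2"), tp = c("EEP", ""))
  pd <- loadPhenoData(writeXlsxFixture(pdf), format = "excel")
  expect_identical(pd@categories$tp, c("EEP", ""))
})

test_that("dataset validation reports missing and extra ids correctly", {
  cm <- smallCounts(); ga <- smallAnnotation(); pd <- smallPheno()
  ok <- validateDataset(cm, ga, pd)
  expect_true(reportOk(ok))
  expect_identical(nrow(reportErrors(ok)), 0L)

  gaShort <- geneAnnotation(c("g1", "g2", "g3"))  # matrix gene g4 missing
  bad <- validateDataset(cm, gaShort, pd)
  expect_false(reportOk(bad))
  expect_match(reportErrors(bad)$message, "g4", all = FALSE)

  gaExtra <- geneAnnotation(c("g1", "g2", "g3", "g4", "gExtra"))
  warn <- validateDataset(cm, gaExtra, pd)
  expect_true(reportOk(warn))
  expect_identical(reportWarnings(warn)$code, "extra_annotation_gene")
  # independent set-difference check of what should be flagged
  expect_identical(setdiff(geneIds(gaExtra), geneIds(cm)), "gExtra")
})

test_that("embedding export writes cell_id + dims and round-trips", {
  cm <- smallCounts()
  emb <- new("Embedding", cellIds = cellIds(cm),
             coords = matrix(c(1.25, -2, 3, 0.5, 1e-7, 9), 3, 2),
             method = "precomputed", meta = list())
  f <- tempfile(fileext = ".csv")
  exportEmbedding(emb, f)
  lines <- readLines(f)
  expect_length(lines, 4L)
  expect_match(lines[1], "cell_id")
  back <- loadPrecomputedEmbedding(f, cm)
  expect_lt(max(abs(coordValues(back) - coordValues(emb))), 1e-9)

  empty <- new("Embedding", cellIds = character(0),
               coords = matrix(numeric(0), 0, 2), method = "precomputed",
               meta = list())
  f2 <- tempfile(fileext = ".csv")
  exportEmbedding(empty, f2)
  expect_length(readLines(f2), 1L)  # header only
})

test_that("annotation export round-trips and adds G_ columns for new groups", {
  ga <- smallAnnotation()
  f <- tempfile(fileext = ".csv")
  exportGeneAnnotation(ga, list(), f)
  expect_annotation_equal(loadGeneAnnotation(f), ga)

  f2 <- tempfile(fileext = ".csv")
  exportGeneAnnotation(ga, list(picked = "g1"), f2)
  ga2 <- loadGeneAnnotation(f2)
  expect_identical(ga2@groups$picked, c(TRUE, FALSE, FALSE, FALSE))
  raw <- utils::read.csv(f2, check.names = FALSE, colClasses = "character")
  expect_true("G_picked" %in% colnames(raw))
  expect_identical(raw$G_picked, c("1", "", "", ""))

  expect_error(exportGeneAnnotation(ga, list(bad = "gZZ"), tempfile()),
               class = "UnknownIdError")
})

test_that("pheno export round-trips and adds painted cell-group columns", {
  pd <- smallPheno()
  f <- tempfile(fileext = ".csv")
  exportPhenoData(pd, list(), f)
  back <- loadPhenoData(f)
  expect_identical(cellIds(back), cellIds(pd))
  expect_identical(back@categories, pd@categories)

  f2 <- tempfile(fileext = ".csv")
  exportPhenoData(pd, list(clusterA = c("c2", "c3")), f2)
  back2 <- loadPhenoData(f2)
  expect_identical(back2@categories$clusterA, c("", "1", "1"))
  expect_error(exportPhenoData(pd, list(x = "cZZ"), tempfile()),
               class = "UnknownIdError")
})

test_that("comma split/join is idempotent for trimmed values", {
  cells <- c("a,b,c", "single", "", "x,y")
  split <- lapply(cells, scRadial:::splitListCell)
  joined <- vapply(split, scRadial:::joinListCell, character(1))
  expect_identical(joined, c("a,b,c", "single", "", "x,y"))
  expect_identical(lapply(joined, scRadial:::splitListCell), split)
})

test_that("unwritable paths raise IoError", {
  emb <- new("Embedding", cellIds = "c1",
             coords = matrix(0, 1, 2), method = "precomputed", meta = list())
  expect_error(exportEmbedding(emb, "/nonexistent-dir/x/y.csv"),
               class = "IoError")
})
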