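# Small in-memory fixtures and file writers shared across tests.

writeTmpCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# 3 cells x 4 genes with decimals and an exact tie (g1 vs g2 in c3)
smallCountsLines <- c(
  "cell,g1,g2,g3,g4",
  "c1,10,5,1,0",
  "c2,2.5,7,0,3",
  "c3,4,4,9,1.25")

smallCounts <- function() loadCountMatrix(writeTmpCsv(smallCountsLines))

smallAnnotationLines <- c(
  "Locus_Tag,Start,End,KEGG,G_virulence",
  "g1,100,200,\"map00010,map00020\",1",
  "g2,300,400,map00030,",
  "g3,500,650,\"map00020,map00040\",",
  "g4,700,900,,1")

smallAnnotation <- function() loadGeneAnnotation(writeTmpCsv(smallAnnotationLines))

smallPhenoLines <- c(
  "cell,timepoint,batch",
  "c1,EEP,b1",
  "c2,MEP,b1",
  "c3,EEP,b2")

smallPheno <- function() loadPhenoData(writeTmpCsv(smallPhenoLines))

# random CountMatrix built directly in memory
randomCounts <- function(nCells, nGenes, seed = 1) {
  set.seed(seed)
  countMatrix(matrix(rpois(nCells * nGenes, 20), nrow = nCells,
                     dimnames = list(sprintf("c%d", seq_len(nCells)),
                                     sprintf("g%d", seq_len(nGenes)))))
}

# write a data.frame as .xlsx through openpyxl (no xlsx writer in R here);
# all cells become text, which matches the loaders' text-first parsing
writeXlsxFixture <- function(df, path = tempfile(fileext = ".xlsx")) {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE, na = "")
  code <- sprintf(paste0(
    "import csv, openpyxl\n",
    "wb = openpyxl.Workbook(); ws = wb.active\n",
    "with open(r'%s') as f:\n",
    "    for row in csv.reader(f): ws.append(row)\n",
    "wb.save(r'%s')\n"), csv, path)
  status <- system2("python", c("-c", shQuote(code)))
  stopifnot(status == 0L)
  path
}
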