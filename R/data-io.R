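# Readers and writers for the three-file dataset model: count matrix,
# gene annotation, phenotypic data. Naming conventions are enforced
# case-sensitively: 'Locus_Tag', 'Start', 'End', and the 'G_' group prefix.

NEUTRAL_COLOR  <- "#C8C8C8"
SELECTED_COLOR <- "#808080"

# Read a CSV or Excel file into an all-character data.frame with verbatim
# headers. Blank/missing cells become "".
readRawTable <- function(path, format = c("csv", "excel")) {
  format <- match.arg(format)
  if (!file.exists(path))
    scStop("IoError", sprintf("file not found: %s", path))
  df <- if (format == "csv") {
    tryCatch(
      utils::read.csv(path, check.names = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE),
      error = function(e) scStop("ParseError",
        sprintf("cannot parse '%s' as CSV: %s", path, conditionMessage(e))))
  } else {
    x <- tryCatch(
      readxl::read_excel(path, sheet = 1, col_types = "text"),
      error = function(e) scStop("ParseError",
        sprintf("cannot parse '%s' as Excel: %s", path, conditionMessage(e))))
    as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(df) == 0L)
    scStop("ParseError", sprintf("'%s' is empty", path))
  df[] <- lapply(df, function(col) { col[is.na(col)] <- ""; col })
  df
}

# Comma-split one table cell into a trimmed character vector; blank -> empty.
splitListCell <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(character(0))
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  parts[parts != ""]
}

joinListCell <- function(parts) paste(parts, collapse = ",")

#' Load a count matrix from CSV or Excel
#'
#' The first column must contain a unique identifier for each cell and the
#' first row unique identifiers for each gene. Any numeric matrix (raw
#' counts or normalized values) is accepted; values must be finite.
#' Identifiers are taken verbatim apart from trimming surrounding
#' whitespace; cell order follows file row order and gene order file column
#' order.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"excel"` (first worksheet).
#' @return a [CountMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("cell,g1,g2", "c1,1,2", "c2,3,4"), f)
#' cm <- loadCountMatrix(f)
#' exprValues(cm)
#' @export
loadCountMatrix <- function(path, format = c("csv", "excel")) {
  df <- readRawTable(path, format)
  if (ncol(df) < 2L)
    scStop("ParseError", sprintf("'%s' has no gene columns", path))
  cells <- trimws(df[[1L]])
  genes <- trimws(colnames(df)[-1L])
  if (anyDuplicated(cells))
    scStop("DuplicateIdError", sprintf(
      "duplicate cell id(s): %s",
      paste(unique(cells[duplicated(cells)]), collapse = ", ")))
  if (anyDuplicated(genes))
    scStop("DuplicateIdError", sprintf(
      "duplicate gene id(s): %s",
      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  vals <- matrix(NA_real_, nrow = length(cells), ncol = length(genes),
                 dimnames = list(cells, genes))
  for (j in seq_along(genes)) {
    raw <- trimws(df[[j + 1L]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      scStop("ParseError", sprintf(
        "non-numeric value '%s' at row %d (cell '%s'), column %d (gene '%s')",
        raw[bad[1L]], bad[1L], cells[bad[1L]], j, genes[j]))
    vals[, j] <- num
  }
  new("CountMatrix", values = vals)
}

#' Construct a CountMatrix from a matrix in memory
#'
#' @param values numeric matrix, cells as rows and genes as columns, with
#'   unique dimnames.
#' @return a [CountMatrix-class].
#' @export
countMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("CountMatrix", values = values)
}

#' Construct a GeneAnnotation in memory
#'
#' @param ids unique gene identifiers (locus tags).
#' @param start,end integer genomic coordinates (1-based, inclusive), `NA`
#'   when unknown.
#' @param categories named list: each element one value per gene, either a
#'   list of character vectors or a character vector of comma-joined values.
#' @param groups named list of logical membership vectors.
#' @return a [GeneAnnotation-class].
#' @export
geneAnnotation <- function(ids, start = NA_integer_, end = NA_integer_,
                           categories = list(), groups = list()) {
  n <- length(ids)
  categories <- lapply(categories, function(cl) {
    if (is.character(cl)) cl <- lapply(cl, splitListCell)
    lapply(cl, as.character)
  })
  order <- c(
    if (!all(is.na(start)) || !all(is.na(end))) c("Start", "End"),
    names(categories),
    if (length(groups)) paste0("G_", names(groups)))
  new("GeneAnnotation", geneIds = as.character(ids),
      start = rep_len(as.integer(start), n), end = rep_len(as.integer(end), n),
      categories = categories, groups = lapply(groups, as.logical),
      columnOrder = as.character(order))
}

#' Construct PhenoData in memory
#'
#' @param ids unique cell identifiers.
#' @param categories named list of per-cell label vectors.
#' @return a [PhenoData-class].
#' @export
phenoData <- function(ids, categories = list()) {
  new("PhenoData", cellIds = as.character(ids),
      categories = lapply(categories, as.character))
}

parseCoordColumn <- function(raw, colname) {
  raw <- trimws(raw)
  out <- rep(NA_integer_, length(raw))
  has <- raw != ""
  num <- suppressWarnings(as.numeric(raw[has]))
  if (any(is.na(num)) || any(num != floor(num)))
    scStop("ParseError", sprintf(
      "non-integer value in column '%s': '%s'", colname,
      raw[has][which(is.na(num) | num != floor(num))[1L]]))
  out[has] <- as.integer(num)
  out
}

annotationFromTable <- function(df, path) {
  if (!"Locus_Tag" %in% colnames(df))
    scStop("SchemaError", sprintf(
      "'%s' lacks the mandatory 'Locus_Tag' column (case sensitive)", path))
  ids <- trimws(df[["Locus_Tag"]])
  if (anyDuplicated(ids))
    scStop("DuplicateIdError", sprintf(
      "duplicate locus tag(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  n <- length(ids)
  others <- setdiff(colnames(df), "Locus_Tag")
  start <- if ("Start" %in% others) parseCoordColumn(df[["Start"]], "Start")
           else rep(NA_integer_, n)
  end   <- if ("End" %in% others) parseCoordColumn(df[["End"]], "End")
           else rep(NA_integer_, n)
  categories <- list(); groups <- list()
  for (nm in others) {
    if (nm %in% c("Start", "End")) next
    if (startsWith(nm, "G_")) {
      raw <- trimws(df[[nm]])
      bad <- !(raw %in% c("", "1"))
      if (any(bad))
        scStop("ParseError", sprintf(
          "group column '%s' must contain only '1' or blank; found '%s'",
          nm, raw[which(bad)[1L]]))
      groups[[substring(nm, 3L)]] <- raw == "1"
    } else {
      categories[[nm]] <- lapply(df[[nm]], splitListCell)
    }
  }
  new("GeneAnnotation", geneIds = ids, start = start, end = end,
      categories = categories, groups = groups, columnOrder = others)
}

annotationFromGFF <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) scStop("ParseError", sprintf(
                   "cannot parse '%s' as GFF3: %s", path, conditionMessage(e))))
  md <- as.data.frame(S4Vectors::mcols(gr))
  types <- as.character(md$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  if (!any(keep))
    scStop("ParseError", sprintf("'%s' contains no gene or CDS features", path))
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  idCol <- if ("locus_tag" %in% colnames(md)) "locus_tag" else "ID"
  if (!idCol %in% colnames(md))
    scStop("SchemaError", sprintf(
      "'%s' features carry neither a locus_tag nor an ID attribute", path))
  ids <- as.character(md[[idCol]])
  if (anyNA(ids) || any(ids == ""))
    scStop("ParseError", sprintf("feature without a '%s' attribute", idCol))
  if (anyDuplicated(ids))
    scStop("DuplicateIdError", sprintf(
      "duplicate locus tag(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  attrCols <- setdiff(colnames(md), c("source", "type", "score", "phase", idCol))
  categories <- list()
  for (nm in attrCols) {
    col <- md[[nm]]
    categories[[nm]] <- if (is.list(col) || methods::is(col, "List")) {
      lapply(as.list(col), function(v) as.character(v[!is.na(v)]))
    } else {
      lapply(as.character(col),
             function(v) if (is.na(v) || v == "") character(0) else v)
    }
  }
  new("GeneAnnotation", geneIds = ids,
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      categories = categories, groups = list(),
      columnOrder = c("Start", "End", attrCols))
}

#' Load a gene annotation table from CSV, Excel or GFF3
#'
#' For tabular formats the column holding locus tags must be named
#' `Locus_Tag` and gene coordinates, when present, `Start` and `End` (all
#' case sensitive). Multiple entries in one cell are comma-separated and are
#' split into lists; columns named `G_<name>` define binary gene groups
#' (`1` = member, blank = not). For GFF3, features of type `gene` are read
#' (falling back to `CDS` when no `gene` features exist); the `locus_tag`
#' attribute is the gene identifier (falling back to `ID`) and every other
#' attribute key becomes a metadata category.
#'
#' @param path path to the file.
#' @param format `"csv"`, `"excel"` or `"gff"`.
#' @return a [GeneAnnotation-class].
#' @export
loadGeneAnnotation <- function(path, format = c("csv", "excel", "gff")) {
  format <- match.arg(format)
  if (format == "gff") {
    if (!file.exists(path)) scStop("IoError", sprintf("file not found: %s", path))
    return(annotationFromGFF(path))
  }
  annotationFromTable(readRawTable(path, format), path)
}

#' Load per-cell phenotypic data from CSV or Excel
#'
#' The first column must contain the unique cell identifiers matching the
#' count matrix; every further column is one metadata category (condition,
#' time point, batch, precomputed cluster, ...). Blank cells become the
#' empty-string label.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"excel"`.
#' @return a [PhenoData-class].
#' @export
loadPhenoData <- function(path, format = c("csv", "excel")) {
  df <- readRawTable(path, format)
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids))
    scStop("DuplicateIdError", sprintf(
      "duplicate cell id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  categories <- list()
  for (nm in colnames(df)[-1L]) categories[[nm]] <- as.character(df[[nm]])
  new("PhenoData", cellIds = ids, categories = categories)
}

#' Cross-check the three dataset files against each other
#'
#' Errors are produced for count-matrix genes missing from the annotation
#' and count-matrix cells missing from the phenotypic data; annotation
#' genes or phenotype cells absent from the matrix are tolerated as extra
#' metadata and reported as warnings.
#'
#' @param cm a [CountMatrix-class].
#' @param ga a [GeneAnnotation-class].
#' @param pd a [PhenoData-class].
#' @return a [ValidationReport-class]; nothing is raised.
#' @export
validateDataset <- function(cm, ga, pd) {
  errs <- list(); warns <- list()
  addTo <- function(lst, code, message)
    c(lst, list(data.frame(code = code, message = message)))
  for (g in setdiff(geneIds(cm), geneIds(ga)))
    errs <- addTo(errs, "gene_not_annotated",
                  sprintf("matrix gene '%s' absent from gene annotation", g))
  for (cc in setdiff(cellIds(cm), cellIds(pd)))
    errs <- addTo(errs, "cell_not_in_pheno",
                  sprintf("matrix cell '%s' absent from phenotypic data", cc))
  for (g in setdiff(geneIds(ga), geneIds(cm)))
    warns <- addTo(warns, "extra_annotation_gene",
                   sprintf("annotation gene '%s' not in count matrix", g))
  for (cc in setdiff(cellIds(pd), cellIds(cm)))
    warns <- addTo(warns, "extra_pheno_cell",
                   sprintf("phenotype cell '%s' not in count matrix", cc))
  empty <- data.frame(code = character(0), message = character(0))
  errors <- if (length(errs)) do.call(rbind, errs) else empty
  warnings <- if (length(warns)) do.call(rbind, warns) else empty
  new("ValidationReport", ok = nrow(errors) == 0L, errors = errors,
      warnings = warnings)
}

openForWrite <- function(path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) scStop("IoError", sprintf(
                    "cannot write '%s': %s", path, conditionMessage(e))),
                  warning = function(w) scStop("IoError", sprintf(
                    "cannot write '%s': %s", path, conditionMessage(w))))
  con
}

writeCsv <- function(df, path) {
  con <- openForWrite(path)
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
}

#' Export an embedding as CSV
#'
#' Writes `cell_id,dim1,...,dimD`; the file is re-importable through
#' [loadPrecomputedEmbedding()] with coordinates preserved to well below
#' 1e-9.
#'
#' @param emb an [Embedding-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportEmbedding <- function(emb, path) {
  coords <- coordValues(emb)
  df <- data.frame(cell_id = cellIds(emb), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(coords)))
    df[[paste0("dim", j)]] <- sprintf("%.15g", coords[, j])
  writeCsv(df, path)
  invisible(path)
}

#' Export a gene annotation table, optionally with new gene groups
#'
#' Reproduces the original columns (`Locus_Tag` first, then the source
#' column order): coordinates, comma-rejoined category lists and `G_`
#' group columns, then appends one `G_<name>` column per entry of
#' `newGroups` with `1` for members and blank otherwise. This is how gene
#' sets saved during exploration are persisted for re-import.
#'
#' @param ga a [GeneAnnotation-class].
#' @param newGroups named list of gene-id vectors; every id must exist.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportGeneAnnotation <- function(ga, newGroups = list(), path) {
  ids <- geneIds(ga)
  for (nm in names(newGroups)) {
    unknown <- setdiff(newGroups[[nm]], ids)
    if (length(unknown))
      scStop("UnknownIdError", sprintf(
        "group '%s' refers to unknown gene id(s): %s", nm,
        paste(unknown, collapse = ", ")))
  }
  df <- data.frame(Locus_Tag = ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fmtCoord <- function(x) ifelse(is.na(x), "", as.character(x))
  for (nm in ga@columnOrder) {
    df[[nm]] <- if (nm == "Start") fmtCoord(ga@start)
      else if (nm == "End") fmtCoord(ga@end)
      else if (startsWith(nm, "G_"))
        ifelse(ga@groups[[substring(nm, 3L)]], "1", "")
      else vapply(ga@categories[[nm]], joinListCell, character(1))
  }
  for (nm in names(newGroups))
    df[[paste0("G_", nm)]] <- ifelse(ids %in% newGroups[[nm]], "1", "")
  writeCsv(df, path)
  invisible(path)
}

#' Export phenotypic data, optionally with new (painted) cell groups
#'
#' Original categories are preserved; each entry of `newGroups` becomes a
#' binary column with `1` for member cells and blank otherwise, the format
#' [loadPhenoData()] reads back and [computeMetacell()] can aggregate over.
#'
#' @param pd a [PhenoData-class].
#' @param newGroups named list of cell-id vectors; every id must exist.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportPhenoData <- function(pd, newGroups = list(), path) {
  ids <- cellIds(pd)
  for (nm in names(newGroups)) {
    unknown <- setdiff(newGroups[[nm]], ids)
    if (length(unknown))
      scStop("UnknownIdError", sprintf(
        "group '%s' refers to unknown cell id(s): %s", nm,
        paste(unknown, collapse = ", ")))
  }
  df <- data.frame(Cell_ID = ids, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(pd@categories)) df[[nm]] <- pd@categories[[nm]]
  for (nm in names(newGroups))
    df[[nm]] <- ifelse(ids %in% newGroups[[nm]], "1", "")
  writeCsv(df, path)
  invisible(path)
}
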