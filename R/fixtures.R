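# Synthetic three-file dataset generator. Emulates the dataset model the
# loaders expect (count matrix, gene annotation with categories/groups,
# per-cell phenotype with true cluster labels) with controllable cluster
# structure, and records the ground truth in a JSON sidecar so tests can
# score filters, metacells and fold changes without re-deriving it.

#' Generate a synthetic scRNA-seq dataset on disk
#'
#' Writes `counts.csv`, `genes.csv`, `pheno.csv` and a `truth.json` sidecar
#' to `outDir`. Counts are drawn per gene and cell from a negative binomial
#' (the norm for overdispersed scRNA-seq counts) or Poisson model with base
#' mean `mu`; a designated 10% of genes are markers whose mean is shifted
#' by `2^clusterSeparation` in one cluster (cycling through clusters), so
#' `clusterSeparation` is an effect size in log2 units. Cells are assigned
#' to `nClusters` balanced clusters, recorded as the phenotype category
#' `"cluster"`. The gene annotation carries non-overlapping consecutive
#' `[Start, End]` intervals of 900 bp spaced 1 kb apart, `nCategories`
#' metadata categories with 0-3 comma-separated values per gene drawn from
#' `valuesPerCategory` possible values each, and `nGroups` random `G_`
#' gene groups. The same seed yields byte-identical files.
#'
#' @param outDir output directory (created if needed).
#' @param nCells,nGenes dataset dimensions.
#' @param nClusters number of true cell clusters (`<= nCells`).
#' @param clusterSeparation marker effect size in log2 units (0 = no
#'   cluster structure).
#' @param nCategories,valuesPerCategory gene-annotation metadata layout.
#' @param nGroups number of `G_` gene-group columns.
#' @param countModel `"negative_binomial"` (default) or `"poisson"`.
#' @param mu base count mean.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); ignored for Poisson.
#' @param seed RNG seed; recorded in the sidecar.
#' @return invisibly, a list with the four file `paths` and the `truth`
#'   list (parameters, marker genes and their high cluster, per-cell
#'   cluster labels).
#' @export
generateDataset <- function(outDir, nCells = 100L, nGenes = 200L,
                            nClusters = 2L, clusterSeparation = 2,
                            nCategories = 2L, valuesPerCategory = 4L,
                            nGroups = 2L,
                            countModel = c("negative_binomial", "poisson"),
                            mu = 20, dispersion = 0.5, seed = 1L) {
  countModel <- match.arg(countModel)
  nCells <- assertCount(nCells, "nCells", 1L)
  nGenes <- assertCount(nGenes, "nGenes", 1L)
  nClusters <- assertCount(nClusters, "nClusters", 1L)
  if (nClusters > nCells)
    scStop("ParameterError", "nClusters must be <= nCells")
  if (clusterSeparation < 0)
    scStop("ParameterError", "clusterSeparation must be non-negative")
  if (mu <= 0 || (countModel == "negative_binomial" && dispersion < 0))
    scStop("ParameterError", "mu must be positive and dispersion non-negative")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(assertCount(seed, "seed", 0L))

  cells <- sprintf("cell_%03d", seq_len(nCells))
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  clusters <- sprintf("cluster%d", rep_len(seq_len(nClusters), nCells))

  nMarkers <- max(1L, round(0.1 * nGenes))
  markers <- sort(sample(genes, nMarkers))
  highCluster <- sprintf("cluster%d",
                         rep_len(seq_len(nClusters), nMarkers))
  names(highCluster) <- markers

  means <- matrix(mu, nrow = nCells, ncol = nGenes,
                  dimnames = list(cells, genes))
  for (m in markers)
    means[clusters == highCluster[[m]], m] <- mu * 2^clusterSeparation
  counts <- if (countModel == "poisson") {
    matrix(stats::rpois(nCells * nGenes, lambda = means), nrow = nCells,
           dimnames = dimnames(means))
  } else if (dispersion == 0) {
    matrix(stats::rpois(nCells * nGenes, lambda = means), nrow = nCells,
           dimnames = dimnames(means))
  } else {
    matrix(stats::rnbinom(nCells * nGenes, mu = means,
                          size = 1 / dispersion), nrow = nCells,
           dimnames = dimnames(means))
  }

  countsPath <- file.path(outDir, "counts.csv")
  cdf <- data.frame(Cell_ID = cells, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  writeCsv(cdf, countsPath)

  start <- as.integer((seq_len(nGenes) - 1L) * 1000L + 1L)
  gdf <- data.frame(Locus_Tag = genes, Start = start,
                    End = start + 899L, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nCategories)) {
    pool <- sprintf("C%d_V%d", j, seq_len(valuesPerCategory))
    gdf[[sprintf("category%d", j)]] <- vapply(seq_len(nGenes), function(i) {
      k <- sample(0:min(3L, valuesPerCategory), 1L)
      paste(sample(pool, k), collapse = ",")
    }, character(1))
  }
  for (j in seq_len(nGroups))
    gdf[[sprintf("G_group%d", j)]] <-
      ifelse(stats::runif(nGenes) < 0.2, "1", "")
  genesPath <- file.path(outDir, "genes.csv")
  writeCsv(gdf, genesPath)

  pdf <- data.frame(Cell_ID = cells, cluster = clusters,
                    check.names = FALSE, stringsAsFactors = FALSE)
  phenoPath <- file.path(outDir, "pheno.csv")
  writeCsv(pdf, phenoPath)

  truth <- list(
    params = list(nCells = nCells, nGenes = nGenes, nClusters = nClusters,
                  clusterSeparation = clusterSeparation,
                  nCategories = nCategories,
                  valuesPerCategory = valuesPerCategory, nGroups = nGroups,
                  countModel = countModel, mu = mu, dispersion = dispersion,
                  seed = seed, markerFraction = 0.1),
    markerGenes = markers,
    markerHighCluster = as.list(highCluster),
    cellClusters = as.list(stats::setNames(clusters, cells)))
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(paths = list(counts = countsPath, genes = genesPath,
                              pheno = phenoPath, truth = truthPath),
                 truth = truth))
}
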