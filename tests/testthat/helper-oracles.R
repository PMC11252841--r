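# Independent reference implementations ("oracles") the package code is
# checked against. These deliberately share no code with the package: naive
# line splitting, per-gene loops, full sorts, covariance eigendecomposition.

# line-by-line CSV count parser (no read.csv)
naiveParseCounts <- function(path) {
  lines <- readLines(path)
  split1 <- function(l) {
    # minimal CSV field splitter handling double quotes
    out <- character(0); field <- ""; inq <- FALSE
    for (ch in strsplit(l, "")[[1]]) {
      if (ch == "\"") inq <- !inq
      else if (ch == "," && !inq) { out <- c(out, field); field <- "" }
      else field <- paste0(field, ch)
    }
    c(out, field)
  }
  header <- split1(lines[1])
  genes <- trimws(header[-1])
  cells <- character(0)
  vals <- matrix(NA_real_, nrow = length(lines) - 1, ncol = length(genes))
  for (i in seq_along(lines)[-1]) {
    f <- split1(lines[i])
    cells <- c(cells, trimws(f[1]))
    vals[i - 1, ] <- as.numeric(f[-1])
  }
  dimnames(vals) <- list(cells, genes)
  vals
}

# fold-left filter-chain evaluator built from the stated contracts with
# per-gene loops and explicit index-stable sorts
bruteChainEval <- function(steps, cm, ga, context = list()) {
  cur <- colnames(exprValues(cm))
  gi <- function(g) match(g, ga@geneIds)
  for (s in steps) {
    cur <- switch(s$kind,
      top_expressed = {
        e <- as.numeric(context$expression[cur])
        df <- data.frame(g = cur, e = e, i = seq_along(cur))
        df <- df[order(-df$e, df$i), ]
        utils::head(df$g, s$n)
      },
      top_differential = {
        f <- as.numeric(context$foldChange[cur])
        key <- switch(s$mode, absolute = -abs(f), up = -f, down = f)
        df <- data.frame(g = cur, k = key, i = seq_along(cur))
        df <- df[order(df$k, df$i), ]
        utils::head(df$g, s$n)
      },
      genomic_region = {
        keep <- character(0)
        for (g in cur) {
          st <- ga@start[gi(g)]; en <- ga@end[gi(g)]
          if (!is.na(st) && !is.na(en) && st <= s$end && en >= s$start)
            keep <- c(keep, g)
        }
        keep
      },
      metadata_category = {
        keep <- character(0)
        for (g in cur)
          if (s$value %in% ga@categories[[s$category]][[gi(g)]])
            keep <- c(keep, g)
        keep
      },
      gene_group = {
        keep <- character(0)
        for (g in cur) if (ga@groups[[s$group]][gi(g)]) keep <- c(keep, g)
        keep
      },
      custom_set = cur[cur %in% s$genes])
  }
  cur
}

# draw one random filter step valid for the given dataset
randomFilterStep <- function(cm, ga) {
  kind <- sample(c("top_expressed", "top_differential", "genomic_region",
                   "metadata_category", "gene_group", "custom_set"), 1)
  genes <- colnames(exprValues(cm))
  genomeEnd <- max(ga@end, na.rm = TRUE)
  switch(kind,
    top_expressed = filterSpec("top_expressed",
                               n = sample(0:length(genes), 1)),
    top_differential = filterSpec("top_differential",
                                  n = sample(0:length(genes), 1),
                                  mode = sample(c("absolute", "up", "down"), 1)),
    genomic_region = {
      a <- sort(sample(seq_len(genomeEnd), 2))
      filterSpec("genomic_region", start = a[1], end = a[2])
    },
    metadata_category = {
      cat <- sample(names(ga@categories), 1)
      vals <- unique(unlist(ga@categories[[cat]]))
      filterSpec("metadata_category", category = cat,
                 value = sample(vals, 1))
    },
    gene_group = filterSpec("gene_group",
                            group = sample(names(ga@groups), 1)),
    custom_set = filterSpec("custom_set",
                            genes = sample(genes, sample(seq_along(genes), 1))))
}

# per-gene loop aggregation over member cells
loopMetacell <- function(cm, members, method) {
  vals <- exprValues(cm)
  out <- numeric(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    v <- numeric(0)
    for (cc in members) v <- c(v, vals[cc, j])
    out[j] <- if (method == "mean") sum(v) / length(v) else stats::median(v)
  }
  names(out) <- colnames(vals)
  out
}

# PCA scores from an explicit covariance eigendecomposition
eigenPCA <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = xc %*% ev$vectors[, seq_len(k), drop = FALSE],
       fractions = ev$values / sum(ev$values))
}

# largest absolute difference after aligning each column's sign
signAlignedDiff <- function(a, b) {
  stopifnot(dim(a) == dim(b))
  d <- 0
  for (j in seq_len(ncol(a))) {
    s <- if (sum(a[, j] * b[, j]) < 0) -1 else 1
    d <- max(d, max(abs(a[, j] - s * b[, j])))
  }
  d
}

expect_annotation_equal <- function(a, b) {
  expect_identical(a@geneIds, b@geneIds)
  expect_identical(a@start, b@start)
  expect_identical(a@end, b@end)
  expect_identical(a@categories, b@categories)
  expect_identical(a@groups, b@groups)
  expect_identical(a@columnOrder, b@columnOrder)
}
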