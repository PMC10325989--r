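#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<-
#' @importFrom SummarizedExperiment assay colData rowData colData<- rowData<-
#' @importFrom Matrix colSums rowSums rowMeans colMeans readMM writeMM t
#' @importFrom stats prcomp dist rnbinom runif rnorm sd setNames
NULL

# Evaluate an expression under a fixed RNG state, restoring the caller's
# stream afterwards so seeded internals never perturb user code.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a single-cell UMI container
#'
#' Wraps a genes x cells UMI count matrix in a `SingleCellExperiment` with a
#' per-gene mitochondrial flag (`rowData()$mito`) and optional per-cell
#' cluster labels (`colData()$cluster`).
#'
#' @param counts Non-negative integer matrix (genes in rows, cells in
#'   columns), dense or sparse.
#' @param mito Logical per-gene flag; defaults to gene names matching
#'   `^mt-` (case-insensitive).
#' @param clusters Optional per-cell cluster labels.
#' @return A `SingleCellExperiment`.
#' @export
cell_matrix <- function(counts, mito = NULL, clusters = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and cell (column) names")
  if (is.null(mito)) mito <- grepl("^mt-", rownames(counts), ignore.case = TRUE)
  stopifnot(length(mito) == nrow(counts))
  sce <- SingleCellExperiment(assays = list(counts = counts))
  rowData(sce)$mito <- mito
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == ncol(counts))
    colData(sce)$cluster <- as.character(clusters)
  }
  sce
}

#' Read a UMI matrix from MTX plus annotation TSVs
#'
#' @param mtx_path MatrixMarket file (genes x cells).
#' @param genes_path TSV with header, columns `gene_id` and optionally `mito`.
#' @param barcodes_path TSV with header, column `cell_id` and optionally
#'   `cluster`.
#' @return A `SingleCellExperiment`.
#' @export
read_cell_matrix <- function(mtx_path, genes_path, barcodes_path) {
  counts <- readMM(mtx_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  cells <- utils::read.delim(barcodes_path, stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(counts), nrow(cells) == ncol(counts))
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  cell_matrix(counts,
              mito = if ("mito" %in% names(genes)) as.logical(genes$mito) else NULL,
              clusters = if ("cluster" %in% names(cells)) cells$cluster else NULL)
}

#' Write a UMI matrix as MTX plus annotation TSVs
#'
#' @param sce A `SingleCellExperiment` from [cell_matrix()].
#' @param mtx_path,genes_path,barcodes_path Output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_cell_matrix <- function(sce, mtx_path, genes_path, barcodes_path) {
  writeMM(methods::as(assay(sce, "counts"), "CsparseMatrix"), mtx_path)
  utils::write.table(
    data.frame(gene_id = rownames(sce), mito = rowData(sce)$mito),
    genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- data.frame(cell_id = colnames(sce))
  if ("cluster" %in% names(colData(sce))) cells$cluster <- colData(sce)$cluster
  utils::write.table(cells, barcodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx_path)
}

#' Single-cell QC thresholds
#'
#' Defaults keep cells with 3000-25,000 total transcripts, at least 1000
#' expressed genes, and a mitochondrial transcript fraction strictly below
#' 10%. Count bounds are inclusive; the mitochondrial bound is strict.
#'
#' @param min_total,max_total Inclusive bounds on total UMI per cell.
#' @param min_genes Minimum expressed genes per cell (inclusive).
#' @param max_mito_frac Strict upper bound on the mitochondrial fraction.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total = 3000L, max_total = 25000L,
                          min_genes = 1000L, max_mito_frac = 0.10) {
  stopifnot(min_total > 0, min_total < max_total,
            max_mito_frac > 0, max_mito_frac < 1)
  structure(list(min_total = min_total, max_total = max_total,
                 min_genes = min_genes, max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Filter cells by QC criteria
#'
#' @param sce A `SingleCellExperiment` with `rowData()$mito`.
#' @param thresholds A [qc_thresholds()].
#' @return The subset of cells passing all criteria; genes are unchanged. An
#'   empty result is returned with a warning, not an error.
#' @export
qc_filter <- function(sce, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- assay(sce, "counts")
  total <- colSums(counts)
  n_genes <- colSums(counts > 0)
  mito_frac <- ifelse(total > 0, colSums(counts[rowData(sce)$mito, , drop = FALSE]) /
                        pmax(total, 1), 0)
  keep <- total >= thresholds$min_total & total <= thresholds$max_total &
    n_genes >= thresholds$min_genes & mito_frac < thresholds$max_mito_frac
  if (!any(keep)) warning("no cells pass QC; returning an empty matrix")
  sce[, keep]
}

#' Log-normalize UMI counts
#'
#' Per cell: `log(1 + scale * count / total)`. All-zero cells (total 0) are
#' left at zero with a warning.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param scale Size-factor target (default `1e4`).
#' @return `sce` with a `logcounts` assay added.
#' @export
log_normalize <- function(sce, scale = 1e4) {
  counts <- assay(sce, "counts")
  total <- colSums(counts)
  if (any(total == 0)) warning("all-zero cells left unnormalized (zero)")
  sf <- ifelse(total > 0, scale / total, 0)
  logcounts(sce) <- log1p(Matrix::t(Matrix::t(counts) * sf))
  sce
}

pca_embed <- function(sce, npcs = 20L) {
  x <- as.matrix(Matrix::t(logcounts(sce)))
  keep <- apply(x, 2, sd) > 0
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  p$x[, seq_len(min(npcs, ncol(p$x))), drop = FALSE]
}

#' Reference graph-based clusterer
#'
#' Satisfies the clusterer contract `(embedding, resolution, seed) -> labels`:
#' builds a shared-nearest-neighbor graph (Jaccard weights over k-nearest
#' neighborhoods in the embedding) and partitions it by seeded Louvain
#' modularity optimization at the given resolution.
#'
#' @param embedding Cells x dimensions numeric matrix (e.g. top PCs).
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed; fixed seed gives fixed labels.
#' @param k Neighborhood size (default 10, capped at n - 1).
#' @return Integer cluster labels, one per row of `embedding`.
#' @export
snn_cluster <- function(embedding, resolution, seed = 0L, k = 10L) {
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(embedding))
  nn <- lapply(seq_len(n), function(i) order(d[i, ])[2:(k + 1L)])
  edges <- list(); w <- list(); idx <- 1L
  for (i in seq_len(n)) {
    for (j in nn[[i]]) {
      if (j > i || !(i %in% nn[[j]])) {
        shared <- length(intersect(nn[[i]], nn[[j]]))
        jac <- shared / (2L * k - shared)
        if (jac > 0) {
          edges[[idx]] <- c(i, j); w[[idx]] <- jac; idx <- idx + 1L
        }
      }
    }
  }
  if (idx == 1L) return(rep(1L, n))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, weights = unlist(w),
                                               resolution = resolution)))
  as.integer(memb)
}

#' Select a clustering resolution by silhouette
#'
#' Clusters the PCA embedding at each resolution in a grid and retains the
#' resolution maximizing the mean silhouette width over cells (Euclidean
#' distance in the embedding). Resolutions yielding a single cluster have no
#' silhouette and are skipped; ties break toward the lowest resolution.
#'
#' @param sce A log-normalized `SingleCellExperiment`.
#' @param clusterer A function `(embedding, resolution, seed) -> labels`;
#'   defaults to [snn_cluster()].
#' @param resolutions Resolution grid (default 0.2-2.0, step 0.1).
#' @param seed Integer seed forwarded to the clusterer.
#' @param npcs Number of principal components for the embedding.
#' @return A list with `resolution`, `labels`, and a `silhouette` data frame
#'   (resolution, k, mean silhouette).
#' @export
select_resolution <- function(sce, clusterer = snn_cluster,
                              resolutions = seq(0.2, 2.0, by = 0.1),
                              seed = 0L, npcs = 20L) {
  emb <- pca_embed(sce, npcs)
  d <- dist(emb)
  rows <- lapply(resolutions, function(res) {
    labels <- clusterer(emb, res, seed)
    k <- length(unique(labels))
    sil <- if (k >= 2)
      mean(cluster::silhouette(as.integer(factor(labels)), d)[, "sil_width"])
    else NA_real_
    list(resolution = res, k = k, mean_silhouette = sil, labels = labels)
  })
  tab <- data.frame(resolution = vapply(rows, `[[`, numeric(1), "resolution"),
                    k = vapply(rows, `[[`, numeric(1), "k"),
                    mean_silhouette = vapply(rows, `[[`, numeric(1), "mean_silhouette"))
  if (all(is.na(tab$mean_silhouette)))
    stop("degenerate clustering: a single cluster at every resolution")
  best <- which.max(tab$mean_silhouette)  # first maximum = lowest resolution
  list(resolution = tab$resolution[best], labels = rows[[best]]$labels,
       silhouette = tab)
}

#' Per-cluster marker detection (Wilcoxon)
#'
#' For each cluster, a gene is tested against all remaining cells if it is
#' expressed in at least `min_pct` of the cells on either side and its mean
#' log-expression difference is at least `logfc_threshold` in absolute value.
#' Wilcoxon rank-sum p-values are BH-adjusted within cluster. Clusters of a
#' single cell are skipped with a warning.
#'
#' @param sce A log-normalized `SingleCellExperiment`.
#' @param labels Per-cell cluster labels.
#' @param min_pct Minimum expressed fraction (default 0.1).
#' @param logfc_threshold Minimum absolute mean log difference (default 0.25).
#' @return A `data.frame` with cluster, gene, pct_in, pct_out, log_diff,
#'   p_value and fdr, ordered by cluster then fdr.
#' @export
find_markers <- function(sce, labels, min_pct = 0.1, logfc_threshold = 0.25) {
  x <- logcounts(sce)
  stopifnot(length(labels) == ncol(x))
  if (length(unique(labels)) < 2) stop("need at least two clusters")
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 2) {
      warning("skipping cluster of a single cell: ", cl)
      next
    }
    xin <- x[, in_cl, drop = FALSE]
    xout <- x[, !in_cl, drop = FALSE]
    pct_in <- rowSums(xin > 0) / ncol(xin)
    pct_out <- rowSums(xout > 0) / ncol(xout)
    log_diff <- rowMeans(xin) - rowMeans(xout)
    test <- (pmax(pct_in, pct_out) >= min_pct) & (abs(log_diff) >= logfc_threshold)
    if (!any(test)) next
    idx <- which(test)
    p <- vapply(idx, function(i) {
      suppressWarnings(wilcox.test(as.numeric(xin[i, ]), as.numeric(xout[i, ]),
                                   correct = FALSE)$p.value)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = rownames(x)[idx],
      pct_in = pct_in[idx], pct_out = pct_out[idx], log_diff = log_diff[idx],
      p_value = p, fdr = p.adjust(p, "BH"), row.names = NULL)
  }
  if (!length(out))
    return(data.frame(cluster = character(0), gene = character(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      log_diff = numeric(0), p_value = numeric(0), fdr = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$cluster, res$fdr, res$gene), , drop = FALSE]
}

#' Identify double-positive cells
#'
#' A cell is double-positive when its raw count for the primary factor
#' exceeds `floor` and its count for at least one of the partner factors does
#' too. Intended to be applied within the mesenchymal clusters.
#'
#' @param sce A `SingleCellExperiment`.
#' @param primary Primary factor gene (default `"Hand2"`).
#' @param partners Partner genes, any one suffices (default `Pbx1`, `Pbx2`).
#' @param floor Expression floor on raw counts (default 0, i.e. any count).
#' @return Character vector of double-positive cell ids.
#' @export
double_positive_cells <- function(sce, primary = "Hand2",
                                  partners = c("Pbx1", "Pbx2"), floor = 0) {
  counts <- assay(sce, "counts")
  missing <- setdiff(c(primary, partners), rownames(counts))
  if (length(missing)) stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  prim <- as.numeric(counts[primary, ]) > floor
  part <- Matrix::colSums(counts[partners, , drop = FALSE] > floor) > 0
  colnames(counts)[prim & part]
}

#' Co-expression AUROC of a gene against double-positive cells
#'
#' The area under the ROC curve of the target gene's expression classifying
#' positive (double-positive) versus background cells: `U / (n1 * n2)` with
#' midrank tie handling, where `U` is the Mann-Whitney statistic. An AUC of
#' 0.5 means no association; genes pass the co-expression filter at
#' `auc >= threshold` (0.55 by convention).
#'
#' @param sce A log-normalized `SingleCellExperiment`.
#' @param target Target gene id.
#' @param positive_cells,background_cells Disjoint, non-empty cell-id sets.
#' @return A list of class `coexpression_score` with `gene_id`, `auc`,
#'   `positive_n`, `negative_n`.
#' @export
coexpression_auc <- function(sce, target, positive_cells, background_cells) {
  if (!target %in% rownames(sce)) stop("target gene absent from matrix: ", target)
  if (!length(positive_cells) || !length(background_cells))
    stop("positive and background cell sets must both be non-empty")
  if (length(intersect(positive_cells, background_cells)))
    stop("positive and background cell sets must be disjoint")
  expr <- as.numeric(logcounts(sce)[target, ])
  names(expr) <- colnames(sce)
  pos <- expr[positive_cells]
  bg <- expr[background_cells]
  n1 <- length(pos); n2 <- length(bg)
  r <- rank(c(pos, bg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  structure(list(gene_id = target, auc = u / (n1 * n2),
                 positive_n = n1, negative_n = n2),
            class = "coexpression_score")
}

#' Gene-set module score per cell
#'
#' For each cell: mean log-expression of the gene set minus mean
#' log-expression of control genes sampled (seeded) from the same
#' average-expression bins, following the standard module-score construction.
#'
#' @param sce A log-normalized `SingleCellExperiment`.
#' @param gene_set Character vector of gene ids (non-empty, all present).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100; capped at
#'   bin size).
#' @param seed Integer seed; fixed seed gives an identical score vector.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(sce, gene_set, n_bins = 24L, n_ctrl = 100L, seed = 0L) {
  if (!length(gene_set)) stop("gene_set must be non-empty")
  missing <- setdiff(gene_set, rownames(sce))
  if (length(missing)) stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  x <- logcounts(sce)
  avg <- rowMeans(x)
  n_bins <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(x)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, size = min(n_ctrl, length(pool)))
    })))
  })
  set_mean <- colMeans(x[gene_set, , drop = FALSE])
  ctrl_mean <- colMeans(x[ctrl, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(x))
}
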