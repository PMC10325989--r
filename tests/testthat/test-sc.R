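# Small matrices built in code; the generator-backed checks live in
# test-simulate.R and test-acceptance.R.

mk_sce <- function(counts, mito = NULL, clusters = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
  cell_matrix(counts, mito = mito, clusters = clusters)
}

test_that("QC filtering applies inclusive count bounds and a strict mito bound", {
  t <- qc_thresholds(min_total = 100, max_total = 1000, min_genes = 3,
                     max_mito_frac = 0.10)
  counts <- cbind(
    below = c(97, 1, 1, 0),      # total 99 -> removed
    at_min = c(97, 2, 1, 0),     # total 100, 3 genes -> kept
    at_max = c(997, 2, 1, 0),    # total 1000 -> kept
    above = c(998, 2, 1, 0),     # total 1001 -> removed
    few_genes = c(150, 0, 0, 0), # 1 expressed gene -> removed
    mito_at = c(85, 3, 2, 10),   # mito fraction exactly 0.10 -> removed (strict)
    mito_under = c(86, 3, 2, 9), # 0.09 -> kept
    zero = c(0, 0, 0, 0))        # removed
  rownames(counts) <- c("a", "b", "c", "mt-1")
  sce <- mk_sce(counts)
  kept <- colnames(qc_filter(sce, t))
  expect_setequal(kept, c("at_min", "at_max", "mito_under"))
  # idempotence
  expect_equal(colnames(qc_filter(qc_filter(sce, t), t)), kept)
  expect_warning(qc_filter(sce, qc_thresholds(min_total = 1e6, max_total = 2e6)),
                 "no cells")
})

test_that("QC on a generated matrix equals a per-cell rule loop", {
  set.seed(77)
  counts <- matrix(rnbinom(40 * 500, mu = 6, size = 1), nrow = 40)
  rownames(counts) <- c(sprintf("g%d", 1:36), sprintf("mt-%d", 1:4))
  colnames(counts) <- sprintf("c%d", 1:500)
  t <- qc_thresholds(min_total = 200, max_total = 320, min_genes = 30,
                     max_mito_frac = 0.12)
  kept <- colnames(qc_filter(mk_sce(counts), t))
  want <- character(0)
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    ng <- sum(counts[, j] > 0)
    mf <- if (tot > 0) sum(counts[37:40, j]) / tot else 0
    if (tot >= 200 && tot <= 320 && ng >= 30 && mf < 0.12)
      want <- c(want, colnames(counts)[j])
  }
  expect_equal(kept, want)
})

test_that("log-normalization matches the elementwise formula", {
  counts <- matrix(c(0, 5, 0, 0, 0, 12), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  sce <- log_normalize(mk_sce(counts), scale = 1e4)
  x <- as.matrix(SingleCellExperiment::logcounts(sce))
  expect_equal(x["g1", "c1"], 0)
  expect_equal(x["g2", "c1"], log1p(1e4 * 5 / 5))   # single expressed gene
  expect_equal(x["g3", "c2"], log1p(1e4 * 12 / 12))
  set.seed(9)
  counts <- matrix(rpois(600, 4), nrow = 20)
  sce <- log_normalize(mk_sce(counts), scale = 100)
  x <- as.matrix(SingleCellExperiment::logcounts(sce))
  want <- log1p(100 * sweep(counts, 2, colSums(counts), "/"))
  expect_equal(unname(x), want, tolerance = 1e-12)
  withzero <- cbind(counts[, 1:3], 0)
  expect_warning(log_normalize(mk_sce(withzero)), "all-zero")
})

test_that("co-expression AUC equals exhaustive pair counting and is rank-invariant", {
  counts <- rbind(target = c(3, 5, 9, 1, 0, 7, 2, 2, 0, 4, 6),
                  other = rep(1, 11))
  colnames(counts) <- sprintf("c%d", 1:11)
  sce <- log_normalize(mk_sce(counts))
  pos <- sprintf("c%d", 1:6); bg <- sprintf("c%d", 7:11)
  got <- coexpression_auc(sce, "target", pos, bg)
  x <- as.numeric(SingleCellExperiment::logcounts(sce)["target", ])
  expect_equal(got$auc, brute_auc(x[1:6], x[7:11]))
  expect_equal(got$positive_n, 6); expect_equal(got$negative_n, 5)

  # complete tie -> 0.5 (equal library sizes keep the gene tied after scaling)
  tie <- rbind(flat = rep(2, 11), other = rep(3, 11))
  colnames(tie) <- colnames(counts)
  expect_equal(coexpression_auc(log_normalize(mk_sce(tie)), "flat", pos, bg)$auc,
               0.5)
  perfect <- rbind(hit = c(rep(5, 6), rep(0, 5)), other = rep(1, 11))
  colnames(perfect) <- colnames(counts)
  expect_equal(coexpression_auc(log_normalize(mk_sce(perfect)), "hit", pos, bg)$auc, 1)

  # invariance under a strictly monotone transform of expression
  counts2 <- counts; counts2["target", ] <- counts["target", ]^3
  got2 <- coexpression_auc(log_normalize(mk_sce(counts2)), "target", pos, bg)
  expect_equal(got2$auc, got$auc)

  expect_error(coexpression_auc(sce, "absent", pos, bg), "absent")
  expect_error(coexpression_auc(sce, "target", pos, c(pos[1], bg)), "disjoint")
})

test_that("module scores cancel under self-controls and rank planted programs first", {
  set.seed(15)
  mu <- rlnorm(200, log(5), 0.5)  # spread of baselines so bins mix gene kinds
  counts <- matrix(rpois(200 * 90, mu), nrow = 200,
                   dimnames = list(sprintf("g%d", 1:200), sprintf("c%d", 1:90)))
  program <- sprintf("g%d", 1:5)
  counts[program, 1:30] <- counts[program, 1:30] * 4
  sce <- log_normalize(mk_sce(counts))
  sc1 <- module_score(sce, program, seed = 4)
  sc2 <- module_score(sce, program, seed = 4)
  expect_identical(sc1, sc2)  # determinism for a fixed seed
  grp <- rep(c("hi", "lo", "lo"), each = 30)
  expect_gt(mean(sc1[grp == "hi"]), mean(sc1[grp == "lo"]))

  # with one bin per gene-rank the only candidate control is the gene itself
  self <- module_score(sce, "g40", n_bins = 200, n_ctrl = 10, seed = 1)
  expect_true(all(self == 0))
  expect_error(module_score(sce, character(0)), "non-empty")
})

test_that("resolution selection maximizes silhouette and breaks ties low", {
  set.seed(2)
  blob <- cbind(matrix(rpois(20 * 40, 10), nrow = 20),
                matrix(rpois(20 * 40, 10) + rep(c(40, 0), c(10, 10)), nrow = 20))
  dimnames(blob) <- list(sprintf("g%d", 1:20), sprintf("c%d", 1:80))
  sce <- log_normalize(mk_sce(blob))
  sel <- select_resolution(sce, resolutions = seq(0.2, 1.0, by = 0.2), seed = 1)
  expect_equal(length(unique(sel$labels)), 2)
  split_truth <- rep(1:2, each = 40)
  # labels recover the planted split (up to a stray ambiguous cell)
  agreement <- max(table(sel$labels, split_truth)[, 1]) +
    max(table(sel$labels, split_truth)[, 2])
  expect_gte(agreement / 80, 0.975)

  # tie-break: identical two-cluster solutions offered at 0.4 and 0.6 only
  fake <- function(emb, res, seed) {
    if (res %in% c(0.4, 0.6)) rep(1:2, each = nrow(emb) / 2) else rep(1L, nrow(emb))
  }
  sel2 <- select_resolution(sce, clusterer = fake,
                            resolutions = seq(0.2, 1.0, by = 0.1))
  expect_equal(sel2$resolution, 0.4)

  only1 <- function(emb, res, seed) rep(1L, nrow(emb))
  expect_error(select_resolution(sce, clusterer = only1), "degenerate")
})

test_that("three planted NB clusters are recovered at the silhouette optimum", {
  set.seed(33)
  n_per <- 40
  mk_block <- function(shift_genes) {
    mu <- matrix(3, nrow = 60, ncol = n_per)
    mu[shift_genes, ] <- 24
    matrix(rnbinom(length(mu), mu = mu, size = 2), nrow = 60)
  }
  counts <- cbind(mk_block(1:15), mk_block(16:30), mk_block(31:45))
  dimnames(counts) <- list(sprintf("g%d", 1:60), sprintf("c%d", 1:(3 * n_per)))
  sel <- select_resolution(log_normalize(mk_sce(counts)), seed = 3)
  expect_equal(length(unique(sel$labels)), 3)
  truth <- rep(1:3, each = n_per)
  expect_equal(length(unique(paste(sel$labels, truth))), 3)
})

test_that("marker detection finds cluster-specific genes and filters flat ones", {
  set.seed(44)
  counts <- matrix(rpois(30 * 60, 4), nrow = 30,
                   dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:60)))
  labels <- rep(c(1, 2), each = 30)
  counts["g1", labels == 2] <- 0            # expressed only in cluster 1
  counts["g2", ] <- 4                        # uniform -> filtered by logfc
  sce <- log_normalize(mk_sce(counts))
  mk <- find_markers(sce, labels)
  g1row <- mk[mk$gene == "g1" & mk$cluster == 1, ]
  expect_equal(nrow(g1row), 1)
  expect_equal(g1row$pct_out, 0)
  expect_lt(g1row$fdr, 0.01)
  expect_false("g2" %in% mk$gene)
  expect_warning(find_markers(sce, c(rep(1, 59), 2)), "single cell")
})

test_that("double-positive calls require the primary and at least one partner", {
  counts <- rbind(Hand2 = c(1, 1, 0, 5), Pbx1 = c(2, 0, 3, 0),
                  Pbx2 = c(0, 0, 1, 2), other = c(1, 1, 1, 1))
  colnames(counts) <- c("dp1", "h_only", "p_only", "dp2")
  sce <- mk_sce(counts)
  expect_setequal(double_positive_cells(sce), c("dp1", "dp2"))
  expect_setequal(double_positive_cells(sce, floor = 1), "dp2")
  expect_error(double_positive_cells(sce, primary = "Nope"), "absent")
})

test_that("MTX round-trip preserves the matrix and annotations", {
  set.seed(6)
  counts <- matrix(rpois(200, 2), nrow = 20,
                   dimnames = list(c(sprintf("g%d", 1:18), "mt-1", "mt-2"),
                                   sprintf("c%d", 1:10)))
  sce <- mk_sce(counts, clusters = rep(c("x", "y"), 5))
  d <- withr::local_tempdir()
  write_cell_matrix(sce, file.path(d, "m.mtx"), file.path(d, "g.tsv"),
                    file.path(d, "b.tsv"))
  back <- read_cell_matrix(file.path(d, "m.mtx"), file.path(d, "g.tsv"),
                           file.path(d, "b.tsv"))
  expect_equal(as.matrix(SummarizedExperiment::assay(back)), counts)
  expect_equal(SummarizedExperiment::rowData(back)$mito, grepl("^mt-", rownames(counts)))
  expect_equal(SummarizedExperiment::colData(back)$cluster, rep(c("x", "y"), 5))
})
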