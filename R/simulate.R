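# Seeded synthetic-data generators. Every pipeline input can be produced at
# desk scale with planted ground truth: co-binding structure with elevated
# accessibility at co-bound sites, concordant/discordant DEG tables,
# negative-binomial single-cell counts with a double-positive subpopulation,
# a TAD with planted passing/failing enhancer candidates, and cross-tissue
# cistromes with planted cofactor-selection rates. All generators are pure
# functions of the configuration: a fixed seed gives byte-identical outputs.

#' Simulation configuration
#'
#' Bundles every generator's parameters. Defaults mirror the study
#' conditions the pipeline was built around, scaled to desk size: two TF
#' ChIP replicates combined at stringent/weak thresholds, a co-bound region
#' fraction with a +3 accessibility shift, DEG classes of 46/37/31
#' concordant-up/concordant-down/discordant genes, a double-positive
#' mesenchymal subpopulation with planted co-expressed targets, and
#' cross-tissue cofactor-selection rates of 48%/18% (HAND2 vs HL/MF) and
#' 70%/43% (HOXA2 vs BA2/HL).
#'
#' @param seed Master seed; each generator derives its own fixed stream.
#' @param genome Named integer vector of chromosome lengths.
#' @param n_genes Number of genes in the synthetic gene model.
#' @param n_tads Number of TADs tiling the genome.
#' @param peak_plan List: `n_a_only`, `n_cobound`, `n_b_only` region counts,
#'   `n_reps` replicates per TF, `width` peak width, `jitter_bp` replicate
#'   center jitter SD, `jitter_p` replicate score jitter SD,
#'   `cobound_signal_shift` added to ATAC/H3K27ac `-log10(p)` at co-bound
#'   regions, `deg_tad_extra` extra TF sites placed in TADs containing
#'   planted shared DEGs.
#' @param deg_plan List of class counts (`concordant_up`, `concordant_down`,
#'   `discordant`, `a_only`, `b_only`, `undetected`) and effect bounds
#'   (`lfc_min`, `lfc_max` on |log2FC|).
#' @param sc_plan List: cells per cluster, genes, negative-binomial size,
#'   `dp_fraction` of the posterior mesenchymal cluster that is
#'   double-positive, `n_targets` planted co-expressed genes,
#'   `target_effect` (log-units), planted QC-failure counts.
#' @param enhancer_plan List: `n_pass`, `n_fail` candidates in the scanned
#'   TAD, `min_fold` the downstream filter threshold.
#' @param cross_tissue_plan List: tissue names, peaks per tissue, shared-core
#'   fraction, cofactor rates, signal-table sizes and planted log2FC shift.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 0L,
                       genome = c(chr1 = 20e6, chr2 = 20e6),
                       n_genes = 400L,
                       n_tads = 40L,
                       peak_plan = list(),
                       deg_plan = list(),
                       sc_plan = list(),
                       enhancer_plan = list(),
                       cross_tissue_plan = list()) {
  peak_plan <- utils::modifyList(list(
    n_a_only = 700L, n_cobound = 300L, n_b_only = 220L,
    n_reps = 2L, n_atac_reps = 3L, width = 300L,
    jitter_bp = 20, jitter_p = 0.5,
    p_min = 8, p_max = 30,
    mark_p_mean = 6, mark_p_sd = 1, cobound_signal_shift = 3,
    deg_tad_extra = 6L), peak_plan)
  deg_plan <- utils::modifyList(list(
    concordant_up = 46L, concordant_down = 37L, discordant = 31L,
    a_only = 60L, b_only = 40L, undetected = 10L,
    lfc_min = log2(1.5), lfc_max = 2), deg_plan)
  sc_plan <- utils::modifyList(list(
    cells = c(mes_posterior = 800L, mes_other = 800L, epithelial = 400L),
    n_genes = 1500L, n_mito = 10L, nb_size = 2,
    base_mean = 6, marker_genes = 25L, marker_fold = 4,
    dp_fraction = 0.5, n_targets = 7L, target_effect = 1.5,
    qc_low_umi = 5L, qc_high_umi = 2L, qc_high_mito = 3L,
    qc_min_total = 3000, qc_max_total = 25000, qc_max_mito = 0.10), sc_plan)
  enhancer_plan <- utils::modifyList(list(
    n_pass = 5L, n_fail = 10L, min_fold = 15), enhancer_plan)
  cross_tissue_plan <- utils::modifyList(list(
    tissues = c("HL", "BA2", "MF"),
    n_per_tissue = 1000L, core_fraction = 0.6,
    n_cofactor = 1000L,
    hand2_rates = c(HL = 0.48, MF = 0.18),
    hoxa2_rates = c(BA2 = 0.70, HL = 0.43),
    n_signal = 300L, signal_shift = 1), cross_tissue_plan)
  stopifnot(all(genome > 0), n_genes >= 0, n_tads >= 1,
            peak_plan$n_cobound >= 0, sc_plan$dp_fraction >= 0,
            sc_plan$dp_fraction <= 1)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes), n_tads = as.integer(n_tads),
                 peak_plan = peak_plan, deg_plan = deg_plan, sc_plan = sc_plan,
                 enhancer_plan = enhancer_plan,
                 cross_tissue_plan = cross_tissue_plan),
            class = "sim_config")
}

# Sample n non-overlapping intervals of `width` bp from a slotted grid over
# the genome (one interval per `spacing`-bp slot at most). Caller manages RNG.
place_regions <- function(n, genome, width, spacing = 2000L) {
  slots_per_chr <- pmax(0L, as.integer(floor(genome / spacing)) - 1L)
  total <- sum(slots_per_chr)
  if (n > total) stop("genome too small for ", n, " regions at spacing ", spacing)
  picked <- sort(sample.int(total, n))
  chr_idx <- findInterval(picked - 1L, cumsum(c(0L, slots_per_chr)),
                          rightmost.closed = FALSE)
  offset_in_chr <- picked - c(0L, cumsum(slots_per_chr))[chr_idx]
  start <- (offset_in_chr - 1L) * spacing + 1L +
    sample.int(max(1L, spacing - width - 1L), n, replace = TRUE)
  GRanges(names(genome)[chr_idx], IRanges(start, width = width))
}

#' Generate a synthetic genome annotation
#'
#' Non-overlapping gene bodies with strand-aware TSSs, TADs tiling each
#' chromosome end to end, and conserved elements scattered at fixed density.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (gene models), `tads` (`GRanges` with
#'   `tad_id`), `conserved` (`GRanges`), and `gene_tad` (a `data.frame`
#'   mapping genes to TADs).
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  with_seed(cfg$seed + 101L, {
    bodies <- place_regions(cfg$n_genes, cfg$genome, width = 8000L,
                            spacing = 40000L)
    strand(bodies) <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- gene_models(bodies, sprintf("gene_%03d", seq_len(cfg$n_genes)))
    per_chr <- pmax(1L, round(cfg$n_tads * cfg$genome / sum(cfg$genome)))
    tad_df <- do.call(rbind, lapply(seq_along(cfg$genome), function(i) {
      k <- per_chr[i]
      bounds <- round(seq(1, cfg$genome[i], length.out = k + 1))
      data.frame(chrom = names(cfg$genome)[i], start = bounds[-(k + 1)],
                 end = bounds[-1] - c(rep(1, k - 1), 0))
    }))
    tads <- GRanges(tad_df$chrom, IRanges(tad_df$start, tad_df$end))
    mcols(tads)$tad_id <- sprintf("tad_%02d", seq_along(tads))
    n_cons <- as.integer(sum(cfg$genome) / 10000)
    conserved <- place_regions(n_cons, cfg$genome, width = 200L, spacing = 5000L)
    hits <- findOverlaps(genes, tads, ignore.strand = TRUE)
    gene_tad <- data.frame(gene_id = genes$gene_id[queryHits(hits)],
                           tad_id = tads$tad_id[subjectHits(hits)])
    gene_tad <- gene_tad[!duplicated(gene_tad$gene_id), ]
    list(genes = genes, tads = tads, conserved = conserved, gene_tad = gene_tad)
  })
}

# Deterministic DEG class assignment: classes are dealt to genes in id order,
# so every generator agrees on which genes are planted where without sharing
# state. Randomness enters only through the statistics drawn for each gene.
deg_truth_classes <- function(cfg) {
  p <- cfg$deg_plan
  classes <- rep("null", cfg$n_genes)
  idx <- 1L
  for (cls in c("concordant_up", "concordant_down", "discordant",
                "a_only", "b_only", "undetected")) {
    k <- p[[cls]]
    if (idx + k - 1L > cfg$n_genes)
      stop("deg_plan counts exceed n_genes")
    if (k > 0) classes[idx:(idx + k - 1L)] <- cls
    idx <- idx + k
  }
  data.frame(gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
             class = classes)
}

#' Generate synthetic peak sets with planted co-binding structure
#'
#' Lays out disjoint A-only, co-bound and B-only regions; emits jittered
#' per-replicate TF peak collections (center jitter, score jitter) so the
#' consensus stage has real work to do; and emits ATAC / H3K27ac replicates
#' covering every region, with the configured extra `-log10(p)` signal at
#' co-bound regions. Extra TF sites are added inside TADs containing planted
#' shared DEGs so TAD regulatory scores carry signal.
#'
#' @param cfg A [sim_config()].
#' @param genome_ann Optional result of [gen_genome()] (regenerated if
#'   missing).
#' @return A list with `reps_a`, `reps_b` (lists of replicate collections),
#'   `atac_reps`, `h3k27ac_reps`, and `truth` (regions with planted class).
#' @export
gen_peaksets <- function(cfg, genome_ann = gen_genome(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$peak_plan
  with_seed(cfg$seed + 202L, {
    deg_classes <- deg_truth_classes(cfg)
    shared <- deg_classes$gene_id[deg_classes$class %in%
                                    c("concordant_up", "concordant_down", "discordant")]
    deg_tads <- unique(genome_ann$gene_tad$tad_id[
      genome_ann$gene_tad$gene_id %in% shared])
    n_extra <- p$deg_tad_extra * length(deg_tads)
    n_total <- p$n_a_only + p$n_cobound + p$n_b_only
    regions <- place_regions(n_total, cfg$genome, width = p$width)
    cls <- sample(rep(c("A_only", "both", "B_only"),
                      c(p$n_a_only, p$n_cobound, p$n_b_only)))
    # extra A sites inside DEG TADs (distal placement handled downstream)
    extra <- GRanges()
    if (n_extra > 0 && length(deg_tads)) {
      tads <- genome_ann$tads[genome_ann$tads$tad_id %in% deg_tads]
      tad_pick <- rep(seq_along(tads), each = p$deg_tad_extra)
      st <- round(start(tads)[tad_pick] +
                    runif(n_extra) * (width(tads)[tad_pick] - p$width - 1))
      extra <- GRanges(seqnames(tads)[tad_pick], IRanges(st, width = p$width))
      extra <- extra[!overlapsAny(extra, regions, ignore.strand = TRUE)]
    }
    truth <- if (length(extra)) suppressWarnings(c(regions, extra)) else regions
    mcols(truth)$class <- c(cls, rep("A_only", length(extra)))
    mcols(truth)$true_p <- runif(length(truth), p$p_min, p$p_max)
    jittered <- function(gr, rep_i, factor, assay, tissue = "HL") {
      shift_bp <- round(rnorm(length(gr), 0, p$jitter_bp))
      pj <- pmax(0, mcols(gr)$true_p + rnorm(length(gr), 0, p$jitter_p))
      st <- pmax(1L, start(gr) + as.integer(shift_bp))
      peak_collection(GRanges(seqnames(gr), IRanges(st, width = width(gr))),
                      neglog10_p = pj, assay = assay, factor = factor,
                      tissue = tissue, replicate = rep_i)
    }
    a_regions <- truth[mcols(truth)$class %in% c("A_only", "both")]
    b_regions <- truth[mcols(truth)$class %in% c("B_only", "both")]
    reps_a <- lapply(seq_len(p$n_reps), function(i)
      jittered(a_regions, i, "PBX1", "TF-ChIP"))
    reps_b <- lapply(seq_len(p$n_reps), function(i)
      jittered(b_regions, i, "HAND2", "TF-ChIP"))
    mark_regions <- truth
    mcols(mark_regions)$true_p <- pmax(0, rnorm(length(truth), p$mark_p_mean,
                                                p$mark_p_sd)) +
      ifelse(mcols(truth)$class == "both", p$cobound_signal_shift, 0)
    atac_reps <- lapply(seq_len(p$n_atac_reps), function(i)
      jittered(mark_regions, i, "ATAC", "ATAC"))
    mcols(mark_regions)$true_p <- pmax(0, rnorm(length(truth), p$mark_p_mean,
                                                p$mark_p_sd)) +
      ifelse(mcols(truth)$class == "both", p$cobound_signal_shift, 0)
    h3k27ac_reps <- lapply(seq_len(p$n_reps), function(i)
      jittered(mark_regions, i, "H3K27ac", "histone-ChIP"))
    list(reps_a = reps_a, reps_b = reps_b, atac_reps = atac_reps,
         h3k27ac_reps = h3k27ac_reps, truth = truth)
  })
}

#' Generate two synthetic DEG tables with planted concordance classes
#'
#' Gene classes are assigned deterministically in gene-id order
#' (concordant-up first, then concordant-down, discordant, single-contrast,
#' undetected, null); per-gene statistics are drawn so that planted classes
#' pass the downstream thresholds (|log2FC| >= `lfc_min` > log2(1.2),
#' FDR <= 0.05) in the designated contrasts and null genes fail at least one
#' threshold. `undetected` genes are significant in both contrasts but
#' flagged as not detected in all replicates, exercising the universe
#' restriction.
#'
#' @param cfg A [sim_config()].
#' @return A list with `table_a`, `table_b` (DEG `data.frame`s) and `truth`.
#' @export
gen_deg_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$deg_plan
  truth <- deg_truth_classes(cfg)
  n <- nrow(truth)
  with_seed(cfg$seed + 303L, {
    draw_sig <- function(k, sign) {
      lfc <- sign * runif(k, d$lfc_min, d$lfc_max)
      data.frame(log2fc = lfc, fdr = runif(k, 0, 0.04))
    }
    draw_null <- function(k) {
      # fail on effect size, significance, or both
      mode <- sample(3, k, replace = TRUE)
      lfc <- ifelse(mode == 2, runif(k, 0.3, 1.5) * sample(c(-1, 1), k, TRUE),
                    runif(k, -0.15, 0.15))
      fdr <- ifelse(mode == 1, runif(k, 0, 0.04), runif(k, 0.2, 1))
      data.frame(log2fc = lfc, fdr = fdr)
    }
    stats_for <- function(contrast) {
      out <- data.frame(log2fc = numeric(n), fdr = numeric(n))
      for (cls in unique(truth$class)) {
        i <- which(truth$class == cls)
        k <- length(i)
        out[i, ] <- switch(cls,
          concordant_up = draw_sig(k, +1),
          concordant_down = draw_sig(k, -1),
          discordant = {
            s <- rep_len(c(+1, -1), k)
            if (contrast == "b") s <- -s
            data.frame(log2fc = s * runif(k, d$lfc_min, d$lfc_max),
                       fdr = runif(k, 0, 0.04))
          },
          a_only = if (contrast == "a") draw_sig(k, sample(c(-1, 1), k, TRUE))
                   else draw_null(k),
          b_only = if (contrast == "b") draw_sig(k, sample(c(-1, 1), k, TRUE))
                   else draw_null(k),
          undetected = draw_sig(k, +1),
          null = draw_null(k))
      }
      out
    }
    sa <- stats_for("a")
    sb <- stats_for("b")
    detected <- truth$class != "undetected"
    table_a <- data.frame(gene_id = truth$gene_id, log2fc = sa$log2fc,
                          fdr = sa$fdr, detected_all_reps = detected)
    table_b <- data.frame(gene_id = truth$gene_id, log2fc = sb$log2fc,
                          fdr = sb$fdr, detected_all_reps = detected)
    list(table_a = table_a, table_b = table_b, truth = truth)
  })
}

#' Generate a synthetic single-cell UMI matrix
#'
#' Negative-binomial counts over three clusters (two mesenchymal, one
#' epithelial), each with its own marker genes. Within the posterior
#' mesenchymal cluster a configurable fraction of cells is double-positive
#' (nonzero `Hand2` plus `Pbx1`/`Pbx2`); planted target genes are elevated by
#' `target_effect` log-units in those cells. `Prrx1` is planted as a
#' pan-mesenchymal marker. A few cells are planted to fail each QC rule.
#'
#' @param cfg A [sim_config()].
#' @return A list with `sce` (a `SingleCellExperiment`) and `truth`
#'   (per-cell cluster / double-positive / QC-failure labels and the planted
#'   target gene ids).
#' @export
gen_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- cfg$sc_plan
  with_seed(cfg$seed + 404L, {
    clusters <- rep(names(s$cells), s$cells)
    n_cells <- length(clusters)
    targets <- sprintf("target_%d", seq_len(s$n_targets))
    mito <- sprintf("mt-%d", seq_len(s$n_mito))
    special <- c("Pbx1", "Pbx2", "Hand2", "Prrx1", targets, mito)
    n_bg <- s$n_genes - length(special)
    if (n_bg < 3 * s$marker_genes)
      stop("sc_plan$n_genes too small for the planted gene structure")
    bg <- sprintf("bg_%03d", seq_len(n_bg))
    genes <- c(special, bg)
    base <- stats::rlnorm(length(genes), meanlog = log(s$base_mean), sdlog = 0.6)
    names(base) <- genes
    base[mito] <- s$base_mean * 0.6           # ~6% mitochondrial mass
    base[c("Pbx1", "Pbx2")] <- s$base_mean * 2
    base[c("Hand2", "Prrx1")] <- s$base_mean * 2
    base[targets] <- s$base_mean
    mean_mat <- matrix(base, nrow = length(genes), ncol = n_cells,
                       dimnames = list(genes, sprintf("cell_%04d", seq_len(n_cells))))
    # cluster-specific markers from the background pool
    marker_sets <- split(bg[seq_len(3 * s$marker_genes)],
                         rep(names(s$cells), each = s$marker_genes))
    for (cl in names(s$cells))
      mean_mat[marker_sets[[cl]], clusters != cl] <-
        mean_mat[marker_sets[[cl]], clusters != cl] / s$marker_fold
    is_mes <- clusters %in% c("mes_posterior", "mes_other")
    mean_mat["Prrx1", !is_mes] <- 0.05
    mean_mat[c("Pbx1", "Pbx2"), !is_mes] <- s$base_mean * 0.2
    dp <- rep(FALSE, n_cells)
    post <- which(clusters == "mes_posterior")
    dp[post[seq_len(round(s$dp_fraction * length(post)))]] <- TRUE
    mean_mat["Hand2", !dp] <- 0.02
    mean_mat["Hand2", dp] <- s$base_mean * 3
    mean_mat[targets, dp] <- mean_mat[targets, dp] * exp(s$target_effect)
    counts <- matrix(rnbinom(length(mean_mat), mu = mean_mat, size = s$nb_size),
                     nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
    qc_reason <- rep("pass", n_cells)
    ord <- sample(which(!dp & clusters != "mes_posterior"))
    low <- ord[seq_len(s$qc_low_umi)]
    high <- ord[s$qc_low_umi + seq_len(s$qc_high_umi)]
    himito <- ord[s$qc_low_umi + s$qc_high_umi + seq_len(s$qc_high_mito)]
    for (i in low) {  # thin to well below the minimum-UMI bound
      tot <- sum(counts[, i])
      counts[, i] <- rbinom(nrow(counts), counts[, i],
                            min(1, 0.5 * s$qc_min_total / tot))
    }
    for (i in high) counts[, i] <- counts[, i] *
      ceiling(1.2 * s$qc_max_total / sum(counts[, i]))
    for (i in himito) {
      tot <- sum(counts[, i])
      counts[mito, i] <- counts[mito, i] +
        ceiling(2.5 * s$qc_max_mito * tot / length(mito))
    }
    qc_reason[low] <- "low_umi"; qc_reason[high] <- "high_umi"
    qc_reason[himito] <- "high_mito"
    sce <- cell_matrix(counts, mito = genes %in% mito, clusters = clusters)
    truth <- list(cells = data.frame(cell_id = colnames(counts),
                                     cluster = clusters, double_positive = dp,
                                     qc = qc_reason),
                  targets = targets,
                  mesenchymal_marker = "Prrx1")
    list(sce = sce, truth = truth)
  })
}

#' Generate a synthetic enhancer landscape inside one TAD
#'
#' Plants `n_pass` TF peaks satisfying every prioritization filter (fold
#' enrichment >= `min_fold`, distal, H3K27ac-marked, accessible, conserved)
#' and `n_fail` peaks each violating exactly one filter, cycling through the
#' five failure modes.
#'
#' @param cfg A [sim_config()].
#' @return A list with `tad`, `tf_peaks`, `h3k27ac`, `atac`, `conserved`,
#'   `genes` (the target gene whose promoter is excluded), and `truth`
#'   (per-candidate pass flag and failure mode).
#' @export
gen_enhancer_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  e <- cfg$enhancer_plan
  with_seed(cfg$seed + 505L, {
    tad <- GRanges("chrE", IRanges(1, 1000000))
    mcols(tad)$tad_id <- "tad_target"
    gene <- gene_models(GRanges("chrE", IRanges(800001, 808000), strand = "+"),
                        "Hand2")
    n <- e$n_pass + e$n_fail
    start <- 10000 + (seq_len(n) - 1L) * 30000
    cand <- GRanges("chrE", IRanges(start, width = 400))
    mode <- c(rep("pass", e$n_pass),
              rep_len(c("low_fold", "promoter", "no_h3k27ac", "no_atac",
                        "no_conserved"), e$n_fail))
    fold <- ifelse(mode == "low_fold", runif(n, 5, 14.9), runif(n, 15, 40))
    # promoter-failure candidates are moved onto the target gene's TSS window
    cand[mode == "promoter"] <-
      GRanges("chrE", IRanges(rep(800001 - 200, sum(mode == "promoter")) +
                                seq_len(sum(mode == "promoter")) - 1L,
                              width = 400))
    tf_peaks <- peak_collection(cand, neglog10_p = runif(n, 15, 30),
                                fold_enrichment = fold,
                                name = sprintf("cand_%02d", seq_len(n)),
                                factor = "PBX1", tissue = "HL")
    over <- function(keep) {
      gr <- cand[keep]
      peak_collection(GenomicRanges::resize(gr, 600, fix = "center"),
                      neglog10_p = runif(sum(keep), 5, 20),
                      assay = "histone-ChIP", factor = "H3K27ac")
    }
    h3k27ac <- over(mode != "no_h3k27ac")
    atac <- over(mode != "no_atac")
    metadata(atac)$assay <- "ATAC"
    conserved <- granges(cand[mode != "no_conserved"])
    truth <- data.frame(name = sprintf("cand_%02d", seq_len(n)), mode = mode,
                        passes = mode == "pass")
    # sort order of tf_peaks differs from construction order; align truth
    truth <- truth[match(mcols(tf_peaks)$name, truth$name), ]
    rownames(truth) <- NULL
    list(tad = tad, tf_peaks = tf_peaks, h3k27ac = h3k27ac, atac = atac,
         conserved = conserved, genes = gene, truth = truth)
  })
}

#' Generate synthetic cross-tissue cistromes and a signal table
#'
#' Three tissue cistromes share a planted common core; two cofactor
#' cistromes are placed so that each cofactor peak overlaps the promiscuous
#' factor's regions at the planted per-tissue rates (e.g. 48% in HL vs 18%
#' in MF for the HAND2-like cofactor). A per-region normalized signal table
#' carries a planted +`signal_shift` median log2FC at cofactor-co-bound
#' regions.
#'
#' @param cfg A [sim_config()].
#' @return A list with `pbx` (per-tissue collections), `hand2`, `hoxa2`
#'   cofactor collections, `signal_table`, and `truth` planted rates.
#' @export
gen_cross_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ct <- cfg$cross_tissue_plan
  with_seed(cfg$seed + 606L, {
    width <- 300L
    n_core <- round(ct$core_fraction * ct$n_per_tissue)
    n_spec <- ct$n_per_tissue - n_core
    n_free <- 2L * ct$n_cofactor
    n_slots <- n_core + 3L * n_spec + n_free
    slots <- place_regions(n_slots, cfg$genome, width = width)
    core <- slots[seq_len(n_core)]
    spec <- split(slots[n_core + seq_len(3L * n_spec)],
                  rep(ct$tissues, each = n_spec))
    free <- slots[(n_core + 3L * n_spec) + seq_len(n_free)]
    pbx <- lapply(ct$tissues, function(tis)
      peak_collection(c(core, spec[[tis]]),
                      neglog10_p = runif(ct$n_per_tissue, 8, 30),
                      factor = "PBX1", tissue = tis))
    names(pbx) <- ct$tissues
    centered_in <- function(gr) {
      GRanges(seqnames(gr),
              IRanges(start(gr) + (width(gr) - 100L) %/% 2L, width = 100L))
    }
    place_cofactor <- function(rate_shared, rate_primary_only, n) {
      # exact-count planting: round(rate * n) peaks on core regions (overlap
      # both tissues' sets), round(rate_primary_only * n) on the primary
      # tissue's specific regions, the rest in free space; positions are
      # shuffled so category carries no positional order
      n_sh <- round(rate_shared * n)
      n_pr <- round(rate_primary_only * n)
      cat_vec <- sample(rep(c("core", "primary", "off"),
                            c(n_sh, n_pr, n - n_sh - n_pr)))
      list(on_core = cat_vec == "core", on_primary = cat_vec == "primary",
           off = cat_vec == "off")
    }
    build_cofactor <- function(primary, secondary, rates, factor_name, free_pool) {
      n <- ct$n_cofactor
      arr <- place_cofactor(rates[2], rates[1] - rates[2], n)
      parts <- list()
      if (any(arr$on_core))
        parts <- c(parts, list(centered_in(core[sample.int(n_core, sum(arr$on_core))])))
      if (any(arr$on_primary))
        parts <- c(parts, list(centered_in(spec[[primary]][
          sample.int(n_spec, sum(arr$on_primary), replace = TRUE)])))
      if (any(arr$off))
        parts <- c(parts, list(centered_in(free_pool[sample.int(length(free_pool),
                                                                sum(arr$off))])))
      pos <- suppressWarnings(do.call(c, parts))
      peak_collection(pos, neglog10_p = runif(n, 8, 30),
                      factor = factor_name, tissue = primary)
    }
    hand2 <- build_cofactor("HL", "MF", ct$hand2_rates, "HAND2",
                            free[seq_len(ct$n_cofactor)])
    hoxa2 <- build_cofactor("BA2", "HL", ct$hoxa2_rates, "HOXA2",
                            free[ct$n_cofactor + seq_len(ct$n_cofactor)])
    n_sig <- ct$n_signal
    base_hl <- stats::rlnorm(2 * n_sig, log(20), 0.5)
    base_ba2 <- stats::rlnorm(2 * n_sig, log(20), 0.5)
    subset_label <- rep(c("cofactor_cobound", "other"), each = n_sig)
    base_hl[subset_label == "cofactor_cobound"] <-
      base_hl[subset_label == "cofactor_cobound"] * 2^ct$signal_shift
    if (2 * n_sig > n_slots) stop("n_signal too large for the slot pool")
    sig_regions <- slots[seq_len(2 * n_sig)]
    signal_table <- data.frame(chrom = as.character(seqnames(sig_regions)),
                               start = start(sig_regions), end = end(sig_regions),
                               HL = base_hl, BA2 = base_ba2,
                               subset_label = subset_label)
    list(pbx = pbx, hand2 = hand2, hoxa2 = hoxa2, signal_table = signal_table,
         truth = list(hand2_rates = ct$hand2_rates, hoxa2_rates = ct$hoxa2_rates,
                      core_fraction = ct$core_fraction,
                      signal_shift = ct$signal_shift))
  })
}

#' Write a full synthetic data set to standard-format files
#'
#' Emits every generator's output in the format the pipeline readers consume
#' (narrowPeak, BED, GFF3, MTX + TSV, TSV tables), plus sidecar `truth_*.tsv`
#' files carrying the planted labels. Byte-identical across runs for a fixed
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  ann <- gen_genome(cfg)
  gff <- data.frame(seqid = as.character(seqnames(ann$genes)), source = "sim",
                    type = "gene", start = start(ann$genes), end = end(ann$genes),
                    score = ".", strand = as.character(strand(ann$genes)),
                    phase = ".",
                    attributes = paste0("ID=", ann$genes$gene_id, ";gene_id=",
                                        ann$genes$gene_id))
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), fp("genes.gff3"))
  bed_out <- function(gr, path, name = ".") {
    utils::write.table(data.frame(as.character(seqnames(gr)), start(gr) - 1L,
                                  end(gr), name),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  bed_out(ann$tads, fp("tads.bed"), ann$tads$tad_id)
  bed_out(ann$conserved, fp("conserved.bed"))
  pk <- gen_peaksets(cfg, ann)
  for (i in seq_along(pk$reps_a))
    write_peaks(pk$reps_a[[i]], fp(sprintf("pbx1_rep%d.narrowPeak", i)))
  for (i in seq_along(pk$reps_b))
    write_peaks(pk$reps_b[[i]], fp(sprintf("hand2_rep%d.narrowPeak", i)))
  for (i in seq_along(pk$atac_reps))
    write_peaks(pk$atac_reps[[i]], fp(sprintf("atac_rep%d.narrowPeak", i)))
  for (i in seq_along(pk$h3k27ac_reps))
    write_peaks(pk$h3k27ac_reps[[i]], fp(sprintf("h3k27ac_rep%d.narrowPeak", i)))
  utils::write.table(data.frame(chrom = as.character(seqnames(pk$truth)),
                                start = start(pk$truth) - 1L, end = end(pk$truth),
                                class = pk$truth$class),
                     fp("truth_regions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dg <- gen_deg_tables(cfg)
  utils::write.table(dg$table_a, fp("deg_pbx.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dg$table_b, fp("deg_hand2.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dg$truth, fp("truth_deg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- gen_sc_counts(cfg)
  write_cell_matrix(sc$sce, fp("sc_counts.mtx"), fp("sc_genes.tsv"),
                    fp("sc_barcodes.tsv"))
  utils::write.table(sc$truth$cells, fp("truth_sc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sc$truth$targets, fp("truth_sc_targets.txt"))
  invisible(dir)
}
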