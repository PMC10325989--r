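# End-to-end orchestration: consensus -> co-binding partition -> chromatin
# overlay -> DEG integration -> single-cell co-expression -> enhancer
# prioritization -> TAD scoring -> cross-tissue analysis, on synthetic input
# with planted truth, producing a machine-readable run report.

#' Pipeline run configuration
#'
#' Thresholds default to the values the analysis is built around: weak/
#' stringent consensus thresholds 1e-6 / 1e-10, linear fold-change cutoff
#' 1.2 at FDR 0.05, co-expression AUC cutoff 0.55, enhancer fold-enrichment
#' cutoff 15, single-cell QC bounds 3000-25,000 UMI / 1000 genes / <10%
#' mitochondrial, and a clustering resolution grid of 0.2-2.0 in steps of
#' 0.1.
#'
#' @param seed Master seed for the synthetic inputs and seeded stages.
#' @param sim A [sim_config()]; defaults to `sim_config(seed)`.
#' @param stringent_p,weak_p,min_replicates Consensus settings.
#' @param fc_min,fdr_max DEG thresholds.
#' @param auc_min Co-expression AUC threshold.
#' @param min_fold Enhancer fold-enrichment threshold.
#' @param promoter_halfwidth_bp Promoter window half-width.
#' @param qc A [qc_thresholds()].
#' @param resolutions Clustering resolution grid.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 0L, sim = sim_config(seed),
                       stringent_p = 1e-10, weak_p = 1e-6, min_replicates = 2L,
                       fc_min = 1.2, fdr_max = 0.05, auc_min = 0.55,
                       min_fold = 15, promoter_halfwidth_bp = 2000L,
                       qc = qc_thresholds(),
                       resolutions = seq(0.2, 2.0, by = 0.1)) {
  if (fc_min <= 1) stop("fc_min must exceed 1 (linear fold change)")
  if (fdr_max <= 0 || fdr_max >= 1) stop("fdr_max must lie in (0, 1)")
  if (auc_min < 0.5 || auc_min > 1) stop("auc_min must lie in [0.5, 1]")
  if (min_fold <= 0) stop("min_fold must be positive")
  structure(list(seed = as.integer(seed), sim = sim,
                 consensus = consensus_config(stringent_p = stringent_p,
                                              weak_p = weak_p,
                                              min_replicates = min_replicates),
                 fc_min = fc_min, fdr_max = fdr_max, auc_min = auc_min,
                 min_fold = min_fold,
                 promoter_halfwidth_bp = as.integer(promoter_halfwidth_bp),
                 qc = qc, resolutions = resolutions),
            class = "run_config")
}

#' Run the full pipeline on synthetic input
#'
#' Generates every input from the configured [sim_config()], executes the
#' stages in dependency order, and returns a run report recording per-stage
#' counts, the thresholds used, and the seed. If a stage fails its error is
#' recorded and downstream stages are skipped. The report carries no
#' timestamps, so identical configurations produce identical reports.
#'
#' @param cfg A [run_config()].
#' @param out Optional path; when given the report is written there as JSON.
#' @return The run report (a nested list), invisibly when `out` is given.
#' @export
run_pipeline <- function(cfg = run_config(), out = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("limbGRN")),
                 thresholds = list(
                   stringent_p = cfg$consensus$stringent_p,
                   weak_p = cfg$consensus$weak_p,
                   min_replicates = cfg$consensus$min_replicates,
                   fc_min = cfg$fc_min, fdr_max = cfg$fdr_max,
                   auc_min = cfg$auc_min, min_fold = cfg$min_fold,
                   promoter_halfwidth_bp = cfg$promoter_halfwidth_bp),
                 stages = list())
  state <- new.env(parent = emptyenv())
  failed <- FALSE
  stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     cause = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
  }

  stage("simulate", function() {
    state$ann <- gen_genome(cfg$sim)
    state$pk <- gen_peaksets(cfg$sim, state$ann)
    state$dg <- gen_deg_tables(cfg$sim)
    state$sc <- gen_sc_counts(cfg$sim)
    state$enh <- gen_enhancer_landscape(cfg$sim)
    state$ct <- gen_cross_tissue(cfg$sim)
    list(n_genes = length(state$ann$genes), n_tads = length(state$ann$tads),
         n_regions_planted = length(state$pk$truth))
  })

  stage("consensus", function() {
    state$cons_a <- consensus_replicates(state$pk$reps_a, cfg$consensus)
    state$cons_b <- consensus_replicates(state$pk$reps_b, cfg$consensus)
    atac_cfg <- cfg$consensus
    atac_cfg$min_replicates <- min(atac_cfg$min_replicates,
                                   length(state$pk$atac_reps))
    state$cons_atac <- consensus_replicates(state$pk$atac_reps, atac_cfg)
    state$cons_ac <- consensus_replicates(state$pk$h3k27ac_reps, cfg$consensus)
    list(peaks_in_a = sum(lengths(state$pk$reps_a)),
         consensus_a = length(state$cons_a),
         peaks_in_b = sum(lengths(state$pk$reps_b)),
         consensus_b = length(state$cons_b),
         consensus_atac = length(state$cons_atac),
         consensus_h3k27ac = length(state$cons_ac))
  })

  stage("classify", function() {
    part <- partition_cobinding(state$cons_a, state$cons_b)
    mcols(part)$context <- assign_context(part, state$ann$genes,
                                          cfg$promoter_halfwidth_bp)
    part <- annotate_chromatin(part, list(atac = state$cons_atac,
                                          h3k27ac = state$cons_ac))
    state$partition <- part
    kw <- compare_classes(split(mcols(part)$signal_atac, mcols(part)$class),
                          test = "kruskal_wallis")
    summ <- partition_summary(part)
    c(summ, list(context = as.list(table(mcols(part)$context)),
                 atac_kruskal_p = kw$p_value))
  })

  stage("integrate_degs", function() {
    da <- filter_degs(state$dg$table_a, cfg$fc_min, cfg$fdr_max)
    db <- filter_degs(state$dg$table_b, cfg$fc_min, cfg$fdr_max)
    universe <- intersect(
      state$dg$table_a$gene_id[state$dg$table_a$detected_all_reps],
      state$dg$table_b$gene_id[state$dg$table_b$detected_all_reps])
    state$shared <- intersect_contrasts(da, db, universe)
    c(list(degs_a = nrow(da), degs_b = nrow(db)),
      lapply(unclass(state$shared), length))
  })

  stage("sc_coexpression", function() {
    sce <- qc_filter(state$sc$sce, cfg$qc)
    sce <- log_normalize(sce)
    sel <- select_resolution(sce, resolutions = cfg$resolutions, seed = cfg$seed)
    labels <- sel$labels
    # mesenchymal clusters: those expressing the pan-mesenchymal marker
    marker <- state$sc$truth$mesenchymal_marker
    cl_means <- vapply(split(seq_len(ncol(sce)), labels), function(i)
      mean(logcounts(sce)[marker, i]), numeric(1))
    mes_clusters <- names(cl_means)[cl_means >= 0.5 * max(cl_means)]
    mes_cells <- colnames(sce)[as.character(labels) %in% mes_clusters]
    sce_mes <- sce[, mes_cells]
    dp <- double_positive_cells(sce_mes)
    bg <- setdiff(mes_cells, dp)
    auc <- vapply(rownames(sce_mes), function(g)
      coexpression_auc(sce_mes, g, dp, bg)$auc, numeric(1))
    state$auc <- auc
    targets <- state$sc$truth$targets
    state$sc_pass <- names(auc)[auc >= cfg$auc_min]
    null_genes <- setdiff(names(auc), c(targets, "Hand2", "Pbx1", "Pbx2"))
    list(cells_pass_qc = ncol(sce), resolution = sel$resolution,
         n_clusters = length(unique(labels)),
         n_mesenchymal_cells = length(mes_cells),
         n_double_positive = length(dp),
         targets_pass_auc = sum(auc[targets] >= cfg$auc_min),
         n_targets = length(targets),
         null_below_auc_frac = mean(auc[null_genes] < cfg$auc_min))
  })

  stage("enhancers", function() {
    enh <- state$enh
    cand <- prioritize_enhancers(enh$tad, enh$tf_peaks, enh$h3k27ac, enh$atac,
                                 enh$conserved, enh$genes,
                                 min_fold = cfg$min_fold,
                                 promoter_halfwidth_bp = cfg$promoter_halfwidth_bp)
    truth_pass <- enh$truth$passes
    state$candidates <- cand
    list(candidates = nrow(cand), passing = sum(cand$passes),
         precision = if (sum(cand$passes))
           sum(cand$passes & truth_pass) / sum(cand$passes) else NA,
         recall = if (sum(truth_pass))
           sum(cand$passes & truth_pass) / sum(truth_pass) else NA)
  })

  stage("tad_scores", function() {
    tads <- state$ann$tads
    shared_genes <- unlist(state$shared[c("concordant_up", "concordant_down",
                                          "discordant")], use.names = FALSE)
    deg_tad_ids <- unique(state$ann$gene_tad$tad_id[
      state$ann$gene_tad$gene_id %in% shared_genes])
    scores <- lapply(seq_along(tads), function(i)
      tad_regulatory_score(tads[i], list(state$cons_a, state$cons_b),
                           state$ann$genes, cfg$promoter_halfwidth_bp))
    is_deg <- tads$tad_id %in% deg_tad_ids
    cmp <- compare_tad_scores(scores[is_deg], scores[!is_deg])
    list(n_deg_tads = sum(is_deg), n_other_tads = sum(!is_deg),
         strength_p = cmp$strength$p_value, count_p = cmp$count$p_value)
  })

  stage("cross_tissue", function() {
    ct <- state$ct
    ov <- multi_tissue_overlap(ct$pbx)
    f_hl <- cofactor_selection_fraction(ct$pbx$HL, ct$hand2)
    f_mf <- cofactor_selection_fraction(ct$pbx$MF, ct$hand2)
    f_ba2 <- cofactor_selection_fraction(ct$pbx$BA2, ct$hoxa2)
    f_hl_hox <- cofactor_selection_fraction(ct$pbx$HL, ct$hoxa2)
    lfc <- signal_log2fc(ct$signal_table, "HL", "BA2")
    list(per_tissue = as.list(ov$per_tissue),
         shared_fraction_of = as.list(ov$shared_fraction_of),
         hand2_fraction_hl = f_hl$fraction, hand2_fraction_mf = f_mf$fraction,
         hoxa2_fraction_ba2 = f_ba2$fraction, hoxa2_fraction_hl = f_hl_hox$fraction,
         signal_mw_p = lfc$comparison$p_value)
  })

  report$audit <- audit_report(report)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Audit a run report for internal consistency
#'
#' Checks the bookkeeping identities that must hold on every run: partition
#' class counts sum to the merged total, the shared-DEG classes are disjoint
#' pieces of the significant sets, and the enhancer pass count never exceeds
#' the candidate count.
#'
#' @param report A [run_pipeline()] report.
#' @return A list with `consistent` (logical) and any `problems`.
#' @export
audit_report <- function(report) {
  problems <- character(0)
  st <- report$stages
  ok <- function(x) !is.null(x) && identical(x$status, "ok")
  if (ok(st$classify)) {
    if (st$classify$A_only + st$classify$B_only + st$classify$both !=
        st$classify$total)
      problems <- c(problems, "partition class counts do not sum to total")
    if (sum(unlist(st$classify$context)) != st$classify$total)
      problems <- c(problems, "context counts do not sum to total")
  }
  if (ok(st$integrate_degs)) {
    with(st$integrate_degs, {
      if (concordant_up + concordant_down + discordant + a_only > degs_a ||
          concordant_up + concordant_down + discordant + b_only > degs_b)
        problems <<- c(problems, "shared classes exceed per-contrast DEG counts")
    })
  }
  if (ok(st$enhancers) && st$enhancers$passing > st$enhancers$candidates)
    problems <- c(problems, "more passing enhancers than candidates")
  list(consistent = length(problems) == 0, problems = as.list(problems))
}
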