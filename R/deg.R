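# Differential-expression integration across two mutant-genotype contrasts:
# threshold each contrast, restrict to genes detected in all replicates of
# both experiments, and classify the shared targets as concordant or
# discordant between the two regulators.

#' Read a differential-expression table
#'
#' Expects a tab-separated file with header columns `gene_id`, `log2fc`,
#' `fdr`, `detected_all_reps`.
#'
#' @param path File path.
#' @return A `data.frame` with those four columns.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "log2fc", "fdr", "detected_all_reps")
  if (!all(needed %in% names(df)))
    stop("DEG table must have columns: ", paste(needed, collapse = ", "))
  df$detected_all_reps <- as.logical(df$detected_all_reps)
  df[needed]
}

#' Threshold a DEG table
#'
#' A gene is differentially expressed when its linear fold change is at least
#' `fc_min` in either direction (|log2fc| >= log2(fc_min), boundary inclusive)
#' and its BH-adjusted p-value is at most `fdr_max`.
#'
#' @param table A `data.frame` with `gene_id`, `log2fc`, `fdr` columns.
#' @param fc_min Minimum linear fold change (> 1; default 1.2).
#' @param fdr_max Maximum FDR (default 0.05).
#' @return A `data.frame` of retained genes with a `sign` column (+1/-1).
#' @export
filter_degs <- function(table, fc_min = 1.2, fdr_max = 0.05) {
  stopifnot(fc_min > 1, fdr_max > 0, fdr_max < 1)
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene_id in DEG table: ",
         table$gene_id[duplicated(table$gene_id)][1])
  if (any(table$fdr < 0 | table$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  keep <- !is.na(table$log2fc) & !is.na(table$fdr) &
    abs(table$log2fc) >= log2(fc_min) & table$fdr <= fdr_max
  out <- table[keep, , drop = FALSE]
  out$sign <- ifelse(out$log2fc > 0, 1L, -1L)
  rownames(out) <- NULL
  out
}

#' Intersect two DEG contrasts into a shared target set
#'
#' Restricts both significant sets to a detection universe (genes detected in
#' all replicates of both experiments), then classifies each gene by its sign
#' pair: up in both contrasts -> `concordant_up`; down in both ->
#' `concordant_down`; opposite signs -> `discordant`; significant in one
#' contrast only -> `a_only` / `b_only`. The five sets are pairwise disjoint.
#'
#' @param degs_a,degs_b Outputs of [filter_degs()] for the two contrasts.
#' @param universe Character vector of gene ids detected in all replicates of
#'   both experiments.
#' @return A list of class `shared_target_set` with the five gene-id sets.
#' @export
intersect_contrasts <- function(degs_a, degs_b, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  a <- degs_a[degs_a$gene_id %in% universe, ]
  b <- degs_b[degs_b$gene_id %in% universe, ]
  sign_a <- stats::setNames(a$sign, a$gene_id)
  sign_b <- stats::setNames(b$sign, b$gene_id)
  shared <- intersect(a$gene_id, b$gene_id)
  concordant_up <- shared[sign_a[shared] > 0 & sign_b[shared] > 0]
  concordant_down <- shared[sign_a[shared] < 0 & sign_b[shared] < 0]
  discordant <- shared[sign_a[shared] * sign_b[shared] < 0]
  structure(list(concordant_up = sort(concordant_up),
                 concordant_down = sort(concordant_down),
                 discordant = sort(discordant),
                 a_only = sort(setdiff(a$gene_id, shared)),
                 b_only = sort(setdiff(b$gene_id, shared))),
            class = "shared_target_set")
}

#' Regulatory semantics of a shared target set
#'
#' Reads the sign pairs as regulation by the two factors: genes up in both
#' mutants are repressed by both factors in the wild type; genes down in both
#' are positively regulated by both; opposite signs are discordantly
#' regulated.
#'
#' @param shared A [intersect_contrasts()] result.
#' @return Named character vector, one regulatory label per shared gene.
#' @export
regulation_semantics <- function(shared) {
  stopifnot(inherits(shared, "shared_target_set"))
  c(stats::setNames(rep("repressed by both", length(shared$concordant_up)),
                    shared$concordant_up),
    stats::setNames(rep("positively regulated by both", length(shared$concordant_down)),
                    shared$concordant_down),
    stats::setNames(rep("discordantly regulated", length(shared$discordant)),
                    shared$discordant))
}

#' Write a shared target set as TSV
#'
#' @param shared A [intersect_contrasts()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_targets <- function(shared, path) {
  stopifnot(inherits(shared, "shared_target_set"))
  df <- do.call(rbind, lapply(names(shared), function(cls) {
    if (!length(shared[[cls]])) return(NULL)
    data.frame(gene_id = shared[[cls]], class = cls)
  }))
  if (is.null(df)) df <- data.frame(gene_id = character(0), class = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
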