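# Cross-tissue binding-specificity analysis: how much of a promiscuous
# factor's cistrome is shared across embryonic tissues, which fraction a
# tissue-restricted cofactor selects, and how normalized binding signal
# shifts between tissues at cofactor-co-bound regions.

#' Multi-tissue cistrome overlap summary
#'
#' Builds the merged-region universe over all tissues' peak collections and
#' computes Venn-region counts from each merged region's tissue-membership
#' pattern. Also reports, per tissue, the fraction of that tissue's peaks
#' overlapping the common core (regions present in every tissue).
#'
#' @param peaksets Named list (>= 2 entries) of peak collections, one per
#'   tissue.
#' @param min_overlap_bp Minimum overlap in bases (default 1).
#' @return A list with `per_tissue` peak counts, `venn` (named by
#'   membership pattern, e.g. `"HL+MF"`), `core_regions`, and
#'   `shared_fraction_of` per tissue.
#' @export
multi_tissue_overlap <- function(peaksets, min_overlap_bp = 1L) {
  stopifnot(is.list(peaksets), length(peaksets) >= 2, !is.null(names(peaksets)))
  empty <- names(peaksets)[lengths(peaksets) == 0]
  if (length(empty))
    warning("empty peak collection(s): ", paste(empty, collapse = ", "))
  universe <- muffle_seqinfo(reduce(do.call(c, unname(lapply(peaksets, granges))),
                                    ignore.strand = TRUE))
  membership <- vapply(peaksets, function(p)
    muffle_seqinfo(overlapsAny(universe, p, minoverlap = as.integer(min_overlap_bp),
                               ignore.strand = TRUE)), logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(peaksets)))
  pattern <- apply(membership, 1, function(m)
    paste(names(peaksets)[m], collapse = "+"))
  core <- rowSums(membership) == length(peaksets)
  core_regions <- universe[core]
  shared_fraction <- vapply(peaksets, function(p) {
    if (!length(p)) return(0)
    sum(muffle_seqinfo(overlapsAny(p, core_regions,
                                   minoverlap = as.integer(min_overlap_bp),
                                   ignore.strand = TRUE))) / length(p)
  }, numeric(1))
  list(per_tissue = lengths(peaksets),
       venn = table(pattern),
       core_regions = sum(core),
       shared_fraction_of = shared_fraction)
}

#' Cofactor selection fraction
#'
#' The fraction of a cofactor's peaks that overlap at least one peak of the
#' promiscuous factor: numerator and denominator are reported alongside the
#' fraction so the alternative (factor-peak) denominator can be audited.
#'
#' @param pbx Peak collection of the promiscuous factor.
#' @param cofactor Peak collection of the cofactor (non-empty).
#' @param min_overlap_bp Minimum overlap in bases (default 1).
#' @return A list with `fraction`, `n_overlapping`, `n_cofactor`,
#'   `n_factor_overlapping` (factor peaks touched by the cofactor).
#' @export
cofactor_selection_fraction <- function(pbx, cofactor, min_overlap_bp = 1L) {
  if (!length(cofactor)) stop("cofactor collection is empty")
  if (!length(pbx)) stop("factor collection is empty")
  hit <- muffle_seqinfo(overlapsAny(cofactor, pbx,
                                    minoverlap = as.integer(min_overlap_bp),
                                    ignore.strand = TRUE))
  rev_hit <- muffle_seqinfo(overlapsAny(pbx, cofactor,
                                        minoverlap = as.integer(min_overlap_bp),
                                        ignore.strand = TRUE))
  list(fraction = mean(hit), n_overlapping = sum(hit),
       n_cofactor = length(cofactor), n_factor_overlapping = sum(rev_hit))
}

#' Per-region signal log2 fold change between tissues
#'
#' `log2((signal_a + pseudocount) / (signal_b + pseudocount))` per region,
#' plus a two-sided Mann-Whitney comparison of the log2FC distribution
#' between the region subsets (e.g. cofactor-co-bound vs other regions).
#'
#' @param table A `data.frame` with columns `chrom`, `start`, `end`,
#'   per-tissue signal columns, and `subset_label`.
#' @param tissue_a,tissue_b Names of the two signal columns.
#' @param pseudocount Added to both signals to guard zeros (default 1).
#' @return A list with `log2fc` (the input table plus a `log2fc` column) and
#'   `comparison` (a `class_comparison` between the subset labels).
#' @export
signal_log2fc <- function(table, tissue_a, tissue_b, pseudocount = 1) {
  stopifnot(all(c(tissue_a, tissue_b, "subset_label") %in% names(table)))
  a <- table[[tissue_a]]; b <- table[[tissue_b]]
  if (any(a < 0) || any(b < 0)) stop("signals must be non-negative")
  table$log2fc <- log2((a + pseudocount) / (b + pseudocount))
  groups <- split(table$log2fc, table$subset_label)
  ord <- intersect(c("cofactor_cobound", "other"), names(groups))
  if (length(ord) == 2) groups <- groups[ord]
  comparison <- if (length(groups) >= 2)
    compare_classes(groups[1:2], test = "mann_whitney_two_sided")
  else NULL
  list(log2fc = table, comparison = comparison)
}
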