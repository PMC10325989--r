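# TAD-scoped enhancer prioritization and regulatory scoring. A candidate
# cis-regulatory module (CRM) is a consensus TF peak inside the TAD that is
# strongly enriched, distal to promoters, marked by H3K27ac, accessible
# (ATAC), and evolutionarily conserved.

#' Read TAD definitions from BED
#'
#' @param path BED file; the name column (if any) supplies `tad_id`.
#' @return A `GRanges` with a `tad_id` column.
#' @export
read_tads <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  id <- if (!is.null(gr$name) && all(nzchar(gr$name))) gr$name
        else sprintf("tad_%d", seq_along(gr))
  out <- granges(gr)
  mcols(out)$tad_id <- id
  out
}

#' Prioritize enhancer candidates within a TAD
#'
#' One candidate per consensus TF peak inside the TAD. Each candidate carries
#' six evidence flags: replicated TF binding (always true for consensus
#' input), fold enrichment at least `min_fold` (inclusive), no overlap with
#' any promoter window, H3K27ac overlap, ATAC overlap, and overlap with a
#' conserved element (each by >= 1 bp). `passes` is the conjunction of all
#' six.
#'
#' @param tad A single-range `GRanges` (the TAD).
#' @param tf_peaks Replicate-consensus TF peak collection with
#'   `fold_enrichment`.
#' @param h3k27ac,atac Peak collections for the activity mark and
#'   accessibility.
#' @param conserved `GRanges` of conserved elements.
#' @param genes Gene models ([gene_models()]); their promoter windows are
#'   excluded.
#' @param min_fold Minimum fold enrichment (default 15).
#' @param promoter_halfwidth_bp Promoter half-width (default 2000).
#' @return A `data.frame`, one row per in-TAD TF peak, with coordinates, the
#'   six flags, and `passes`; empty when the TAD contains no TF peaks.
#' @export
prioritize_enhancers <- function(tad, tf_peaks, h3k27ac, atac, conserved, genes,
                                 min_fold = 15, promoter_halfwidth_bp = 2000L) {
  stopifnot(length(tad) == 1)
  cand <- muffle_seqinfo(subsetByOverlaps(tf_peaks, tad, ignore.strand = TRUE))
  if (!length(cand)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), fold_enrichment = numeric(0),
                      replicated_tf = logical(0), min_fold = logical(0),
                      non_promoter = logical(0), h3k27ac = logical(0),
                      atac = logical(0), conserved = logical(0),
                      passes = logical(0)))
  }
  prom <- promoter_windows(genes, promoter_halfwidth_bp)
  ov <- function(x, y) muffle_seqinfo(overlapsAny(x, y, ignore.strand = TRUE))
  flags <- data.frame(
    chrom = as.character(seqnames(cand)), start = start(cand), end = end(cand),
    name = mcols(cand)$name,
    fold_enrichment = mcols(cand)$fold_enrichment,
    replicated_tf = TRUE,
    min_fold = !is.na(mcols(cand)$fold_enrichment) &
      mcols(cand)$fold_enrichment >= min_fold,
    non_promoter = !ov(cand, prom),
    h3k27ac = ov(cand, h3k27ac),
    atac = ov(cand, atac),
    conserved = ov(cand, conserved))
  flags$passes <- flags$replicated_tf & flags$min_fold & flags$non_promoter &
    flags$h3k27ac & flags$atac & flags$conserved
  rownames(flags) <- NULL
  flags
}

#' Tally transgenic reporter-assay outcomes
#'
#' The ledger has one row per candidate element: whether it was previously
#' known as a limb enhancer, whether it was tested in a reporter assay,
#' whether it showed activity in any tissue, and whether it showed
#' reproducible activity in the limb bud domain. The validated-limb total is
#' the previously known enhancers plus the newly reproducible ones.
#'
#' @param ledger A `data.frame` with columns `element_id`,
#'   `previously_known_limb`, `tested`, `any_tissue_activity`,
#'   `reproducible_limb_domain`.
#' @return A list of counts: `known_limb`, `tested`, `tissue_active`,
#'   `reproducible_limb`, `total_validated_limb`.
#' @export
tally_reporter_assays <- function(ledger) {
  needed <- c("element_id", "previously_known_limb", "tested",
              "any_tissue_activity", "reproducible_limb_domain")
  if (!all(needed %in% names(ledger)))
    stop("ledger must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(ledger$element_id)) stop("element_id values must be unique")
  bad <- ledger$reproducible_limb_domain & !ledger$tested
  if (any(bad))
    stop("reproducible_limb_domain requires tested = TRUE: ",
         paste(ledger$element_id[bad], collapse = ", "))
  known <- sum(ledger$previously_known_limb)
  reproducible <- sum(ledger$reproducible_limb_domain)
  list(known_limb = known,
       tested = sum(ledger$tested),
       tissue_active = sum(ledger$any_tissue_activity),
       reproducible_limb = reproducible,
       total_validated_limb = known + reproducible)
}

#' Regulatory score of a TAD
#'
#' Scores a TAD by the distal (non-promoter) consensus sites of the supplied
#' factors that fall inside it: `n_distal_sites` is their count and
#' `summed_strength` the sum of their `-log10(p)` scores, so both the number
#' and the individual strength of contacted sites contribute.
#'
#' @param tad A single-range `GRanges` with a `tad_id` column (or unnamed).
#' @param site_collections List of consensus peak collections (one or more
#'   factors; their union is scored).
#' @param genes Gene models; sites in promoter windows are excluded.
#' @param promoter_halfwidth_bp Promoter half-width (default 2000).
#' @return A list of class `tad_score` with `tad_id`, `n_distal_sites`,
#'   `summed_strength`.
#' @export
tad_regulatory_score <- function(tad, site_collections, genes,
                                 promoter_halfwidth_bp = 2000L) {
  stopifnot(length(tad) == 1, is.list(site_collections))
  sites <- do.call(c, lapply(site_collections, function(x) {
    gr <- granges(x)
    mcols(gr)$neglog10_p <- mcols(x)$neglog10_p
    gr
  }))
  sites <- muffle_seqinfo(subsetByOverlaps(sites, tad, ignore.strand = TRUE))
  prom <- promoter_windows(genes, promoter_halfwidth_bp)
  sites <- sites[!muffle_seqinfo(overlapsAny(sites, prom, ignore.strand = TRUE))]
  structure(list(tad_id = mcols(tad)$tad_id %||% "tad",
                 n_distal_sites = length(sites),
                 summed_strength = sum(mcols(sites)$neglog10_p)),
            class = "tad_score")
}

#' Compare regulatory scores of DEG TADs against other TADs
#'
#' One-sided Mann-Whitney test of the hypothesis that TADs containing
#' differentially expressed genes have higher regulatory scores than TADs
#' whose genes are unchanged, run on both the summed strength and the distal
#' site count.
#'
#' @param deg_tads,other_tads Lists of [tad_regulatory_score()] results.
#' @return A list with two `class_comparison` objects, `strength` and `count`.
#' @export
compare_tad_scores <- function(deg_tads, other_tads) {
  stopifnot(length(deg_tads) >= 1, length(other_tads) >= 1)
  pull <- function(xs, f) vapply(xs, `[[`, numeric(1), f)
  list(strength = compare_classes(
         list(deg = pull(deg_tads, "summed_strength"),
              other = pull(other_tads, "summed_strength")),
         test = "mann_whitney_two_sided", alternative = "greater"),
       count = compare_classes(
         list(deg = pull(deg_tads, "n_distal_sites"),
              other = pull(other_tads, "n_distal_sites")),
         test = "mann_whitney_two_sided", alternative = "greater"))
}
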