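#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps reduce start end width strand strand<- seqnames granges pintersect
#' @importFrom IRanges IRanges ranges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits DataFrame
#' @importFrom stats pchisq
NULL

# Peaks are held as GRanges (1-based, closed intervals — the native R/Bioconductor
# convention). BED-family files on disk are 0-based half-open; conversion happens
# only at the I/O boundary, inside read_peaks()/write_peaks().

#' Construct a scored peak collection
#'
#' A peak collection is a `GRanges` whose metadata columns carry, per peak, a
#' `-log10(p)` enrichment score (`neglog10_p`), an optional fold enrichment
#' over background (`fold_enrichment`, `NA` when unknown) and a `name`.
#' Assay-level descriptors (assay type, factor/mark, tissue, replicate index)
#' live in `metadata()`.
#'
#' @param gr A `GRanges`, or anything coercible via `GRanges()`.
#' @param neglog10_p Numeric vector of `-log10` peak p-values (non-negative).
#' @param fold_enrichment Optional numeric vector of fold enrichments
#'   (non-negative); `NA` marks missing values.
#' @param name Optional character vector of peak identifiers.
#' @param assay One of `"TF-ChIP"`, `"histone-ChIP"`, `"ATAC"`, `"CTCF"`.
#' @param factor Factor or mark name (e.g. `"PBX1"`, `"H3K27ac"`).
#' @param tissue Tissue label (e.g. `"HL"`).
#' @param replicate Replicate index (integer >= 1).
#' @return A `GRanges` with validated metadata columns, sorted by position.
#' @export
peak_collection <- function(gr, neglog10_p = numeric(0), fold_enrichment = NULL,
                            name = NULL, assay = "TF-ChIP", factor = NA_character_,
                            tissue = NA_character_, replicate = 1L) {
  gr <- GRanges(gr)
  n <- length(gr)
  if (length(neglog10_p) != n)
    stop("neglog10_p must have one value per peak")
  if (any(!is.finite(neglog10_p) & !is.na(neglog10_p)))
    stop("neglog10_p must be finite; clamp infinite scores before construction")
  if (any(neglog10_p < 0, na.rm = TRUE)) stop("neglog10_p must be non-negative")
  if (is.null(fold_enrichment)) fold_enrichment <- rep(NA_real_, n)
  if (any(fold_enrichment < 0, na.rm = TRUE)) stop("fold_enrichment must be non-negative")
  if (is.null(name)) name <- if (n) sprintf("peak_%d", seq_len(n)) else character(0)
  assay <- match.arg(assay, c("TF-ChIP", "histone-ChIP", "ATAC", "CTCF"))
  mcols(gr) <- DataFrame(name = as.character(name),
                         neglog10_p = as.numeric(neglog10_p),
                         fold_enrichment = as.numeric(fold_enrichment))
  metadata(gr) <- list(assay = assay, factor = factor, tissue = tissue,
                       replicate = as.integer(replicate))
  sort(gr)
}

#' Read peaks from narrowPeak or BED6
#'
#' narrowPeak (ENCODE BED6+4) column 8 (`pValue`) maps to `neglog10_p` and
#' column 7 (`signalValue`) to `fold_enrichment`. For plain BED6 the score
#' column maps to `neglog10_p` and fold enrichment is `NA`. Files use 0-based
#' half-open coordinates; the returned `GRanges` is 1-based closed.
#'
#' @param path Path to the file.
#' @param format `"narrowPeak"` or `"BED6"`.
#' @inheritParams peak_collection
#' @return A peak collection (`GRanges`), empty if the file has no records.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "BED6"),
                       assay = "TF-ChIP", factor = NA_character_,
                       tissue = NA_character_, replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ncol_needed <- if (format == "narrowPeak") 10L else 6L
  if (!length(lines)) {
    return(peak_collection(GRanges(), assay = assay, factor = factor,
                           tissue = tissue, replicate = replicate))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields, got %d",
                 format, bad[1], path, ncol_needed, nf[bad[1]]))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: non-numeric coordinates", format, bad[1], path))
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop(sprintf("invalid interval at line %d in %s: start must satisfy 0 <= start < end",
                 bad[1], path))
  score_col <- if (format == "narrowPeak") 8L else 5L
  neglog10_p <- suppressWarnings(as.numeric(m[, score_col]))
  bad <- which(is.na(neglog10_p))
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: non-numeric score", format, bad[1], path))
  fe <- if (format == "narrowPeak") suppressWarnings(as.numeric(m[, 7])) else NULL
  if (!is.null(fe)) fe[fe < 0] <- NA_real_  # ENCODE "not available" sentinel
  gr <- GRanges(m[, 1], IRanges(start0 + 1L, end0),
                strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"))
  peak_collection(gr, neglog10_p = neglog10_p, fold_enrichment = fe,
                  name = m[, 4], assay = assay, factor = factor,
                  tissue = tissue, replicate = replicate)
}

#' Write peaks to narrowPeak or BED6
#'
#' Inverse of [read_peaks()]; coordinates are converted back to 0-based
#' half-open on output. narrowPeak `qValue` and `peak` columns, which the
#' in-memory model does not carry, are written as `-1` (the ENCODE
#' "not available" sentinel).
#'
#' @param x A peak collection (`GRanges` with `neglog10_p` etc.).
#' @param path Output path.
#' @param format `"narrowPeak"` or `"BED6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, format = c("narrowPeak", "BED6")) {
  format <- match.arg(format)
  strand_chr <- as.character(strand(x))
  strand_chr[strand_chr == "*"] <- "."
  base <- data.frame(chrom = as.character(seqnames(x)),
                     start = start(x) - 1L, end = end(x),
                     name = mcols(x)$name, stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    fe <- mcols(x)$fold_enrichment
    fe[is.na(fe)] <- -1
    out <- cbind(base[, 1:4],
                 score = 0L, strand = strand_chr, signalValue = fe,
                 pValue = mcols(x)$neglog10_p, qValue = -1, peak = -1L)
  } else {
    out <- cbind(base[, 1:4], score = mcols(x)$neglog10_p, strand = strand_chr)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Consensus-combination settings
#'
#' Thresholds for replicate-consensus peak combination: each supporting peak
#' must pass the weak per-peak threshold and the group's Fisher-combined
#' p-value must pass the stringent threshold. Defaults mirror the standard
#' stringent/weak settings used for replicated TF ChIP-seq (`-s 1E-10 -W 1E-6`).
#'
#' @param stringent_p Combined-p stringent threshold (default `1e-10`).
#' @param weak_p Per-peak weak threshold (default `1e-6`).
#' @param min_replicates Required number of supporting replicates (default 2).
#' @param min_overlap_bp Minimum overlap in bases for peaks to group (default 1).
#' @param neglog10_ceiling Clamp for infinite `-log10(p)` scores (default 300).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(stringent_p = 1e-10, weak_p = 1e-6,
                             min_replicates = 2L, min_overlap_bp = 1L,
                             neglog10_ceiling = 300) {
  stopifnot(stringent_p > 0, stringent_p <= weak_p, weak_p < 1,
            min_replicates >= 1, min_overlap_bp >= 1, neglog10_ceiling > 0)
  structure(list(stringent_p = stringent_p, weak_p = weak_p,
                 min_replicates = as.integer(min_replicates),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 neglog10_ceiling = neglog10_ceiling),
            class = "consensus_config")
}

#' Fisher combination of -log10 p-values
#'
#' Combines k p-values with Fisher's method: the statistic `-2 * sum(ln p_i)`
#' is referred to a chi-square distribution with `2k` degrees of freedom.
#' Computed throughout on the `-log10` scale to stay stable for very small p.
#'
#' @param neglog10_p Numeric vector of `-log10` p-values.
#' @return The combined `-log10(p)`.
#' @export
fisher_neglog10 <- function(neglog10_p) {
  stopifnot(length(neglog10_p) >= 1, all(neglog10_p >= 0))
  stat <- 2 * log(10) * sum(neglog10_p)
  -pchisq(stat, df = 2 * length(neglog10_p), lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Overlapping index pairs between two peak collections
#'
#' @param a,b Peak collections (`GRanges`).
#' @param min_overlap_bp Minimum intersection length in bases.
#' @return A two-column integer matrix (`a_idx`, `b_idx`), one row per pair
#'   whose intersection is at least `min_overlap_bp` bases. Symmetric under
#'   swapping `a` and `b` (with columns exchanged).
#' @export
overlap_pairs <- function(a, b, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  hits <- muffle_seqinfo(findOverlaps(a, b, minoverlap = as.integer(min_overlap_bp),
                                      ignore.strand = TRUE))
  cbind(a_idx = queryHits(hits), b_idx = subjectHits(hits))
}

# Connected components of the pairwise-overlap graph over a pooled GRanges.
# With min_overlap_bp = 1 this equals grouping by reduce(); the general case
# goes through an explicit overlap graph.
overlap_components <- function(gr, min_overlap_bp = 1L) {
  if (!length(gr)) return(integer(0))
  if (min_overlap_bp == 1L) {
    merged <- reduce(gr, ignore.strand = TRUE)
    hits <- findOverlaps(gr, merged, ignore.strand = TRUE)
    comp <- integer(length(gr))
    comp[queryHits(hits)] <- subjectHits(hits)
    return(comp)
  }
  hits <- findOverlaps(gr, minoverlap = as.integer(min_overlap_bp),
                       ignore.strand = TRUE, drop.self = TRUE, drop.redundant = TRUE)
  g <- igraph::graph_from_edgelist(
    rbind(cbind(queryHits(hits), subjectHits(hits)),
          cbind(seq_along(gr), seq_along(gr))),
    directed = FALSE)
  igraph::components(g)$membership[seq_along(gr)]
}

#' Replicate-consensus peak combination
#'
#' Pools peaks across replicates, drops peaks failing the weak per-peak
#' threshold, groups the survivors into overlapping clusters, and keeps each
#' cluster whose peaks come from at least `min_replicates` distinct replicates
#' and whose Fisher-combined p-value passes the stringent threshold. The output
#' region is the union span of the cluster and its score the combined
#' `-log10(p)`. Peaks with infinite `-log10(p)` (p = 0) are clamped to
#' `cfg$neglog10_ceiling` with a warning.
#'
#' @param reps List of per-replicate peak collections for the same
#'   factor/tissue.
#' @param cfg A [consensus_config()].
#' @return A consensus peak collection; `mcols()$n_support` records the number
#'   of supporting peaks per region.
#' @export
consensus_replicates <- function(reps, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"), is.list(reps))
  if (length(reps) < cfg$min_replicates)
    stop(sprintf("need at least %d replicate collections, got %d",
                 cfg$min_replicates, length(reps)))
  pooled <- do.call(c, lapply(seq_along(reps), function(i) {
    gr <- reps[[i]]
    mcols(gr)$.rep <- rep(i, length(gr))
    gr
  }))
  meta <- metadata(reps[[1]])
  inf <- !is.finite(mcols(pooled)$neglog10_p)
  if (any(inf)) {
    warning(sprintf("clamped %d peak score(s) with -log10(p) = Inf to %g",
                    sum(inf), cfg$neglog10_ceiling))
    mcols(pooled)$neglog10_p[inf] <- cfg$neglog10_ceiling
  }
  weak_neglog10 <- -log10(cfg$weak_p)
  pooled <- pooled[mcols(pooled)$neglog10_p >= weak_neglog10]
  empty <- peak_collection(GRanges(), assay = meta$assay %||% "TF-ChIP",
                           factor = meta$factor, tissue = meta$tissue)
  if (!length(pooled)) return(empty)
  comp <- overlap_components(pooled, cfg$min_overlap_bp)
  keep_chr <- character(0); keep_start <- integer(0); keep_end <- integer(0)
  keep_p <- numeric(0); keep_n <- integer(0)
  for (grp in split(seq_along(pooled), comp)) {
    if (length(unique(mcols(pooled)$.rep[grp])) < cfg$min_replicates) next
    combined <- fisher_neglog10(mcols(pooled)$neglog10_p[grp])
    if (combined < -log10(cfg$stringent_p)) next
    keep_chr <- c(keep_chr, as.character(seqnames(pooled))[grp[1]])
    keep_start <- c(keep_start, min(start(pooled)[grp]))
    keep_end <- c(keep_end, max(end(pooled)[grp]))
    keep_p <- c(keep_p, combined)
    keep_n <- c(keep_n, length(grp))
  }
  if (!length(keep_chr)) return(empty)
  out <- peak_collection(GRanges(keep_chr, IRanges(keep_start, keep_end)),
                         neglog10_p = keep_p,
                         assay = meta$assay %||% "TF-ChIP",
                         factor = meta$factor, tissue = meta$tissue)
  mcols(out)$n_support <- keep_n[order(GRanges(keep_chr, IRanges(keep_start, keep_end)))]
  out
}

#' Union-merge several peak collections
#'
#' Collapses all input peaks into maximal non-overlapping regions (the merged
#' universe of putative regulatory elements). Each output region records which
#' input collections contributed to it.
#'
#' @param collections Named list of peak collections.
#' @return A `GRanges` of merged regions with a `sources` `CharacterList`
#'   column.
#' @export
merge_union <- function(collections) {
  stopifnot(is.list(collections), length(collections) >= 1)
  if (is.null(names(collections)))
    names(collections) <- sprintf("set%d", seq_along(collections))
  pooled <- do.call(c, lapply(names(collections), function(nm) {
    gr <- granges(collections[[nm]])
    mcols(gr)$.src <- rep(nm, length(gr))
    gr
  }))
  merged <- reduce(pooled, ignore.strand = TRUE)
  hits <- findOverlaps(merged, pooled, ignore.strand = TRUE)
  splits <- split(mcols(pooled)$.src[subjectHits(hits)],
                  factor(queryHits(hits), levels = seq_along(merged)))
  mcols(merged)$sources <- IRanges::CharacterList(lapply(splits, function(s) sort(unique(s))))
  merged
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Comparing collections with disjoint chromosome universes is legitimate for
# every overlap operation here; silence only the Seqinfo-merge warning.
muffle_seqinfo <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
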