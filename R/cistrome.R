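#' @importFrom stats kruskal.test wilcox.test p.adjust
NULL

#' Read gene models
#'
#' Imports gene features from GFF3/GTF (features of type `gene`) or BED12 and
#' returns a `GRanges` with `gene_id` and a strand-aware `tss` column (the
#' 5' end of the gene body: `start` for `+` genes, `end` for `-` genes).
#'
#' @param path File path.
#' @param format `"gff3"`, `"gtf"` or `"bed12"` (default guessed from the
#'   extension).
#' @return A `GRanges` of gene bodies with `gene_id` and `tss` columns.
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", gtf = "gtf", bed = "bed12",
                     stop("cannot guess gene-model format from extension: ", ext))
  }
  format <- match.arg(format, c("gff3", "gtf", "bed12"))
  if (format %in% c("gff3", "gtf")) {
    gr <- rtracklayer::import(path, format = sub("3", "", format))
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    id <- gr$gene_id %||% gr$ID %||% gr$Name
    if (is.null(id)) stop("no gene_id/ID/Name attribute on gene features")
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    id <- gr$name
  }
  gene_models(granges(gr), gene_id = as.character(id))
}

#' Construct gene models from a GRanges
#'
#' @param gr A stranded `GRanges` of gene bodies.
#' @param gene_id Unique gene identifiers, one per range.
#' @return `gr` with `gene_id` and `tss` metadata columns.
#' @export
gene_models <- function(gr, gene_id) {
  stopifnot(length(gr) == length(gene_id))
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  tss <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  mcols(gr) <- DataFrame(gene_id = as.character(gene_id), tss = as.integer(tss))
  gr
}

promoter_windows <- function(genes, promoter_halfwidth_bp) {
  stopifnot(promoter_halfwidth_bp > 0)
  GRanges(seqnames(genes),
          IRanges(pmax(1L, genes$tss - as.integer(promoter_halfwidth_bp)),
                  genes$tss + as.integer(promoter_halfwidth_bp) - 1L))
}

#' Partition merged regions by factor co-binding
#'
#' Merges two consensus cistromes into one region universe and labels every
#' merged region `A_only`, `B_only`, or `both` according to which factors'
#' peaks overlap it. The three class counts always sum to the merged-set size.
#'
#' @param a,b Consensus peak collections for factors A and B.
#' @param min_overlap_bp Minimum overlap in bases (default 1).
#' @param labels Length-2 character vector naming the factors (used in the
#'   summary; defaults to `metadata()$factor` when available).
#' @return A `GRanges` of merged regions with a `class` column
#'   (`"A_only"`, `"B_only"`, `"both"`).
#' @export
partition_cobinding <- function(a, b, min_overlap_bp = 1L, labels = NULL) {
  if (!length(a) && !length(b)) {
    warning("both input collections are empty; returning empty partition")
    out <- GRanges()
    mcols(out)$class <- character(0)
    return(out)
  }
  merged <- muffle_seqinfo(reduce(c(granges(a), granges(b)), ignore.strand = TRUE))
  in_a <- muffle_seqinfo(overlapsAny(merged, a,
                                     minoverlap = as.integer(min_overlap_bp),
                                     ignore.strand = TRUE))
  in_b <- muffle_seqinfo(overlapsAny(merged, b,
                                     minoverlap = as.integer(min_overlap_bp),
                                     ignore.strand = TRUE))
  cls <- ifelse(in_a & in_b, "both", ifelse(in_a, "A_only", "B_only"))
  mcols(merged)$class <- cls
  metadata(merged)$factors <- labels %||%
    c(metadata(a)$factor %||% "A", metadata(b)$factor %||% "B")
  merged
}

#' Summarize a co-binding partition
#'
#' @param partition Output of [partition_cobinding()].
#' @return A list with per-class counts and their `total`.
#' @export
partition_summary <- function(partition) {
  cls <- mcols(partition)$class
  counts <- c(A_only = sum(cls == "A_only"), B_only = sum(cls == "B_only"),
              both = sum(cls == "both"))
  c(as.list(counts), list(total = partition_total(counts)))
}

#' Total size of a partitioned region set
#'
#' The bookkeeping identity behind every co-binding Venn: the disjoint class
#' counts (factor-A-only, factor-B-only, co-bound) sum to the merged-set size.
#'
#' @param counts Numeric vector of disjoint class counts.
#' @return Their sum.
#' @export
partition_total <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  sum(counts)
}

#' Assign genomic context to regions
#'
#' Labels each region `promoter` if it overlaps any TSS window
#' (`tss - w` to `tss + w`), else `intragenic` if it overlaps any gene body,
#' else `intergenic`. The precedence promoter > intragenic > intergenic makes
#' the three labels exhaustive and mutually exclusive.
#'
#' @param regions A `GRanges`.
#' @param genes Gene models from [gene_models()].
#' @param promoter_halfwidth_bp Promoter half-width in bases (default 2000).
#' @return Character vector of context labels, one per region.
#' @export
assign_context <- function(regions, genes, promoter_halfwidth_bp = 2000L) {
  prom <- promoter_windows(genes, promoter_halfwidth_bp)
  in_prom <- muffle_seqinfo(overlapsAny(regions, prom, ignore.strand = TRUE))
  in_gene <- muffle_seqinfo(overlapsAny(regions, genes, ignore.strand = TRUE))
  ifelse(in_prom, "promoter", ifelse(in_gene, "intragenic", "intergenic"))
}

#' Overlay chromatin state onto a partition
#'
#' For each region sets a boolean flag per mark (>= 1 bp overlap with the
#' mark's peak collection) and records the maximum `-log10(p)` among
#' overlapping mark peaks (0 if none) in a `signal_<mark>` column. The maximum
#' (rather than the mean) is used so that fragmented mark peaks do not dilute
#' the attributed signal.
#'
#' @param partition A `GRanges` of regions (e.g. from [partition_cobinding()]).
#' @param marks Named list of peak collections; names must be a subset of
#'   `h3k27ac`, `h3k27me3`, `atac`, `ctcf`.
#' @return `partition` with `<mark>` logical and `signal_<mark>` numeric
#'   columns added.
#' @export
annotate_chromatin <- function(partition, marks) {
  allowed <- c("h3k27ac", "h3k27me3", "atac", "ctcf")
  if (is.null(names(marks)) || !all(names(marks) %in% allowed))
    stop("mark names must be among: ", paste(allowed, collapse = ", "))
  for (nm in names(marks)) {
    mk <- marks[[nm]]
    flag <- muffle_seqinfo(overlapsAny(partition, mk, ignore.strand = TRUE))
    sig <- numeric(length(partition))
    if (length(mk)) {
      hits <- muffle_seqinfo(findOverlaps(partition, mk, ignore.strand = TRUE))
      if (length(hits)) {
        mx <- vapply(split(mcols(mk)$neglog10_p[subjectHits(hits)], queryHits(hits)),
                     max, numeric(1))
        sig[as.integer(names(mx))] <- mx
      }
    }
    mcols(partition)[[nm]] <- flag
    mcols(partition)[[paste0("signal_", nm)]] <- sig
  }
  partition
}

#' Rank-based comparison of per-class value distributions
#'
#' Runs a Kruskal-Wallis test (>= 2 groups) or a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test (exactly 2 groups) on values grouped by class,
#' with midrank tie handling. For the Mann-Whitney test the exact null
#' distribution is used when both groups have at most 50 observations and no
#' ties are present (matching `stats::wilcox.test`), otherwise the normal
#' approximation without continuity correction. p-values are floored at the
#' smallest positive double so that "p < 2.2e-16"-style reporting never
#' degenerates to an exact zero.
#'
#' @param values_by_class Named list of numeric vectors, one per class.
#' @param test `"kruskal_wallis"` or `"mann_whitney_two_sided"`.
#' @param alternative For the Mann-Whitney test: `"two.sided"` (default),
#'   `"greater"` or `"less"` (first group vs second).
#' @return A list of class `class_comparison` with `test`, `statistic`,
#'   `p_value`, `p_floored` and `group_sizes`.
#' @export
compare_classes <- function(values_by_class,
                            test = c("kruskal_wallis", "mann_whitney_two_sided"),
                            alternative = "two.sided") {
  test <- match.arg(test)
  sizes <- lengths(values_by_class)
  if (any(sizes == 0)) stop("every class must contain at least one value")
  if (length(values_by_class) < 2) stop("need at least two classes")
  if (test == "kruskal_wallis") {
    x <- unlist(values_by_class, use.names = FALSE)
    g <- factor(rep(seq_along(values_by_class), sizes))
    fit <- kruskal.test(x, g)
  } else {
    if (length(values_by_class) != 2)
      stop("mann_whitney_two_sided requires exactly two classes")
    fit <- suppressWarnings(
      wilcox.test(values_by_class[[1]], values_by_class[[2]],
                  alternative = alternative, correct = FALSE))
  }
  p <- fit$p.value
  # zero rank variance (all observations tied) carries no evidence at all
  if (is.nan(p)) p <- 1
  floored <- !is.na(p) && p < .Machine$double.xmin
  structure(list(test = test,
                 statistic = unname(fit$statistic),
                 p_value = max(p, .Machine$double.xmin),
                 p_floored = floored,
                 group_sizes = unname(sizes)),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  p <- if (x$p_floored) sprintf("< %g", .Machine$double.xmin) else format(x$p_value)
  cat(sprintf("%s: statistic = %.4g, p %s%s (n = %s)\n", x$test, x$statistic,
              if (x$p_floored) "" else "= ", p,
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Export a partition as BED
#'
#' Writes merged regions with class/context/chromatin flags compacted into the
#' BED name field (`class|context|flags`).
#'
#' @param partition Annotated partition `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path) {
  mc <- mcols(partition)
  flags <- vapply(seq_along(partition), function(i) {
    fl <- c("h3k27ac", "h3k27me3", "atac", "ctcf")
    fl <- fl[fl %in% colnames(mc)]
    paste(fl[unlist(mc[i, fl, drop = FALSE]) == TRUE], collapse = "+")
  }, character(1))
  name <- paste(mc$class,
                if ("context" %in% colnames(mc)) mc$context else "NA",
                ifelse(nzchar(flags), flags, "none"), sep = "|")
  out <- data.frame(as.character(seqnames(partition)), start(partition) - 1L,
                    end(partition), name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
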