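# Binding-site mutagenesis planning for enhancer reporter constructs.
# Motif cores are disrupted by a fixed substitution map — T/A bases become C,
# C/G bases become A — which has no fixed points, so every core base counts
# as altered, and the total altered-base count is directly comparable across
# designs.

MUTATION_MAP <- c(A = "C", T = "C", C = "A", G = "A")

#' Describe motif sites within an enhancer sequence
#'
#' @param position 1-based base-pair offsets of the sites within the
#'   enhancer.
#' @param motif_class `"PBX"` or `"HAND"` per site (recycled).
#' @param core_length Bases to disrupt per site (recycled; default 6, the
#'   HAND motif core length).
#' @param core_offset 0-based offset of the core start from `position`
#'   (recycled; default 0, i.e. the printed position is the core start).
#' @return A `data.frame` of validated motif sites.
#' @export
motif_sites <- function(position, motif_class = "PBX", core_length = 6L,
                        core_offset = 0L) {
  stopifnot(all(position >= 1), all(core_length >= 1), all(core_offset >= 0))
  motif_class <- match.arg(motif_class, c("PBX", "HAND"), several.ok = TRUE)
  data.frame(position = as.integer(position),
             motif_class = rep_len(motif_class, length(position)),
             core_length = rep_len(as.integer(core_length), length(position)),
             core_offset = rep_len(as.integer(core_offset), length(position)))
}

#' Read motif sites from TSV
#'
#' @param path TSV with header columns `position`, `motif_class`,
#'   `core_length`, `core_offset`.
#' @return A validated motif-site `data.frame`.
#' @export
read_motif_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  motif_sites(df$position, df$motif_class, df$core_length, df$core_offset)
}

#' Plan binding-site mutagenesis of an enhancer
#'
#' For every core base of every site, emits one substitution edit under the
#' map T->C, A->C, C->A, G->A. Because the map has no fixed points, the
#' number of altered bases equals the total number of core bases. The plan is
#' deterministic.
#'
#' @param sequence Enhancer DNA as a string or `Biostrings::DNAString`
#'   (A/C/G/T only inside site cores).
#' @param sites A motif-site `data.frame` from [motif_sites()]; may be empty.
#' @param design_id Identifier for the design (default `"design"`).
#' @return A list of class `mutagenesis_plan` with `design_id`, `sites`,
#'   `edits` (position, ref, alt) and `n_bases_altered`.
#' @export
plan_mutagenesis <- function(sequence, sites, design_id = "design") {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  bases <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  edits <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    core_start <- s$position + s$core_offset
    core_end <- core_start + s$core_length - 1L
    if (core_start < 1 || core_end > n)
      stop(sprintf("site core at position %d (length %d) lies outside the %d bp sequence",
                   s$position, s$core_length, n))
    pos <- core_start:core_end
    ref <- bases[pos]
    bad <- !ref %in% names(MUTATION_MAP)
    if (any(bad))
      stop(sprintf("non-ACGT base '%s' inside site core at position %d",
                   ref[bad][1], pos[bad][1]))
    edits[[i]] <- data.frame(position = pos, ref = ref,
                             alt = unname(MUTATION_MAP[ref]))
  }
  edits <- if (length(edits)) unique(do.call(rbind, edits))
           else data.frame(position = integer(0), ref = character(0),
                           alt = character(0))
  edits <- edits[order(edits$position), , drop = FALSE]
  rownames(edits) <- NULL
  structure(list(design_id = design_id, sites = sites, edits = edits,
                 n_bases_altered = sum(edits$ref != edits$alt)),
            class = "mutagenesis_plan")
}

#' Apply a mutagenesis plan to a sequence
#'
#' Verifies every edit's reference base against the sequence (guarding stale
#' plans) and substitutes the alternates. Length is preserved and positions
#' outside edits are untouched.
#'
#' @param sequence DNA string (or `DNAString`) the plan was built for.
#' @param plan A [plan_mutagenesis()] result.
#' @return The mutated sequence as a character string.
#' @export
apply_plan <- function(sequence, plan) {
  stopifnot(inherits(plan, "mutagenesis_plan"))
  bases <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  ed <- plan$edits
  if (nrow(ed)) {
    if (any(ed$position > length(bases)))
      stop("edit position beyond sequence end: ",
           ed$position[ed$position > length(bases)][1])
    mismatch <- bases[ed$position] != ed$ref
    if (any(mismatch))
      stop(sprintf("reference mismatch at position %d: plan expects %s, sequence has %s",
                   ed$position[mismatch][1], ed$ref[mismatch][1],
                   bases[ed$position[mismatch][1]]))
    bases[ed$position] <- ed$alt
  }
  paste(bases, collapse = "")
}

#' Compare altered-base counts across designs
#'
#' Reporter comparisons between mutant enhancer versions are only direct when
#' the same number of bases was altered in each design; this reports the
#' per-design counts and whether they all agree.
#'
#' @param plans List (>= 2) of [plan_mutagenesis()] results.
#' @return A list with `n_bases_altered` (named per design), `all_equal`,
#'   and `max_difference`.
#' @export
compare_designs <- function(plans) {
  stopifnot(length(plans) >= 2,
            all(vapply(plans, inherits, logical(1), "mutagenesis_plan")))
  counts <- vapply(plans, `[[`, numeric(1), "n_bases_altered")
  names(counts) <- vapply(plans, `[[`, character(1), "design_id")
  list(n_bases_altered = counts,
       all_equal = length(unique(counts)) == 1,
       max_difference = max(counts) - min(counts))
}

#' Write a mutagenesis plan and its mutated sequence
#'
#' @param plan A [plan_mutagenesis()] result.
#' @param sequence The wild-type sequence.
#' @param edits_path TSV output for the edit list.
#' @param fasta_path FASTA output for the mutated sequence.
#' @return `fasta_path`, invisibly.
#' @export
write_plan <- function(plan, sequence, edits_path, fasta_path) {
  utils::write.table(plan$edits, edits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mutated <- Biostrings::DNAStringSet(apply_plan(sequence, plan))
  names(mutated) <- paste0(plan$design_id, "_mut")
  Biostrings::writeXStringSet(mutated, fasta_path)
  invisible(fasta_path)
}
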