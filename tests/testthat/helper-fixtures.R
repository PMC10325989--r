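# Small in-code fixture builders shared across test files.

library(GenomicRanges)

# Peak collection from parallel coordinate vectors.
mk_peaks <- function(chrom, start, end, p = rep(10, length(start)), fe = NULL,
                     factor = "TF", replicate = 1L, assay = "TF-ChIP") {
  gr <- if (length(start)) GRanges(chrom, IRanges(start, end)) else GRanges()
  peak_collection(gr, neglog10_p = p, fold_enrichment = fe, factor = factor,
                  replicate = replicate, assay = assay)
}

# n random peaks on a small two-chromosome genome (caller seeds the RNG).
random_peaks <- function(n, max_pos = 100000, width_range = c(50, 500)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  mk_peaks(sample(c("chr1", "chr2"), n, replace = TRUE), start, start + w - 1,
           p = runif(n, 0, 30))
}

# Quadratic all-vs-all interval scan: reference for every overlap operation.
brute_overlap_pairs <- function(a, b, min_overlap = 1) {
  out <- NULL
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
      ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1
      if (ov >= min_overlap) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Independent sort-and-sweep union of intervals -> data.frame per chromosome.
sweep_union <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr))
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start, d$end), ]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_e + 1) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
  }
  out
}

# Chi-square upper tail for even df from the closed-form series
# P(X > x) = exp(-x/2) * sum_{j < df/2} (x/2)^j / j!  (independent of pchisq);
# the exact reference for Fisher combination of k p-values (df = 2k).
chisq_tail_even_df <- function(stat, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  exp(-stat / 2) * sum((stat / 2)^j / factorial(j))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (midranks; no-tie data only gives the exact reference distribution).
exact_mw_p_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# Exhaustive concordant-pair counting AUROC (ties count half).
brute_auc <- function(pos, bg) {
  tot <- 0
  for (p in pos) for (b in bg)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(pos) * length(bg))
}

# Tiny simulation configuration for fast end-to-end tests.
small_sim <- function(seed = 7L) {
  sim_config(seed = seed,
             genome = c(chr1 = 4e6, chr2 = 4e6),
             n_genes = 120L, n_tads = 12L,
             peak_plan = list(n_a_only = 120L, n_cobound = 60L, n_b_only = 50L,
                              deg_tad_extra = 4L),
             deg_plan = list(concordant_up = 12L, concordant_down = 9L,
                             discordant = 6L, a_only = 10L, b_only = 8L,
                             undetected = 4L),
             sc_plan = list(cells = c(mes_posterior = 120L, mes_other = 120L,
                                      epithelial = 60L),
                            n_genes = 400L, qc_low_umi = 3L, qc_high_umi = 1L,
                            qc_high_mito = 2L,
                            qc_min_total = 800, qc_max_total = 10000),
             cross_tissue_plan = list(n_per_tissue = 300L, n_cofactor = 300L,
                                      n_signal = 100L))
}
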