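test_that("narrowPeak and BED6 round-trip through read/write identically", {
  set.seed(11)
  pk <- random_peaks(50)
  mcols(pk)$fold_enrichment <- round(runif(50, 1, 40), 3)
  mcols(pk)$neglog10_p <- round(mcols(pk)$neglog10_p, 4)
  for (fmt in c("narrowPeak", "BED6")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_peaks(pk, f, format = fmt)
    back <- read_peaks(f, format = fmt)
    expect_equal(as.character(seqnames(back)), as.character(seqnames(pk)))
    expect_equal(start(back), start(pk))
    expect_equal(end(back), end(pk))
    expect_equal(mcols(back)$neglog10_p, mcols(pk)$neglog10_p)
    expect_equal(mcols(back)$name, mcols(pk)$name)
    if (fmt == "narrowPeak")
      expect_equal(mcols(back)$fold_enrichment, mcols(pk)$fold_enrichment)
  }
})

test_that("read_peaks maps narrowPeak columns and validates records", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tp1\t0\t.\t12.5\t8.0\t-1\t-1", f)
  pk <- read_peaks(f)
  expect_equal(start(pk), 101L)  # 0-based file -> 1-based in memory
  expect_equal(end(pk), 200L)
  expect_equal(mcols(pk)$neglog10_p, 8.0)
  expect_equal(mcols(pk)$fold_enrichment, 12.5)

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_length(read_peaks(empty), 0)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t1\t2\t-1\t-1",
               "chr1\t100\t200"), bad)
  expect_error(read_peaks(bad), "line 2")
  writeLines("chr1\t200\t100\tp1\t0\t.\t1\t2\t-1\t-1", bad)
  expect_error(read_peaks(bad), "start")
})

test_that("overlap_pairs matches an all-vs-all quadratic scan", {
  a <- mk_peaks("chr1", 100, 200)
  b <- mk_peaks("chr1", 150, 250)
  expect_equal(nrow(overlap_pairs(a, b)), 1)
  expect_equal(nrow(overlap_pairs(mk_peaks("chr1", 1, 10),
                                  mk_peaks("chr2", 1, 10))), 0)
  expect_error(overlap_pairs(a, b, min_overlap_bp = 0), "min_overlap")

  set.seed(42)
  a <- random_peaks(200); b <- random_peaks(200)
  for (mo in c(1, 50)) {
    got <- overlap_pairs(a, b, mo)
    want <- brute_overlap_pairs(a, b, mo)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 matrix(want[order(want[, 1], want[, 2]), , drop = FALSE],
                        ncol = 2, dimnames = list(NULL, c("a_idx", "b_idx"))))
    swapped <- overlap_pairs(b, a, mo)
    expect_setequal(paste(got[, 1], got[, 2]), paste(swapped[, 2], swapped[, 1]))
  }
})

test_that("Fisher combination reduces to the member p for k = 1 and to 1 for p = 1", {
  expect_equal(fisher_neglog10(7.3), 7.3)
  expect_equal(fisher_neglog10(c(0, 0)), 0)  # two p = 1 peaks -> statistic 0
})

test_that("consensus requires reproducible support and the stringent combined p", {
  cfg <- consensus_config()
  r1 <- mk_peaks("chr1", c(100, 5000), c(400, 5300), p = c(8, 9), replicate = 1)
  r2 <- mk_peaks("chr1", 150, 450, p = c(8), replicate = 2)
  out <- consensus_replicates(list(r1, r2), cfg)
  # the 5000-5300 peak is present in only one replicate -> excluded
  expect_length(out, 1)
  expect_equal(start(out), 100L)
  expect_equal(mcols(out)$neglog10_p, fisher_neglog10(c(8, 8)))

  # two overlapping peaks at p = 1e-8 each: decided against 1e-10 via the
  # chi-square tail, checked against a numerical-integration oracle
  r1 <- mk_peaks("chr1", 100, 400, p = 8, replicate = 1)
  r2 <- mk_peaks("chr1", 150, 450, p = 8, replicate = 2)
  combined_p <- 10^(-fisher_neglog10(c(8, 8)))
  oracle <- chisq_tail_even_df(2 * log(10) * 16, df = 4)
  expect_lt(abs(combined_p - oracle) / oracle, 1e-9)
  expect_length(consensus_replicates(list(r1, r2), cfg),
                as.integer(combined_p <= 1e-10))

  # weak-threshold gate: both peaks below -log10(1e-6) are never considered
  weak <- consensus_replicates(list(mk_peaks("chr1", 100, 400, p = 5),
                                    mk_peaks("chr1", 150, 450, p = 5)), cfg)
  expect_length(weak, 0)
  expect_error(consensus_replicates(list(r1), cfg), "at least 2")
})

test_that("consensus output is covered by the inputs and monotone in stringent_p", {
  set.seed(5)
  r1 <- random_peaks(150)
  r2 <- peak_collection(GenomicRanges::shift(granges(r1), 25),
                        neglog10_p = pmax(0, mcols(r1)$neglog10_p +
                                            rnorm(150, 0, 0.5)),
                        replicate = 2L)
  sizes <- vapply(c(1e-14, 1e-10, 1e-6), function(s)
    length(consensus_replicates(list(r1, r2),
                                consensus_config(stringent_p = s, weak_p = 1e-4))),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
  out <- consensus_replicates(list(r1, r2), consensus_config())
  union_in <- reduce(c(granges(r1), granges(r2)))
  expect_true(all(overlapsAny(out, union_in)))
  expect_true(all(IRanges::width(GenomicRanges::setdiff(out, union_in)) == 0))
})

test_that("infinite peak scores are clamped with a warning", {
  r1 <- peak_collection(GRanges("chr1", IRanges(100, 400)), neglog10_p = 10)
  mcols(r1)$neglog10_p <- Inf  # bypass constructor check, as a raw caller might
  r2 <- mk_peaks("chr1", 150, 450, p = 10, replicate = 2)
  expect_warning(out <- consensus_replicates(list(r1, r2)), "clamped")
  expect_equal(mcols(out)$neglog10_p, fisher_neglog10(c(300, 10)))
})

test_that("merge_union equals a sort-and-sweep oracle and is idempotent", {
  one <- mk_peaks("chr1", c(0, 500) + 1, c(100, 600))
  expect_equal(length(merge_union(list(one))), 2)
  two <- merge_union(list(mk_peaks("chr1", 1, 100), mk_peaks("chr1", 51, 150)))
  expect_equal(c(start(two), end(two)), c(1L, 150L))

  set.seed(99)
  colls <- list(x = random_peaks(120), y = random_peaks(80), z = random_peaks(40))
  merged <- merge_union(colls)
  oracle <- sweep_union(do.call(c, unname(lapply(colls, granges))))
  got <- data.frame(chrom = as.character(seqnames(merged)),
                    start = start(merged), end = end(merged))
  got <- got[order(got$chrom, got$start), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle[order(oracle$chrom, oracle$start), ])
  expect_lte(length(merged), sum(lengths(colls)))
  again <- merge_union(list(m = merged))
  expect_equal(granges(again), granges(merged), ignore_attr = TRUE)
  # each merged region knows its contributing collections
  expect_true(all(lengths(mcols(merged)$sources) >= 1))
})
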