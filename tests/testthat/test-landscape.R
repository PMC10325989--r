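mk_landscape <- function() {
  genes <- gene_models(GRanges("chrE", IRanges(800001, 808000), strand = "+"),
                       "Hand2")
  tad <- GRanges("chrE", IRanges(1, 1e6))
  mcols(tad)$tad_id <- "t1"
  list(genes = genes, tad = tad)
}

test_that("enhancer flags follow the inclusive 15-fold rule and promoter exclusion", {
  L <- mk_landscape()
  tf <- peak_collection(GRanges("chrE", IRanges(c(10000, 20000, 799000), width = 400)),
                        neglog10_p = c(20, 20, 20),
                        fold_enrichment = c(15, 14.9, 30),
                        name = c("ok", "weak", "promoterhit"))
  support <- granges(tf)  # marks/accessibility/conservation over every peak
  h3k <- peak_collection(support, neglog10_p = rep(8, 3), assay = "histone-ChIP")
  atac <- peak_collection(support, neglog10_p = rep(8, 3), assay = "ATAC")
  cand <- prioritize_enhancers(L$tad, tf, h3k, atac, support, L$genes)
  rownames(cand) <- cand$name
  expect_true(cand["ok", "passes"])           # exactly 15-fold is inclusive
  expect_false(cand["weak", "min_fold"])      # 14.9 fails the threshold
  expect_false(cand["weak", "passes"])
  expect_false(cand["promoterhit", "non_promoter"])
  expect_false(cand["promoterhit", "passes"])
  # passes is always the conjunction of the six flags
  expect_equal(cand$passes,
               cand$replicated_tf & cand$min_fold & cand$non_promoter &
                 cand$h3k27ac & cand$atac & cand$conserved)
  empty_tad <- GRanges("chrQ", IRanges(1, 1000))
  expect_equal(nrow(prioritize_enhancers(empty_tad, tf, h3k, atac, support,
                                         L$genes)), 0)
})

test_that("planted passing candidates are recovered with precision and recall 1", {
  enh <- gen_enhancer_landscape(sim_config(seed = 20))
  cand <- prioritize_enhancers(enh$tad, enh$tf_peaks, enh$h3k27ac, enh$atac,
                               enh$conserved, enh$genes)
  expect_equal(cand$name, enh$truth$name)
  expect_equal(cand$passes, enh$truth$passes)
  expect_equal(sum(cand$passes), 5)
  # each planted failure mode trips exactly its own flag
  flags <- c(low_fold = "min_fold", promoter = "non_promoter",
             no_h3k27ac = "h3k27ac", no_atac = "atac", no_conserved = "conserved")
  for (m in names(flags)) {
    rows <- cand[enh$truth$mode == m, ]
    expect_true(all(!rows[[flags[m]]]))
    expect_true(all(rows[setdiff(unname(flags), flags[m])] == TRUE))
  }
  # stricter settings never add candidates
  for (mf in c(20, 35)) {
    stricter <- prioritize_enhancers(enh$tad, enh$tf_peaks, enh$h3k27ac,
                                     enh$atac, enh$conserved, enh$genes,
                                     min_fold = mf)
    expect_true(all(stricter$name[stricter$passes] %in% cand$name[cand$passes]))
  }
  wider <- prioritize_enhancers(enh$tad, enh$tf_peaks, enh$h3k27ac, enh$atac,
                                enh$conserved, enh$genes,
                                promoter_halfwidth_bp = 50000)
  expect_true(all(wider$name[wider$passes] %in% cand$name[cand$passes]))
})

test_that("reporter tally adds known and newly reproducible limb enhancers", {
  ledger <- data.frame(
    element_id = sprintf("e%02d", 1:17),
    previously_known_limb = rep(c(TRUE, FALSE), c(3, 14)),
    tested = rep(c(FALSE, TRUE), c(3, 14)),
    any_tissue_activity = rep(c(FALSE, TRUE, FALSE), c(3, 7, 7)),
    reproducible_limb_domain = rep(c(FALSE, TRUE, FALSE), c(3, 3, 11)))
  tl <- tally_reporter_assays(ledger)
  expect_equal(tl$known_limb, 3)
  expect_equal(tl$tested, 14)
  expect_equal(tl$tissue_active, 7)
  expect_equal(tl$reproducible_limb, 3)
  expect_equal(tl$total_validated_limb, 6)

  empty <- ledger[0, ]
  expect_equal(unlist(tally_reporter_assays(empty)),
               c(known_limb = 0, tested = 0, tissue_active = 0,
                 reproducible_limb = 0, total_validated_limb = 0))

  bad <- ledger
  bad$tested[5] <- FALSE  # reproducible without being tested is contradictory
  expect_error(tally_reporter_assays(bad), "tested")

  set.seed(50)
  rnd <- data.frame(element_id = sprintf("r%02d", 1:40),
                    previously_known_limb = sample(c(TRUE, FALSE), 40, TRUE),
                    tested = TRUE,
                    any_tissue_activity = sample(c(TRUE, FALSE), 40, TRUE),
                    reproducible_limb_domain = sample(c(TRUE, FALSE), 40, TRUE))
  tl2 <- tally_reporter_assays(rnd)
  expect_equal(tl2$known_limb, nrow(rnd[rnd$previously_known_limb, ]))
  expect_equal(tl2$tissue_active, nrow(rnd[rnd$any_tissue_activity, ]))
  expect_equal(tl2$total_validated_limb,
               nrow(rnd[rnd$previously_known_limb, ]) +
                 nrow(rnd[rnd$reproducible_limb_domain, ]))
})

test_that("TAD regulatory score counts and sums distal sites only", {
  L <- mk_landscape()
  none <- tad_regulatory_score(L$tad, list(mk_peaks("chrE", integer(0), integer(0))),
                               L$genes)
  expect_equal(none$n_distal_sites, 0)
  expect_equal(none$summed_strength, 0)

  sites <- peak_collection(GRanges("chrE", IRanges(c(1000, 50000, 799500), width = 300)),
                           neglog10_p = c(12, 7, 25))
  sc <- tad_regulatory_score(L$tad, list(sites), L$genes)
  expect_equal(sc$n_distal_sites, 2)        # the 799500 site sits in the promoter
  expect_equal(sc$summed_strength, 12 + 7)
  plus <- peak_collection(GRanges("chrE", IRanges(200000, width = 300)),
                          neglog10_p = 5)
  sc2 <- tad_regulatory_score(L$tad, list(sites, plus), L$genes)
  expect_equal(sc2$n_distal_sites, sc$n_distal_sites + 1)
  expect_equal(sc2$summed_strength, sc$summed_strength + 5)

  set.seed(61)
  rnd <- peak_collection(GRanges("chrE", IRanges(sample.int(2e6, 80), width = 200)),
                         neglog10_p = runif(80, 1, 20))
  got <- tad_regulatory_score(L$tad, list(rnd), L$genes, 2000)
  n_want <- 0; s_want <- 0
  prom <- c(800001 - 2000, 800001 + 1999)
  for (i in seq_along(rnd)) {  # brute-force per-site loop
    s <- start(rnd)[i]; e <- end(rnd)[i]
    if (e < 1 || s > 1e6) next
    if (e >= prom[1] && s <= prom[2]) next
    n_want <- n_want + 1; s_want <- s_want + mcols(rnd)$neglog10_p[i]
  }
  expect_equal(got$n_distal_sites, n_want)
  expect_equal(got$summed_strength, s_want)
})

test_that("DEG TADs with planted higher scores show the expected one-sided trend", {
  mk_scores <- function(strengths) lapply(strengths, function(s)
    structure(list(tad_id = "t", n_distal_sites = round(s), summed_strength = s),
              class = "tad_score"))
  set.seed(71)
  deg <- mk_scores(runif(20, 50, 90))
  other <- mk_scores(runif(20, 10, 45))
  cmp <- compare_tad_scores(deg, other)
  expect_lt(cmp$strength$p_value, 0.05)
  expect_lt(cmp$count$p_value, 0.05)
  same <- compare_tad_scores(mk_scores(1:10), mk_scores(1:10))
  expect_gte(same$strength$p_value, 0.5)
  # single-element groups: the exact two-group rank p is returned as-is
  one <- compare_tad_scores(mk_scores(5), mk_scores(3))
  expect_true(one$strength$p_value > 0 && one$strength$p_value <= 1)
})
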