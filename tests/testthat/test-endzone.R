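test_that("gene filter uses the inclusive combined-replicate threshold", {
  cts <- rbind(
    toy_counts(list(gA = c(`50` = 600)), "c1_r1", "c1", 1L),
    toy_counts(list(gA = c(`50` = 400)), "c1_r2", "c1", 2L),
    toy_counts(list(gA = c(`60` = 900)), "c2_r1", "c2", 1L),
    toy_counts(list(gA = c(`60` = 100)), "c2_r2", "c2", 2L),
    toy_counts(list(gB = c(`50` = 600)), "c1_r1", "c1", 1L),
    toy_counts(list(gB = c(`50` = 399)), "c1_r2", "c1", 2L),
    toy_counts(list(gB = c(`60` = 2000)), "c2_r1", "c2", 1L))
  # gA: 600+400 = 1000 in c1 and 1000 in c2 -> kept (inclusive >= 1000)
  # gB: 999 in c1 -> dropped despite 2000 in c2
  expect_equal(filter_genes(cts, 1000), "gA")
  expect_setequal(filter_genes(cts, 0), c("gA", "gB"))
})

test_that("end-zone landmarks match direct arithmetic", {
  prof <- build_profile(c(50, 60, 75, 120, 130), c(200, 1000, 300, 40, 10))
  expect_equal(unname(prof$scaled), c(20, 100, 30, 4, 1))
  expect_equal(prof$max_pos, 60)
  expect_equal(prof$major, c(50, 60, 75))
  expect_equal(prof$mez, c(50, 75))
  expect_equal(prof$span, 25)
  expect_equal(prof$wavg, 98600 / 1550)  # 63.61 nt
  expect_equal(round(prof$wavg, 2), 63.61)

  # degenerate single-isoform profile
  p1 <- build_profile(100, 10)
  expect_equal(p1$max_pos, 100)
  expect_equal(p1$span, 0)
  expect_equal(p1$wavg, 100)

  # scale invariance: any positive rescaling gives the identical profile
  p2 <- build_profile(c(50, 60, 75, 120, 130),
                      7.3 * c(200, 1000, 300, 40, 10))
  expect_equal(p2$scaled, prof$scaled)
  expect_equal(p2$wavg, prof$wavg)

  # max-isoform ties break to the most ORF-proximal offset
  pt <- build_profile(c(30, 80), c(5, 5))
  expect_equal(pt$max_pos, 30)
})

test_that("percentile coordinates walk the cumulative distribution", {
  pc <- percentile_coords(c(50, 60, 75), c(200, 1000, 300))
  expect_equal(unname(pc), c(50, 60, 60, 60, 75))
  # single site: all five coordinates collapse onto it
  expect_equal(unname(percentile_coords(42, 7)), rep(42, 5))
  # uniform counts at offsets 1..4
  expect_equal(unname(percentile_coords(1:4, rep(1, 4))), c(1, 1, 2, 3, 4))
})

test_that("percentile coordinates are non-decreasing in q", {
  withr::with_seed(314, {
    for (i in 1:50) {
      n <- sample(1:20, 1)
      offs <- sort(sample(1:400, n))
      cnts <- stats::rpois(n, 40) + 1
      pc <- percentile_coords(offs, cnts)
      expect_true(all(diff(pc) >= 0))
    }
  })
})

test_that("weighted average is translation-equivariant", {
  offs <- c(50, 60, 75); cnts <- c(200, 1000, 300)
  p0 <- build_profile(offs, cnts)
  p_shift <- build_profile(offs + 13, cnts)
  expect_equal(p_shift$wavg, p0$wavg + 13)
})

test_that("profiled weighted averages converge to the truth ledger", {
  spec <- synthetic_spec(n_genes = 5, depth_per_replicate = 1e6,
                         n_replicates = 1, conditions = c(ref = 0), seed = 60)
  b <- build_genome(spec)
  tr <- assign_site_weights(spec, b)
  cts <- sample_counts(tr, spec)
  prof <- build_profiles(cts)
  m <- merge(prof$landmarks, tr$wavg,
             by.x = c("gene", "condition"), by.y = c("gene_id", "condition"))
  expect_true(all(abs(m$wavg - m$true_wavg) < 0.5))
})

test_that("landmark summary flags an injected proximal shift", {
  # every gene responds, so the paired test must register the shift
  spec <- small_spec(sensitive_fraction = 1, depth = 2000,
                     conditions = c(ref = 0, slow = 4))
  b <- build_genome(spec)
  tr <- assign_site_weights(spec, b)
  cts <- sample_counts(tr, spec)
  gs <- filter_genes(cts, 1000)
  prof <- build_profiles(cts, gs)
  smry <- landmark_summary(prof, comparisons = list(c("slow", "ref")))
  med <- smry$medians
  expect_lt(med$wavg[med$condition == "slow"],
            med$wavg[med$condition == "ref"])
  wtest <- smry$tests[landmark == "wavg"]
  expect_true(wtest$flagged)

  # identical condition compared with itself: nothing flagged
  same <- landmark_summary(prof, comparisons = list(c("ref", "ref")))
  expect_true(all(!same$tests$flagged))
  expect_true(all(same$tests$p == 1))

  # meta-gene profile covers all offsets and is 0 where nothing is expressed
  expect_equal(nrow(smry$metagene), 2 * 400)
  expect_true(all(smry$metagene$mean_pct >= 0))
})

test_that("percent coordinate usage divides covered genes by non-A genes", {
  chrom <- paste0(strrep("C", 20), "GATTACAGGG", strrep("C", 30),
                  "GGGGGGGGGG", strrep("C", 20))
  genes <- data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    orf_start = c(1L, 51L), orf_end = c(20L, 60L),
    utr_start = c(21L, 61L), utr_end = c(30L, 70L), utr_len = 10L)
  bundle <- polyAshift:::new_genome_bundle(c(chr1 = chrom), genes)
  # offset 2: g1 base 'A' (GATTACAGGG), g2 base 'G' -> one non-A gene
  cts <- toy_counts(list(g2 = c(`2` = 5)))
  u <- percent_coordinate_usage(cts, bundle, c("g1", "g2"), utr_len = 10L)
  expect_equal(u$n_non_a[2], 1)
  expect_equal(u$pct_usage[2], 100)
  # offset 1: both genes non-A ('G'), only g2 covered -> 50
  cts2 <- toy_counts(list(g2 = c(`1` = 5)))
  u2 <- percent_coordinate_usage(cts2, bundle, c("g1", "g2"), utr_len = 10L)
  expect_equal(u2$pct_usage[1], 50)
  # no reads anywhere -> 0 at all defined offsets
  u3 <- percent_coordinate_usage(cts2[0], bundle, c("g1", "g2"), utr_len = 10L)
  expect_true(all(u3$pct_usage[u3$n_non_a > 0] == 0))
})

test_that("replicate correlations behave at the three levels", {
  r1 <- toy_counts(list(g1 = c(`10` = 100, `20` = 50),
                        g2 = c(`30` = 9, `40` = 200)), "c1_r1", "c1", 1L)
  r2 <- data.table::copy(r1)[, `:=`(sample = "c1_r2", replicate = 2L)]
  dup <- rbind(r1, r2)
  rc <- replicate_correlations(dup)
  expect_equal(rc$total_r, 1)
  expect_equal(rc$isoform_r, 1)
  expect_equal(rc$profile_r$r, c(1, 1))
  # the 9-read isoform is excluded from the isoform-level correlation
  expect_equal(rc$n_isoforms, 3L)

  # perfectly anticorrelated totals
  anti <- rbind(
    toy_counts(list(g1 = c(`10` = 1), g2 = c(`10` = 2), g3 = c(`10` = 3)),
               "c1_r1", "c1", 1L),
    toy_counts(list(g1 = c(`10` = 3), g2 = c(`10` = 2), g3 = c(`10` = 1)),
               "c1_r2", "c1", 2L))
  expect_equal(replicate_correlations(anti)$total_r, -1)
})
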