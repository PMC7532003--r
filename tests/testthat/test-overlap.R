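test_that("overlap probability matches exhaustive enumeration", {
  # full identity case has a closed form
  expect_equal(overlap_probability(10, 3, 3, 3), 1 / choose(10, 3),
               tolerance = 1e-12)
  # zero required overlap is certain
  expect_equal(overlap_probability(10, 4, 5, 0), 1)
  expect_equal(overlap_probability(400, 1, 1, 1), 1 / 400, tolerance = 1e-12)

  # exhaustive subset enumeration for every configuration up to N = 12
  for (n in c(5, 8, 12)) {
    for (a in 1:n) {
      for (b in 1:n) {
        for (cc in 0:min(a, b)) {
          if (a + b - cc > n) next
          expect_equal(overlap_probability(n, a, b, cc),
                       enumerate_overlap(n, a, b, cc),
                       tolerance = 1e-12,
                       info = sprintf("N=%d a=%d b=%d c=%d", n, a, b, cc))
        }
      }
    }
  }
  # spot checks at N = 20
  withr::with_seed(77, {
    for (i in 1:25) {
      a <- sample(1:20, 1); b <- sample(1:20, 1)
      cc <- sample(0:min(a, b), 1)
      if (a + b - cc > 20) next
      expect_equal(overlap_probability(20, a, b, cc),
                   enumerate_overlap(20, a, b, cc), tolerance = 1e-12)
    }
  })
})

test_that("overlap probability is symmetric and monotone in the overlap", {
  expect_equal(overlap_probability(100, 30, 12, 7),
               overlap_probability(100, 12, 30, 7), tolerance = 1e-13)
  ps <- vapply(0:12, function(cc) overlap_probability(100, 30, 12, cc),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
  # impossible configurations are rejected
  expect_error(overlap_probability(10, 8, 8, 2), "impossible")
})

test_that("overlap probability agrees with the hypergeometric survival function", {
  # independent route: stats::phyper upper tail
  cases <- list(c(2790, 1898, 605, 462), c(100, 30, 12, 7),
                c(50, 25, 25, 20), c(400, 10, 10, 3))
  for (cs in cases) {
    expect_equal(overlap_probability(cs[1], cs[2], cs[3], cs[4]),
                 stats::phyper(cs[4] - 1, cs[2], cs[1] - cs[2], cs[3],
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("combined major end zone is the cross-condition union", {
  # gene with major zones [50,75] in ref and [60,90] in the test condition
  cts <- rbind(
    toy_counts(list(gZ = c(`50` = 100, `60` = 1000, `75` = 80, `90` = 20)),
               "ref_r1", "ref", 1L),
    toy_counts(list(gZ = c(`60` = 500, `75` = 300, `90` = 1000)),
               "tst_r1", "tst", 1L))
  prof <- build_profiles(cts)
  # synthetic sequence with 12 As inside offsets [50, 90]
  utr <- strrep("C", 400)
  for (i in 55:66) substr(utr, i, i) <- "A"
  chrom <- paste0(strrep("G", 20), utr)
  bundle <- polyAshift:::new_genome_bundle(
    c(chr1 = chrom),
    data.table(gene_id = "gZ", chrom = "chr1", strand = "+",
               orf_start = 1L, orf_end = 20L, utr_start = 21L,
               utr_end = 420L, utr_len = 400L))
  cz <- combined_major_end_zone(prof$scaled, bundle)
  expect_equal(cz$cmz5, 50)
  expect_equal(cz$cmz3, 90)
  expect_equal(cz$n_non_a, 41 - 12)  # 29 eligible positions

  # idempotence: identical zones in all conditions give that zone
  same <- rbind(
    toy_counts(list(gZ = c(`50` = 100, `75` = 1000)), "a_r1", "a", 1L),
    toy_counts(list(gZ = c(`50` = 100, `75` = 1000)), "b_r1", "b", 1L))
  czs <- combined_major_end_zone(build_profiles(same)$scaled, bundle)
  expect_equal(c(czs$cmz5, czs$cmz3), c(50, 75))
})

test_that("genewise overlap summary covers both window variants", {
  utr <- strrep("C", 400)
  chrom <- paste0(strrep("G", 20), utr)
  bundle <- polyAshift:::new_genome_bundle(
    c(chr1 = chrom),
    data.table(gene_id = "gZ", chrom = "chr1", strand = "+",
               orf_start = 1L, orf_end = 20L, utr_start = 21L,
               utr_end = 420L, utr_len = 400L))
  # both conditions reuse the same single site
  cts <- rbind(toy_counts(list(gZ = c(`100` = 50)), "a_r1", "a", 1L),
               toy_counts(list(gZ = c(`100` = 70)), "b_r1", "b", 1L))
  prof <- build_profiles(cts)
  ful <- genewise_overlap_summary(prof$scaled, bundle, "a", "b", "full")
  expect_equal(ful$table$n, 400)
  expect_equal(ful$median_p, 1 / 400, tolerance = 1e-12)
  # combined window of a single shared site has N = 1 and P = 1
  comb <- genewise_overlap_summary(prof$scaled, bundle, "a", "b", "combined")
  expect_equal(comb$table$n, 1)
  expect_equal(comb$median_p, 1)

  # no shared positions: P = 1 under either window
  cts2 <- rbind(toy_counts(list(gZ = c(`100` = 50)), "a_r1", "a", 1L),
                toy_counts(list(gZ = c(`200` = 70)), "b_r1", "b", 1L))
  prof2 <- build_profiles(cts2)
  expect_equal(
    genewise_overlap_summary(prof2$scaled, bundle, "a", "b", "full")$median_p, 1)

  # the permissive full-UTR window cannot make overlap look more likely
  cts3 <- rbind(
    toy_counts(list(gZ = c(`100` = 50, `110` = 40, `150` = 60)), "a_r1", "a", 1L),
    toy_counts(list(gZ = c(`100` = 50, `110` = 40, `160` = 60)), "b_r1", "b", 1L))
  prof3 <- build_profiles(cts3)
  p_comb <- genewise_overlap_summary(prof3$scaled, bundle, "a", "b", "combined")$median_p
  p_full <- genewise_overlap_summary(prof3$scaled, bundle, "a", "b", "full")$median_p
  expect_lte(p_full, p_comb)
})
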