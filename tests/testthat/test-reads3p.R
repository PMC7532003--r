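test_that("read parsing applies the leading-T and ambiguity rules", {
  p <- parse_reads(c("TTTTGCAGCTAGCTAGCTAGG",   # 4 Ts + 17-nt core
                     "GATTACAGATTACAGATTACA",   # no leading T
                     "TTNTAGCTAGCTAGCTAGCTA",   # ambiguous base
                     "TTTGCAGCTAGC"))           # remainder < 17 nt
  expect_equal(p$status, c("ok", "no_leading_t", "ambiguous", "too_short"))
  expect_equal(p$t_count[1], 4L)
  expect_equal(p$core17[1], "GCAGCTAGCTAGCTAGG")
  expect_equal(nchar(p$core17[1]), 17L)
})

test_that("cores place only at unique exact matches, on either strand", {
  # hand-built genome: gene on +, with one unique and one duplicated 17-mer
  core_a <- "GCAGCTAGCTAGCTAGG"
  core_b <- "ACGTACGTACGTACGTA"
  pad1 <- strrep("C", 30)
  chrom <- paste0(pad1, core_a, strrep("G", 10), core_b,
                  strrep("C", 10), core_b, strrep("G", 10))
  bundle <- polyAshift:::new_genome_bundle(
    c(chr1 = chrom),
    data.table(gene_id = "gX", chrom = "chr1", strand = "+",
               orf_start = 1L, orf_end = 20L, utr_start = 21L,
               utr_end = nchar(chrom), utr_len = nchar(chrom) - 20L))

  # read core = revcomp of the sense 17-mer -> plus-strand placement at its end
  pl <- place_cores(polyAshift:::revcomp(core_a), bundle)
  expect_equal(pl$status, "unique")
  expect_equal(pl$strand, "+")
  expect_equal(pl$pos, 30L + 17L)

  # forward match of the core itself implies a minus-strand endpoint at start
  pl2 <- place_cores(core_a, bundle)
  expect_equal(pl2$status, "unique")
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$pos, 31L)

  expect_equal(place_cores(polyAshift:::revcomp(core_b), bundle)$status, "multi")
  expect_equal(place_cores(strrep("T", 17), bundle)$status, "unmapped")
})

test_that("internal-priming filter requires T count to exceed the A-run", {
  expect_true(internal_priming_keep(5L, 4L))
  expect_false(internal_priming_keep(4L, 4L))
  expect_true(internal_priming_keep(1L, 0L))

  # genomic A-run measured on the sense strand downstream of the endpoint
  chrom <- paste0(strrep("C", 40), "AAAA", strrep("G", 40))
  bundle <- polyAshift:::new_genome_bundle(
    c(chr1 = chrom),
    data.table(gene_id = "gX", chrom = "chr1", strand = "+",
               orf_start = 1L, orf_end = 10L, utr_start = 11L,
               utr_end = nchar(chrom), utr_len = nchar(chrom) - 10L))
  expect_equal(polyAshift:::genomic_a_run(bundle, "chr1", "+", 40L), 4L)
  expect_equal(polyAshift:::genomic_a_run(bundle, "chr1", "+", 50L), 0L)
  # minus strand: A-run on the sense strand is a T-run leftward on forward
  chrom2 <- paste0(strrep("C", 20), "TTT", strrep("G", 20))
  bundle2 <- polyAshift:::new_genome_bundle(
    c(chr1 = chrom2),
    data.table(gene_id = "gY", chrom = "chr1", strand = "-",
               orf_start = 40L, orf_end = 43L, utr_start = 1L,
               utr_end = 39L, utr_len = 39L))
  expect_equal(polyAshift:::genomic_a_run(bundle2, "chr1", "-", 24L), 3L)
})

test_that("endpoints are assigned to genes by 3'UTR window and strand", {
  d <- small_dataset()
  g <- d$bundle$genes[strand == "+"][1]
  # a known poly(A)-site offset (non-A by construction) inside the window,
  # and a position one past the window's end
  site <- d$truth$sites[gene_id == g$gene_id]$offset[1]
  ep <- data.table(chrom = g$chrom, strand = "+",
                   pos = c(g$orf_end + site, g$orf_end + g$utr_len + 1L),
                   weight = c(3, 2))
  tab <- tabulate_endpoints(ep, d$bundle)
  expect_equal(tab$counts$gene, g$gene_id)
  expect_equal(tab$counts$offset, site)
  expect_equal(tab$counts$count, 3)
  expect_equal(tab$unassigned, 2)
})

test_that("depth normalization scales to the target and preserves ratios", {
  cts <- toy_counts(list(g1 = c(`10` = 3e6, `20` = 1e6),
                         g2 = c(`30` = 1e6)))
  sc <- normalize_depth(cts, 25e6)
  expect_equal(sum(sc$count), 25e6, tolerance = 1e-6)
  expect_equal(sc$count, cts$count * 5)
  # ratios of any two counts unchanged
  expect_equal(sc$count[1] / sc$count[2], cts$count[1] / cts$count[2])
  # a table already at target passes through unchanged
  sc2 <- normalize_depth(sc, 25e6)
  expect_equal(sc2$count, sc$count)
  expect_error(normalize_depth(cts[0]), "empty")
})

test_that("decoy-free synthetic reads round-trip to the exact sampled counts", {
  d <- small_dataset()
  dir <- tempfile(); dir.create(dir)
  er <- emit_reads(d$counts[sample == "slow_rep2"], d$bundle, d$spec, dir)
  res <- process_sample_fastq(er$path, d$bundle, "slow_rep2", "slow", 2)
  m <- merge(d$counts[sample == "slow_rep2", list(gene, offset, count)],
             res$counts[, list(gene, offset, count)],
             by = c("gene", "offset"), all = TRUE)
  expect_false(anyNA(m))
  expect_equal(m$count.x, m$count.y)
  expect_equal(res$stats$n_internal_priming, 0L)
})

test_that("every decoy read with T count <= downstream A-run is dropped", {
  spec <- small_spec(n_genes = 12, depth = 300, seed = 21,
                     decoy_fraction = 0.25)
  b <- build_genome(spec)
  tr <- assign_site_weights(spec, b)
  cts <- sample_counts(tr, spec)
  dir <- tempfile(); dir.create(dir)
  er <- suppressWarnings(emit_reads(cts[sample == "ref_rep1"], b, spec, dir))
  expect_gt(er$n_decoys, 0)
  res <- process_sample_fastq(er$path, b, "ref_rep1", "ref", 1)
  # all decoys are removed (by the priming filter, or before it if the decoy
  # core is unmappable), and the genuine counts come back exactly
  m <- merge(cts[sample == "ref_rep1", list(gene, offset, count)],
             res$counts[, list(gene, offset, count)],
             by = c("gene", "offset"), all = TRUE)
  expect_false(anyNA(m))
  expect_equal(m$count.x, m$count.y)
  expect_equal(res$stats$n_internal_priming + res$stats$n_unmapped +
                 res$stats$n_multi + res$stats$n_unassigned,
               er$n_decoys)
})
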