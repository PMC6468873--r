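test_that("informative-site selection applies the het definition", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:4 * 1000L,
    germ_ref = c(50L, 90L, 5L, 45L),
    germ_alt = c(50L, 10L, 4L, 55L), # VAFs 0.5, 0.1, 0.44 (depth 9), 0.55
    tum_ref = 50L, tum_alt = 50L
  )
  inf <- informative_sites(sites)
  expect_equal(inf$pos, c(1000L, 4000L))
})

test_that("segment imbalance test matches exact binomial oracles", {
  ## single balanced site: p = 1 up to discreteness, never LOH
  s1 <- data.frame(chrom = "chr1", pos = 1L, germ_ref = 50L, germ_alt = 50L,
                   tum_ref = 50L, tum_alt = 50L)
  r1 <- test_segment_imbalance(s1)
  expect_gt(r1$p_value, 0.9)
  expect_false(r1$is_loh)

  ## one site 90 ref / 10 alt: exact two-sided binomial tail sum
  s2 <- data.frame(chrom = "chr1", pos = 1L, germ_ref = 50L, germ_alt = 50L,
                   tum_ref = 90L, tum_alt = 10L)
  r2 <- test_segment_imbalance(s2)
  ## frozen from oracle_binom_p(10, 100): direct summation of both tails
  expect_equal(oracle_binom_p(10, 100), 3.06329029507349e-17, tolerance = 1e-10)
  expect_equal(r2$p_value, oracle_binom_p(10, 100), tolerance = 1e-10)

  ## ten sites at 30 ref / 2 alt: Fisher combination flags LOH
  s3 <- data.frame(chrom = "chr1", pos = 1:10, germ_ref = 15L, germ_alt = 15L,
                   tum_ref = 30L, tum_alt = 2L)
  r3 <- test_segment_imbalance(s3)
  p_site <- oracle_binom_p(2, 32)
  p_manual <- pchisq(-2 * sum(log(rep(p_site, 10))), df = 20, lower.tail = FALSE)
  expect_equal(r3$p_value, p_manual, tolerance = 1e-8)
  expect_true(r3$is_loh)
  expect_equal(r3$affected_allele, "alt_lost")

  ## zero tumor depth everywhere: untestable
  s4 <- data.frame(chrom = "chr1", pos = 1:6, germ_ref = 20L, germ_alt = 20L,
                   tum_ref = 0L, tum_alt = 0L)
  r4 <- test_segment_imbalance(s4)
  expect_equal(r4$p_value, 1)
  expect_false(r4$is_loh)
  expect_equal(r4$affected_allele, "unknown")
})

test_that("segmentation handles null, planted and empty inputs", {
  ## 20 balanced sites: one segment, no LOH
  flat <- make_gene_sites("chr1", 20, 100, 0.5, seed = 5)
  segs <- segment_vaf(flat, seed = 5)
  expect_equal(nrow(segs), 1L)
  expect_false(any(segs$is_loh))

  ## 10 balanced then 10 shifted: breakpoint lands between sites 10 and 11
  shifted <- rbind(
    make_gene_sites("chr1", 10, 100, 0.5, seed = 6),
    make_gene_sites("chr1", 10, 100, 0.9, seed = 7, start = 30001L)
  )
  segs2 <- segment_vaf(shifted, seed = 6)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$end[1], shifted$pos[10])
  expect_equal(segs2$start[2], shifted$pos[11])
  expect_equal(segs2$is_loh, c(FALSE, TRUE))

  ## empty input
  expect_equal(nrow(segment_vaf(flat[0, ])), 0L)

  ## fewer than min_sites on a chromosome: single untestable segment
  tiny <- make_gene_sites("chr9", 3, 100, 0.9, seed = 8)
  segs3 <- segment_vaf(tiny)
  expect_equal(nrow(segs3), 1L)
  expect_true(segs3$untestable)
  expect_false(segs3$is_loh)
})

test_that("maximal segment statistic equals the brute-force search", {
  for (seed in 1:30) {
    sim <- withr::with_seed(seed, {
      n <- sample(10:30, 1)
      d <- abs(rnorm(n, 0, 0.05))
      if (seed %% 2 == 0) { # plant a shifted window half the time
        w <- sample(5:(n - 5), 1)
        at <- sample(0:(n - w), 1)
        d[(at + 1):(at + w)] <- d[(at + 1):(at + w)] + 0.3
      }
      d
    })
    got <- germsoma:::max_t_segment(sim, 5)
    want <- oracle_max_t_segment(sim, 5)
    expect_equal(got$t, want$t, tolerance = 1e-10, label = sprintf("seed %d t", seed))
    expect_equal(got$i, want$i, label = sprintf("seed %d i", seed))
    expect_equal(got$j, want$j, label = sprintf("seed %d j", seed))
  }
})

test_that("gene-level calls require overlap and resolve the lost allele", {
  intervals <- data.frame(
    gene = c("GENE001", "GENE002", "GENE003"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10001L, 200001L, 10001L),
    end = c(20000L, 210000L, 20000L),
    stringsAsFactors = FALSE
  )
  segments <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(5000L, 150000L, 5000L),
    end = c(100000L, 400000L, 400000L),
    n_sites = 10L,
    mean_shift = c(0.37, 0.02, 0.03),
    p_value = c(1e-12, 0.8, 0.7),
    is_loh = c(TRUE, FALSE, FALSE),
    affected_allele = c("ref_lost", "unknown", "unknown"),
    untestable = FALSE,
    stringsAsFactors = FALSE
  )
  fh <- data.frame(gene = "GENE001", chrom = "chr1", pos = 15000L, tumor_vaf = 0.85)
  calls <- call_gene_loh(segments, intervals, first_hits = fh, sample_id = "S01")
  expect_equal(calls$is_loh, c(TRUE, FALSE, FALSE))
  expect_true(calls$retains_germline_variant[1]) # wild-type allele lost
  expect_true(is.na(calls$retains_germline_variant[2]))

  ## gene absent from the interval file: warning, no call
  fh2 <- rbind(fh, data.frame(gene = "GENE099", chrom = "chr3", pos = 1L,
                              tumor_vaf = 0.9))
  expect_warning(call_gene_loh(segments, intervals, first_hits = fh2), "GENE099")
})

test_that("balanced tumors stay below the type-I bound", {
  ## 200 copy-balanced genes, 8 sites each at depth ~80: the fraction of
  ## genes called LOH must not exceed 2 * alpha_loh
  alpha_loh <- 0.01
  calls <- withr::with_seed(99, {
    vapply(1:200, function(g) {
      sites <- make_gene_sites(sprintf("chr%d", g), 8, 80, 0.5)
      segs <- segment_vaf(sites, alpha_loh = alpha_loh, seed = g)
      any(segs$is_loh)
    }, TRUE)
  })
  expect_lte(mean(calls), 2 * alpha_loh)
})
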