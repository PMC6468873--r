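loh_call_row <- function(gene, sample_id = "S01", is_loh = TRUE,
                         retains = TRUE) {
  data.frame(
    gene = gene, sample_id = sample_id, is_loh = is_loh,
    seg_chrom = "chr1", seg_start = 1L, seg_end = 1000000L,
    mean_shift = 0.37, p_value = 1e-10, affected_allele = "ref_lost",
    retains_germline_variant = retains, stringsAsFactors = FALSE
  )
}

test_that("pairing assigns the three second-hit classes", {
  germ <- make_variants(
    make_variant(gene = "ADCY8", pos = 1747L), # + distinct somatic SNV
    make_variant(gene = "BRCA2", chrom = "chr2", pos = 4963L, ref = "CT",
                 alt = "C", consequence = "truncating"), # + LOH
    make_variant(gene = "HSPG2", chrom = "chr3", pos = 3148L) # + both
  )
  soma <- make_variants(
    make_variant(origin = "somatic", gene = "ADCY8", pos = 458L,
                 depth = 100L, alt_depth = 40L),
    make_variant(origin = "somatic", gene = "HSPG2", chrom = "chr3",
                 pos = 7406L, depth = 100L, alt_depth = 38L)
  )
  loh <- rbind(loh_call_row("BRCA2"), loh_call_row("HSPG2"))
  cand <- pair_two_hits(germ, soma, loh)
  expect_equal(cand$gene, c("ADCY8", "BRCA2", "HSPG2")) # (gene, sample) order
  expect_equal(cand$second_hit_class, c("somatic_snv", "loh", "both"))
  expect_equal(cand$second_pos[1], 458L)
  expect_true(cand$wildtype_allele_lost[2])
  ## germline-only and somatic-only genes never appear
  germ2 <- rbind(germ, make_variant(gene = "LONE1", chrom = "chr4", pos = 1L))
  soma2 <- rbind(soma, make_variant(origin = "somatic", gene = "LONE2",
                                    chrom = "chr4", pos = 2L))
  cand2 <- pair_two_hits(germ2, soma2, loh)
  expect_false(any(c("LONE1", "LONE2") %in% cand2$gene))
})

test_that("a somatic call at the first-hit position with a different alt is distinct", {
  germ <- make_variant(gene = "G1", pos = 100L, ref = "C", alt = "T")
  soma_same <- make_variant(origin = "somatic", gene = "G1", pos = 100L,
                            ref = "C", alt = "T", depth = 100L, alt_depth = 40L)
  soma_diff <- make_variant(origin = "somatic", gene = "G1", pos = 100L,
                            ref = "C", alt = "G", depth = 100L, alt_depth = 40L)
  expect_equal(nrow(pair_two_hits(germ, soma_same, NULL)), 0L)
  cand <- pair_two_hits(germ, soma_diff, NULL)
  expect_equal(cand$second_hit_class, "somatic_snv")
})

test_that("summaries obey inclusion-exclusion", {
  germ <- do.call(rbind, lapply(1:6, function(i) {
    make_variant(gene = sprintf("G%d", i), chrom = sprintf("chr%d", i), pos = 10L)
  }))
  soma <- do.call(rbind, lapply(c(1, 2, 6), function(i) {
    make_variant(origin = "somatic", gene = sprintf("G%d", i),
                 chrom = sprintf("chr%d", i), pos = 999L,
                 depth = 100L, alt_depth = 40L)
  }))
  loh <- do.call(rbind, lapply(c(3, 4, 5, 6), function(i) loh_call_row(sprintf("G%d", i))))
  cand <- pair_two_hits(germ, soma, loh)
  s <- summarize_candidates(cand)
  expect_equal(unname(s$by_class), c(2L, 3L, 1L))
  expect_equal(s$n_candidates, 6L)
  expect_equal(s$n_with_somatic_snv + s$n_with_loh - s$n_both, s$n_candidates)
  ## empty table: all zero
  s0 <- summarize_candidates(cand[0, ])
  expect_equal(s0$n_candidates, 0L)
  expect_equal(unname(s0$by_class), c(0L, 0L, 0L))
})

test_that("keyword prioritization flags by function text without removing", {
  cand <- data.frame(
    gene = c("BLM", "TTN", "NOMAP"),
    sample_id = "S01", stringsAsFactors = FALSE
  )
  km <- data.frame(
    gene = c("BLM", "TTN"),
    function_text = c("DNA helicase, double-strand break repair via homologous recombination",
                      "muscular sarcomere protein"),
    stringsAsFactors = FALSE
  )
  out <- apply_function_prioritization(cand, km)
  expect_equal(nrow(out), 3L) # annotate, never remove
  expect_true(out$priority_flag[out$gene == "BLM"])
  expect_false(out$priority_flag[out$gene == "TTN"])
  expect_equal(out$gene[1], "BLM") # flagged first
  expect_equal(attr(out, "unmapped_genes"), "NOMAP")
  ## empty keyword list: no flags
  out2 <- apply_function_prioritization(cand, km, keywords = character(0))
  expect_false(any(out2$priority_flag))
})

test_that("planted two-hit genes are recovered end to end, nothing else", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_samples = 6, n_lowqc_tumors = 0L,
                       burden_per_mb = 20, seed = 77)
  gen <- generate_cohort(cfg, dir)
  rep <- run_pipeline(run_config(dir, file.path(dir, "out"), seed = 77))
  truth <- gen$ground_truth$planted_twohit
  got <- rep$candidates
  expect_setequal(
    paste(got$gene, got$sample_id),
    paste(truth$gene, truth$sample_id)
  )
  expect_equal(
    got$second_hit_class[match(truth$gene, got$gene)],
    truth$second_hit_type
  )
  ## inclusion-exclusion on the run
  s <- summarize_candidates(got)
  expect_equal(s$n_with_somatic_snv + s$n_with_loh - s$n_both, s$n_candidates)
  ## candidate table writer emits the report layout
  tab <- read.delim(file.path(dir, "out", "candidate_table.tsv"))
  expect_named(tab, c("gene", "family", "genetic_variant", "path_tools",
                      "pop_freq", "second_hit_class"))
  expect_true(all(grepl("^\\d+/60,706$|^FS$|^\\d/6$",
                        c(tab$path_tools, tab$pop_freq))))
})
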