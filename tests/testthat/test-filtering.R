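test_that("pathogenicity scoring counts passing tools", {
  df <- make_variants(
    make_variant(), # all six
    make_variant(polyphen2 = FALSE, mutationtaster = FALSE, lrt = FALSE), # 3/6
    make_variant(phylop = FALSE, sift = FALSE, polyphen2 = FALSE,
                 mutationtaster = FALSE, lrt = FALSE, cadd15 = FALSE) # 0/6
  )
  np <- score_pathogenicity(df)
  expect_equal(as.integer(np), c(6L, 3L, 0L))
  expect_setequal(attr(np, "passing_tools")[[2]], c("phylop", "sift", "cadd15"))
  ## missing tool column counts as fail, warned once
  df$lrt <- NULL
  expect_warning(np2 <- score_pathogenicity(df), "lrt")
  expect_equal(as.integer(np2), c(5L, 3L, 0L))
})

test_that("germline cascade keeps the worked examples and drops the rest", {
  cfg <- filter_config()
  recs <- make_variants(
    ## rare frameshift, well covered: kept
    make_variant(gene = "BRCA2", ref = "CT", alt = "C",
                 consequence = "truncating", depth = 95L, alt_depth = 48L,
                 pop_allele_count = 0L, pop_allele_number = 60706L),
    ## rare missense 6/6 at 1/60,570: kept
    make_variant(gene = "BLM", pos = 2069L, pop_allele_count = 1L,
                 pop_allele_number = 60570L),
    ## synonymous: removed
    make_variant(gene = "GENE009", pos = 3000L, consequence = "synonymous"),
    ## common missense: removed
    make_variant(gene = "GENE010", pos = 4000L, pop_allele_count = 3000L,
                 pop_allele_number = 60000L),
    ## missense 2/6: removed
    make_variant(gene = "GENE011", pos = 5000L, polyphen2 = FALSE,
                 mutationtaster = FALSE, lrt = FALSE, cadd15 = FALSE),
    ## under-covered truncating: removed
    make_variant(gene = "GENE012", pos = 6000L, consequence = "truncating",
                 depth = 9L, alt_depth = 4L)
  )
  kept <- filter_germline(recs, cfg)
  expect_setequal(kept$gene, c("BRCA2", "BLM"))
  tr <- filter_germline(recs, cfg, trace = TRUE)
  expect_equal(nrow(tr$kept) + nrow(tr$removed), nrow(recs))
  expect_match(tr$removed$filter_trace[tr$removed$gene == "GENE012"], "min_depth")
  expect_match(tr$removed$filter_trace[tr$removed$gene == "GENE010"], "rare_in_population")
})

test_that("somatic cascade enforces dual depth, VAF and germline exclusion", {
  cfg <- filter_config()
  germ <- make_variant(gene = "GENE001", pos = 1000L, depth = 80L, alt_depth = 40L)
  soma <- make_variants(
    ## VAF exactly 0.20 with both depths adequate: kept (inclusive boundary)
    make_variant(origin = "somatic", gene = "GENE002", pos = 2000L,
                 depth = 100L, alt_depth = 20L, lrt = FALSE, phylop = FALSE),
    ## VAF 0.05: removed
    make_variant(origin = "somatic", gene = "GENE003", pos = 3000L,
                 depth = 100L, alt_depth = 5L),
    ## VAF 0.5 but germline depth 6: removed (dual >= 10x rule)
    make_variant(origin = "somatic", gene = "GENE004", pos = 4000L,
                 depth = 100L, alt_depth = 50L),
    ## same chrom/pos/ref/alt as a germline call: removed
    make_variant(origin = "somatic", gene = "GENE001", pos = 1000L,
                 depth = 90L, alt_depth = 40L)
  )
  soma$normal_depth <- c(60L, 70L, 6L, 85L)
  kept <- filter_somatic(soma, germ, cfg)
  expect_equal(kept$gene, "GENE002")
  tr <- filter_somatic(soma, germ, cfg, trace = TRUE)
  expect_match(tr$removed$filter_trace[tr$removed$gene == "GENE004"], "min_germline_depth")
  expect_match(tr$removed$filter_trace[tr$removed$gene == "GENE001"], "not_in_germline")
})

test_that("absent germline coverage fails the somatic depth rule", {
  germ <- make_variant()[0, ]
  soma <- make_variant(origin = "somatic", gene = "GENEX", pos = 9000L,
                       depth = 100L, alt_depth = 50L)
  expect_equal(nrow(filter_somatic(soma, germ, filter_config())), 0L)
})

test_that("cascades match the naive per-record oracle", {
  cfg <- filter_config()
  for (seed in c(101, 202, 303)) {
    germ <- random_variant_table(200, "germline", seed)
    expect_equal(
      filter_germline(germ, cfg),
      oracle_filter_germline(germ, cfg),
      ignore_attr = TRUE
    )
    soma <- random_variant_table(200, "somatic", seed + 7)
    expect_equal(
      filter_somatic(soma, germ, cfg),
      oracle_filter_somatic(soma, germ, cfg),
      ignore_attr = TRUE
    )
  }
})

test_that("raising any threshold never enlarges the surviving set", {
  germ <- random_variant_table(200, "germline", 42)
  soma <- random_variant_table(200, "somatic", 43)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  sweeps <- list(
    min_depth = c(0L, 5L, 10L, 20L, 60L),
    min_predictors = 0:6,
    max_pop_af_germline = c(1, 0.05, 0.001, 1e-5, 0), # tightening downwards
    min_tumor_vaf = c(0, 0.1, 0.2, 0.4, 0.6)
  )
  for (param in names(sweeps)) {
    prev_g <- NULL
    prev_s <- NULL
    for (val in sweeps[[param]]) {
      cfg <- do.call(filter_config, stats::setNames(list(val), param))
      g <- key(filter_germline(germ, cfg))
      s <- key(filter_somatic(soma, germ, cfg))
      if (!is.null(prev_g)) {
        expect_true(all(g %in% prev_g), label = sprintf("germline subset under %s", param))
        expect_true(all(s %in% prev_s), label = sprintf("somatic subset under %s", param))
      }
      prev_g <- g
      prev_s <- s
    }
  }
})
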