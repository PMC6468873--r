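test_that("shorthand columns are normalized on read", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- make_variant()
  df$AD <- "90,10"
  df$pop_freq <- "1/60,570"
  df$depth <- NULL
  df$alt_depth <- NULL
  df$pop_allele_count <- NULL
  df$pop_allele_number <- NULL
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_variant_table(tmp)
  expect_equal(rec$depth, 100L)
  expect_equal(rec$alt_depth, 10L)
  expect_equal(rec$pop_allele_count, 1L)
  expect_equal(rec$pop_allele_number, 60570L)
})

test_that("population-count parser handles the printed repository layout", {
  m <- parse_pop_counts(c("1/60,570", "0/60,706", "53/60,475"))
  expect_equal(m[, "allele_count"], c(1L, 0L, 53L))
  expect_equal(m[, "allele_number"], c(60570L, 60706L, 60475L))
  ## every frequency printed in the shipped candidate table parses
  tab <- read.delim(system.file("extdata", "crc_candidate_genes.tsv",
                                package = "germsoma"))
  parsed <- parse_pop_counts(tab$pop_freq)
  expect_true(all(parsed[, "allele_count"] <= parsed[, "allele_number"]))
  expect_error(parse_pop_counts("abc"), class = "gs_data_error")
})

test_that("variant validation names the violated invariant and row", {
  df <- make_variant(alt_depth = 150L)
  expect_error(validate_variants(df), "alt_depth", class = "gs_data_error")
  df2 <- make_variant()
  df2$gene <- NULL
  expect_error(validate_variants(df2), "gene", class = "gs_data_error")
  expect_error(validate_variants(make_variant(ref = "T", alt = "T")),
               "ref != alt", class = "gs_data_error")
})

test_that("TSV round trip preserves every field", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- make_variants(
    make_variant(),
    make_variant(pos = 2000L, ref = "CT", alt = "C", consequence = "truncating",
                 cadd_phred = 33.1),
    make_variant(pos = 3000L, origin = "germline", phylop = FALSE,
                 pop_allele_count = 53L, pop_allele_number = 60475L)
  )
  write_variant_table(df, tmp)
  back <- read_variant_table(tmp)
  expect_equal(back, df[names(back)], ignore_attr = TRUE)
})

test_that("multi-allelic VCF sites are split into one record per alt", {
  skip_if_not_installed("VariantAnnotation")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD Phred\">",
    "##INFO=<ID=EXAC_AC,Number=1,Type=Integer,Description=\"Control AC\">",
    "##INFO=<ID=EXAC_AN,Number=1,Type=Integer,Description=\"Control AN\">",
    "##INFO=<ID=SIFT,Number=1,Type=Integer,Description=\"SIFT damaging\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS01",
    paste0("chr1\t1500\t.\tC\tA,T\t.\tPASS\t",
           "GENE=GENE001;CSQ=missense;CADD=24.1;EXAC_AC=1;EXAC_AN=60570;SIFT=1\t",
           "GT:AD\t0/1:90,10,5")
  ), tmp)
  rec <- read_vcf_variants(tmp, origin = "germline")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pos, c(1500L, 1500L))
  expect_setequal(rec$alt, c("A", "T"))
  expect_equal(rec$ref, c("C", "C"))
  expect_true(all(rec$sift))
  expect_equal(rec$pop_allele_number, c(60570L, 60570L))
})

test_that("gene-interval BED round trip converts coordinates once", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(
    gene = c("GENE001", "GENE002"), chrom = c("chr1", "chr2"),
    start = c(10001L, 20001L), end = c(20000L, 30000L),
    stringsAsFactors = FALSE
  )
  write_gene_intervals(iv, tmp)
  raw <- read.table(tmp, sep = "\t")
  expect_equal(raw$V2, c(10000L, 20000L)) # 0-based on disk
  back <- read_gene_intervals(tmp)
  expect_equal(back[order(back$gene), ], iv, ignore_attr = TRUE)
})

test_that("QC decision is inclusive at the 70% boundary", {
  m <- data.frame(qc_shared_ge10x_fraction = c(0.95, 0.70, 0.65))
  expect_equal(qc_pass(m), c(TRUE, TRUE, FALSE))
  expect_error(qc_pass(data.frame(x = 1)), class = "gs_data_error")
})

test_that("manifest reader validates the QC fraction range", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(sample_id = "S01", qc_shared_ge10x_fraction = 1.4),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_manifest(tmp), class = "gs_data_error")
  expect_error(read_manifest("/nonexistent/m.tsv"), class = "gs_config_error")
})
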