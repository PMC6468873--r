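# Fixture builders used across test files.  Everything is generated in
# code; nothing binary ships with the package.

# One variant row with sensible defaults, overridable field by field.
make_variant <- function(...) {
  defaults <- list(
    sample_id = "S01", chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
    origin = "germline", gene = "GENE001", consequence = "missense",
    depth = 100L, alt_depth = 50L,
    phylop = TRUE, sift = TRUE, polyphen2 = TRUE,
    mutationtaster = TRUE, lrt = TRUE, cadd15 = TRUE,
    cadd_phred = 25, pop_allele_count = 0L, pop_allele_number = 60706L
  )
  over <- list(...)
  defaults[names(over)] <- over
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Random annotated cohort for filter-oracle comparisons.
random_variant_table <- function(n, origin, seed) {
  withr::with_seed(seed, {
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_variant(
        sample_id = "S01",
        chrom = sample(c("chr1", "chr2"), 1),
        pos = sample.int(500000L, 1),
        ref = sample(c("A", "C", "G", "T"), 1),
        origin = origin,
        gene = sprintf("GENE%03d", sample.int(30, 1)),
        consequence = sample(c("missense", "truncating", "synonymous", "other"), 1,
                             prob = c(0.5, 0.2, 0.2, 0.1)),
        depth = sample(c(5L, 9L, 10L, 11L, 60L, 120L), 1),
        alt_depth = 0L,
        phylop = runif(1) < 0.5, sift = runif(1) < 0.5,
        polyphen2 = runif(1) < 0.5, mutationtaster = runif(1) < 0.5,
        lrt = runif(1) < 0.5, cadd15 = runif(1) < 0.5,
        cadd_phred = round(runif(1, 0, 40), 1),
        pop_allele_count = sample(c(0L, 1L, 5L, 100L, 3000L), 1),
        pop_allele_number = sample(c(0L, 56138L, 60706L), 1)
      )
    }))
    df$alt <- ifelse(df$ref == "T", "G", "T")
    df$alt_depth <- rbinom(n, df$depth, runif(n, 0.05, 0.6))
    df$pop_allele_count <- pmin(df$pop_allele_count, df$pop_allele_number)
    if (origin == "somatic") df$normal_depth <- sample(c(4L, 9L, 10L, 80L), n, replace = TRUE)
    df
  })
}

# Site-depth table for one "gene" on its own chromosome.
make_gene_sites <- function(chrom, n_sites, depth, vaf, seed = NULL, start = 10001L) {
  draw <- function() {
    gd <- rpois(n_sites, depth)
    td <- rpois(n_sites, depth)
    v <- if (length(vaf) == 1) rep(vaf, n_sites) else sample(vaf, n_sites, replace = TRUE)
    ga <- rbinom(n_sites, gd, 0.5)
    ta <- rbinom(n_sites, td, v)
    data.frame(
      chrom = chrom, pos = start + seq_len(n_sites) * 1000L,
      germ_ref = gd - ga, germ_alt = ga,
      tum_ref = td - ta, tum_alt = ta,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
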