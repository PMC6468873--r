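## Core domain model: annotated variant records, paired-site allele depths,
## sample manifests and gene intervals, plus readers/writers for the
## tab-separated interchange formats and VCF/BED via Bioconductor.
##
## Coordinate conventions, centralized here:
##   * variants and het sites: 1-based positions (VCF convention);
##   * gene intervals: 0-based half-open on disk (BED), converted to
##     1-based inclusive in memory immediately on read.

#' Names of the six pathogenicity predictor columns
#'
#' Missense variants are scored by six in-silico tools, each reduced
#' upstream (at annotation time) to a pass/fail call: PhyloP
#' (phyloP46way_placental score >= 1.6), SIFT (damaging), PolyPhen2
#' (probably/possibly damaging), MutationTaster (disease causing), LRT
#' (deleterious) and CADD (Phred score >= 15).  Variant tables carry one
#' logical column per tool under these names.
#'
#' @return Character vector of the six predictor column names.
#' @export
predictor_tools <- function() {
  c("phylop", "sift", "polyphen2", "mutationtaster", "lrt", "cadd15")
}

#' @keywords internal
consequence_levels <- function() c("missense", "truncating", "synonymous", "other")

variant_required_cols <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "origin", "gene",
    "consequence", "depth", "alt_depth", predictor_tools(),
    "cadd_phred", "pop_allele_count", "pop_allele_number")
}

#' Parse an allelic-depth string
#'
#' Parses the VCF `AD`-style field `"ref,alt"` (e.g. `"90,10"`) into
#' reference and alternate read counts.
#'
#' @param x Character vector of `"ref,alt"` strings.
#' @return Integer matrix with columns `ref` and `alt`.
#' @examples
#' parse_allele_depth("90,10")
#' @export
parse_allele_depth <- function(x) {
  parts <- strsplit(as.character(x), ",", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    gs_data_error(sprintf(
      "malformed allele-depth field at entry %d: %s",
      which(bad)[1], x[which(bad)[1]]
    ))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
    ncol = 2, byrow = TRUE, dimnames = list(NULL, c("ref", "alt"))
  )
  if (anyNA(m)) {
    gs_data_error(sprintf(
      "non-numeric allele-depth field at entry %d: %s",
      which(is.na(rowSums(m)))[1], x[which(is.na(rowSums(m)))[1]]
    ))
  }
  m
}

#' Parse population allele counts printed as "count/number"
#'
#' Control-repository (ExAC-style) frequencies are often printed as
#' `"1/60,570"`, meaning allele count 1 over allele number 60570.  Commas
#' used as thousands separators are removed.
#'
#' @param x Character vector of `"count/number"` strings.
#' @return Integer matrix with columns `allele_count` and `allele_number`.
#' @examples
#' parse_pop_counts("1/60,570")
#' @export
parse_pop_counts <- function(x) {
  clean <- gsub(",", "", as.character(x), fixed = TRUE)
  parts <- strsplit(clean, "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    gs_data_error(sprintf(
      "malformed population-count field at entry %d: %s",
      which(bad)[1], x[which(bad)[1]]
    ))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
    ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("allele_count", "allele_number"))
  )
  if (anyNA(m)) gs_data_error("non-numeric population-count field")
  m
}

#' Validate a variant table against the record invariants
#'
#' Checks the structural invariants of annotated variant records: depths
#' non-negative with `alt_depth <= depth`, positions `>= 1`,
#' `pop_allele_count <= pop_allele_number`, `ref != alt`, and a known
#' consequence label.
#'
#' @param df Variant `data.frame`.
#' @return `df` invisibly; signals a data error describing the first
#'   violated invariant otherwise.
#' @export
validate_variants <- function(df) {
  miss <- setdiff(variant_required_cols(), names(df))
  if (length(miss) > 0) {
    gs_data_error(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  check <- function(ok, what) {
    if (!all(ok)) {
      gs_data_error(sprintf("invariant violated (%s) at row %d", what, which(!ok)[1]))
    }
  }
  check(df$pos >= 1, "pos >= 1")
  check(df$depth >= 0 & df$alt_depth >= 0 & df$alt_depth <= df$depth,
        "0 <= alt_depth <= depth")
  check(df$pop_allele_count <= df$pop_allele_number | df$pop_allele_number == 0,
        "pop_allele_count <= pop_allele_number")
  check(df$ref != df$alt, "ref != alt")
  check(df$consequence %in% consequence_levels(), "known consequence")
  check(df$origin %in% c("germline", "somatic"), "origin in {germline, somatic}")
  invisible(df)
}

#' Read an annotated variant table (TSV)
#'
#' Reads one annotated call per row.  The canonical layout has the columns
#' named by [variant_required_cols]; two common shorthand encodings are
#' also accepted and normalized on read:
#' * an `AD` column (`"ref,alt"`) in place of `depth`/`alt_depth`;
#' * a `pop_freq` column (`"count/number"`, e.g. `"1/60,570"`) in place of
#'   `pop_allele_count`/`pop_allele_number`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param origin Optional origin (`"germline"` or `"somatic"`) to assign
#'   when the file lacks an `origin` column.
#' @return A validated `data.frame` of variant records.
#' @export
read_variant_table <- function(path, origin = NULL) {
  if (!file.exists(path)) gs_config_error(sprintf("variant table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(chrom = "character"))
  if (!is.null(origin) && is.null(df$origin)) df$origin <- origin
  if (!is.null(df$AD) && is.null(df$depth)) {
    ad <- parse_allele_depth(df$AD)
    df$alt_depth <- ad[, "alt"]
    df$depth <- ad[, "ref"] + ad[, "alt"]
    df$AD <- NULL
  }
  if (!is.null(df$pop_freq) && is.null(df$pop_allele_count)) {
    pc <- parse_pop_counts(df$pop_freq)
    df$pop_allele_count <- pc[, "allele_count"]
    df$pop_allele_number <- pc[, "allele_number"]
    df$pop_freq <- NULL
  }
  for (tool in predictor_tools()) {
    if (!is.null(df[[tool]])) df[[tool]] <- as.logical(df[[tool]])
  }
  validate_variants(df)
  extras <- intersect(c("normal_depth", "context"), names(df))
  df[c(variant_required_cols(), extras)]
}

#' Write an annotated variant table (TSV)
#'
#' Writes the canonical tab-separated layout read back by
#' [read_variant_table]; a read/write round trip preserves every field.
#'
#' @param df Variant `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  validate_variants(df)
  extras <- intersect(c("normal_depth", "context"), names(df))
  utils::write.table(df[c(variant_required_cols(), extras)], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read annotated variants from a VCF file
#'
#' Reads a VCF v4.2 file (via the VariantAnnotation package) whose INFO
#' field carries the annotation keys `GENE`, `CSQ` (consequence label),
#' `CADD`, `EXAC_AC`, `EXAC_AN` and one 0/1 key per predictor tool
#' (uppercased column name, e.g. `SIFT`).  Multi-allelic sites are split
#' into one record per alternate allele, with allelic depths taken from
#' the first sample's `AD` genotype field.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param origin Variant origin, `"germline"` or `"somatic"`.
#' @param sample_id Sample identifier to assign; defaults to the first
#'   sample name in the VCF header.
#' @return A validated variant `data.frame`, as from [read_variant_table].
#' @export
read_vcf_variants <- function(path, origin, sample_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    gs_config_error("VCF input requires the VariantAnnotation package")
  }
  if (!file.exists(path)) gs_config_error(sprintf("VCF not found: %s", path))
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf) # one row per alternate allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(sample_id)) sample_id <- colnames(vcf)[1]
  n <- length(rr)
  get_info <- function(key, default) {
    v <- info[[key]]
    if (is.null(v)) rep(default, n) else as.vector(v)
  }
  ## expand() turns the Number=R AD field into variants x samples x 2
  ## (ref, alt); unexpanded or Number=. files still yield a list matrix
  if (is.array(ad) && length(dim(ad)) == 3) {
    ref_counts <- as.integer(ad[, 1, 1])
    alt_counts <- as.integer(ad[, 1, 2])
  } else {
    ref_counts <- vapply(seq_len(n), function(i) as.integer(ad[[i, 1]][1]), 1L)
    alt_counts <- vapply(seq_len(n), function(i) {
      a <- ad[[i, 1]]
      if (length(a) >= 2) as.integer(a[2]) else 0L
    }, 1L)
  }
  df <- data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    origin = origin,
    gene = as.character(get_info("GENE", NA_character_)),
    consequence = as.character(get_info("CSQ", "other")),
    depth = ref_counts + alt_counts,
    alt_depth = alt_counts,
    stringsAsFactors = FALSE
  )
  for (tool in predictor_tools()) {
    df[[tool]] <- as.logical(get_info(toupper(tool), 0L))
  }
  df$cadd_phred <- as.numeric(get_info("CADD", NA_real_))
  df$pop_allele_count <- as.integer(get_info("EXAC_AC", 0L))
  df$pop_allele_number <- as.integer(get_info("EXAC_AN", 0L))
  validate_variants(df)
  df
}

#' Read paired germline/tumor allele depths at candidate het sites
#'
#' @param path TSV with columns `chrom`, `pos`, `germ_ref`, `germ_alt`,
#'   `tum_ref`, `tum_alt` (read counts).
#' @return A `data.frame` of site allele depths.
#' @export
read_site_depths <- function(path) {
  if (!file.exists(path)) gs_config_error(sprintf("site-depth table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "germ_ref", "germ_alt", "tum_ref", "tum_alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    gs_data_error(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  counts <- df[c("germ_ref", "germ_alt", "tum_ref", "tum_alt")]
  if (any(counts < 0)) gs_data_error("negative read count in site-depth table")
  df[need]
}

#' Write a site allele-depth table
#' @param df Site-depth `data.frame` as read by [read_site_depths].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_depths <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED uses 0-based half-open coordinates on disk; intervals are converted
#' to 1-based inclusive immediately on read, so every in-memory comparison
#' in the package uses one convention.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, gene).
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) gs_config_error(sprintf("interval file not found: %s", path))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(
      gene = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), # import() already shifts to 1-based
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c("character", "integer", "integer", "character"))
    df <- data.frame(
      gene = raw[[4]], chrom = raw[[1]],
      start = raw[[2]] + 1L, end = raw[[3]], stringsAsFactors = FALSE
    )
  }
  if (any(df$start > df$end)) gs_data_error("empty or inverted interval in BED input")
  df
}

#' Write gene intervals to a BED file
#' @param intervals `data.frame` from [read_gene_intervals] (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_intervals <- function(intervals, path) {
  bed <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start - 1L, # back to BED convention
    end = intervals$end,
    name = intervals$gene
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest lists one paired sample per row with the file paths of its
#' germline/tumor variant tables and het-site depths, and the tumor QC
#' metric: the fraction of shared exome regions covered at >= 10x in both
#' members of the pair.
#'
#' @param path TSV (columns `sample_id`, `germline_path`, `tumor_path`,
#'   `sites_path`, `qc_shared_ge10x_fraction`) or YAML file with a
#'   `samples:` list of the same fields.
#' @return `data.frame` manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) gs_config_error(sprintf("manifest not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(y$samples, function(s) as.data.frame(s, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "qc_shared_ge10x_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    gs_data_error(sprintf("manifest missing column(s): %s", paste(miss, collapse = ", ")))
  }
  q <- df$qc_shared_ge10x_fraction
  if (any(is.na(q)) || any(q < 0) || any(q > 1)) {
    gs_data_error("qc_shared_ge10x_fraction must lie in [0, 1]")
  }
  df
}

#' Sample quality-control decision
#'
#' A paired sample passes QC when the fraction of shared exome regions
#' sequenced at >= 10x coverage is at least `threshold`.  The boundary is
#' inclusive: exactly 70% passes.
#'
#' @param manifest Manifest `data.frame` (or anything with a
#'   `qc_shared_ge10x_fraction` column).
#' @param threshold Minimum acceptable fraction (default 0.70).
#' @return Logical vector, one decision per sample.
#' @examples
#' qc_pass(data.frame(qc_shared_ge10x_fraction = c(0.95, 0.70, 0.65)))
#' @export
qc_pass <- function(manifest, threshold = 0.70) {
  q <- manifest$qc_shared_ge10x_fraction
  if (is.null(q)) gs_data_error("manifest lacks qc_shared_ge10x_fraction")
  q >= threshold
}
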