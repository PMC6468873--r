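## Somatic mutational profiling: 96-channel catalogs, tumor mutational
## burden, and signature refitting.
##
## Channels follow the standard single-base-substitution convention: the
## mutated base is reported on the pyrimidine strand (6 substitution
## classes C>A, C>G, C>T, T>A, T>C, T>G), each in its 16 flanking
## trinucleotide contexts, ordered substitution-major and then
## alphabetically by context (A[C>A]A, A[C>A]C, ..., T[T>G]T).

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 substitution channels in canonical order
#'
#' @return Character vector of 96 channel labels, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s) {
    unlist(lapply(BASES, function(five) {
      paste0(five, "[", s, "]", vapply(BASES, identity, ""))
    }))
  }), use.names = FALSE)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, ""),
    function(ch) paste(rev(ch), collapse = ""), ""
  ))
}

#' Map SNVs to substitution channels
#'
#' Each single-nucleotide variant with its trinucleotide context (the
#' reference base and one flanking base on each side) maps to one of the
#' 96 channels; purine-reference mutations (`G>.`, `A>.`) are
#' reverse-complemented onto the pyrimidine strand first.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide context strings (middle base = `ref`).
#' @return Character vector of channel labels; `NA` for non-SNVs,
#'   ambiguous bases (`N`) or contexts inconsistent with `ref`.
#' @export
snv_channel <- function(ref, alt, context) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  context <- toupper(context)
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- nchar(ref) == 1 & nchar(alt) == 1 & nchar(context) == 3 &
    ref != alt &
    ref %in% BASES & alt %in% BASES &
    substr(context, 2, 2) == ref &
    !grepl("[^ACGT]", context)
  if (!any(ok)) return(out)
  r <- ref[ok]
  a <- alt[ok]
  ctx <- context[ok]
  flip <- r %in% c("A", "G")
  r[flip] <- chartr("ACGT", "TGCA", r[flip])
  a[flip] <- chartr("ACGT", "TGCA", a[flip])
  ctx[flip] <- revcomp(ctx[flip])
  out[ok] <- paste0(
    substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3)
  )
  out
}

#' Build a 96-channel mutational catalog
#'
#' Counts somatic single-nucleotide variants per substitution channel.
#' Indels and multi-base alleles are excluded up front; SNVs whose
#' context contains an ambiguous base (`N`) or contradicts the reference
#' base are dropped with a warning and tallied.
#'
#' @param somatic_snvs `data.frame` with columns `ref`, `alt` and
#'   `context` (trinucleotide).
#' @param sample_id Sample label for the catalog.
#' @return List of class `mutational_catalog`: `sample_id`, `counts`
#'   (named integer vector over [sbs96_channels]), `n_snv`
#'   (total counted) and `n_dropped`.
#' @export
build_catalog <- function(somatic_snvs, sample_id = NA_character_) {
  is_snv <- nchar(somatic_snvs$ref) == 1 & nchar(somatic_snvs$alt) == 1
  snvs <- somatic_snvs[is_snv, , drop = FALSE]
  ch <- snv_channel(snvs$ref, snvs$alt, snvs$context)
  n_dropped <- sum(is.na(ch))
  if (n_dropped > 0) {
    warning(sprintf("%d SNV(s) dropped (ambiguous or inconsistent context)",
                    n_dropped), call. = FALSE)
  }
  counts <- table(factor(ch[!is.na(ch)], levels = sbs96_channels()))
  counts <- stats::setNames(as.integer(counts), sbs96_channels())
  structure(
    list(sample_id = sample_id, counts = counts,
         n_snv = sum(counts), n_dropped = n_dropped),
    class = "mutational_catalog"
  )
}

#' Tumor mutational burden
#'
#' Mutations per megabase under the convention that a whole-exome sample
#' covers `exome_mb` (default 30) megabases with acceptable quality.
#' Burden classes: `hypermutated` at >= 90 mutations/Mb (inclusive
#' boundary) and `ultrahypermutated` at > 500.
#'
#' @param catalog A `mutational_catalog`, or a plain SNV count.
#' @param exome_mb Assumed callable exome size in Mb (default 30).
#' @return List: `sample_id`, `n_snv`, `mutations_per_mb`, `class`.
#' @examples
#' compute_burden(2907) # 96.9 mutations/Mb, hypermutated
#' @export
compute_burden <- function(catalog, exome_mb = 30) {
  if (inherits(catalog, "mutational_catalog")) {
    n <- catalog$n_snv
    id <- catalog$sample_id
  } else {
    n <- as.numeric(catalog)
    id <- NA_character_
  }
  per_mb <- n / exome_mb
  cls <- if (per_mb > 500) {
    "ultrahypermutated"
  } else if (per_mb >= 90) {
    "hypermutated"
  } else {
    "normal"
  }
  list(sample_id = id, n_snv = n, mutations_per_mb = per_mb, class = cls)
}

#' Read a reference signature matrix
#'
#' Tab-separated, 96 rows x K signature columns of channel probabilities,
#' with the channel label in the first column (any of the common header
#' names).  Rows are reordered to the canonical channel order and each
#' column is checked to sum to 1 within `1e-6`.
#'
#' @param path TSV path.
#' @return Numeric 96 x K matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) gs_config_error(sprintf("signature matrix not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lab_col <- names(df)[1]
  labels <- df[[lab_col]]
  S <- as.matrix(df[, -1, drop = FALSE])
  idx <- match(sbs96_channels(), labels)
  if (anyNA(idx)) gs_data_error("signature matrix does not cover all 96 channels")
  S <- S[idx, , drop = FALSE]
  rownames(S) <- sbs96_channels()
  if (any(S < 0)) gs_data_error("negative entry in signature matrix")
  sums <- colSums(S)
  if (any(abs(sums - 1) > 1e-6)) {
    gs_data_error("signature column(s) do not sum to 1 (tolerance 1e-6)")
  }
  S
}

#' Write a signature matrix
#' @param S 96 x K matrix with channel rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(S, path) {
  df <- data.frame(channel = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Refit a catalog against reference signatures
#'
#' Reconstructs the sample's 96-channel catalog as a non-negative
#' combination of the reference signatures by non-negative least squares
#' on raw counts: `exposures = argmin_{e >= 0} ||S e - counts||_2`.
#' Contributions are the exposures normalized to proportions, and the
#' reconstruction quality is the cosine similarity between fitted and
#' observed catalogs.  No sparsity penalty or signature pre-selection is
#' applied.
#'
#' @param catalog A `mutational_catalog` (or bare 96-vector of counts).
#' @param S Signature matrix from [read_signature_matrix].
#' @return List: `sample_id`, `exposures` (named, >= 0), `contributions`
#'   (sum to 1), `reconstruction_cosine`.
#' @export
refit_signatures <- function(catalog, S) {
  if (inherits(catalog, "mutational_catalog")) {
    counts <- catalog$counts
    id <- catalog$sample_id
  } else {
    counts <- as.numeric(catalog)
    id <- NA_character_
  }
  if (length(counts) != nrow(S)) {
    gs_config_error("catalog length does not match signature matrix rows")
  }
  if (sum(counts) <= 0) gs_data_error("empty catalog: no SNVs to refit")
  fit <- nnls(S, counts)
  e <- stats::setNames(fit$x, colnames(S))
  contrib <- if (sum(e) > 0) e / sum(e) else e
  cosine <- sum(fit$fitted * counts) /
    (sqrt(sum(fit$fitted^2)) * sqrt(sum(counts^2)))
  list(
    sample_id = id,
    exposures = e,
    contributions = contrib,
    reconstruction_cosine = cosine
  )
}

#' Write one or more catalogs as a 96 x samples TSV
#' @param catalogs List of `mutational_catalog` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_table <- function(catalogs, path) {
  m <- vapply(catalogs, function(cat) cat$counts, numeric(96))
  colnames(m) <- vapply(catalogs, function(cat) cat$sample_id, "")
  df <- data.frame(channel = sbs96_channels(), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
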