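## Loss-of-heterozygosity detection from allelic imbalance.
##
## At a germline-heterozygous site the tumor variant allele fraction (VAF)
## stays near 0.5 unless one allele has been somatically lost.  The caller
## works on the folded deviation d_i = |VAF_i - 0.5|:
##   1. each chromosome's ordered het sites are partitioned by recursive
##      binary segmentation on d_i, a split being accepted when a seeded
##      permutation test of the maximal two-sample t statistic over all
##      admissible breakpoints gives p < alpha;
##   2. each segment is tested for allelic imbalance: an exact two-sided
##      binomial test of tum_alt ~ Binomial(tum_depth, 0.5) per site,
##      combined across sites by Fisher's method, with an effect-size
##      floor on the mean folded deviation so significance alone (huge
##      depth, tiny shift) never calls LOH;
##   3. gene-level calls are made by interval overlap with the segments,
##      and for genes whose germline first hit lies inside an imbalanced
##      segment the lost allele is identified from the first hit's tumor
##      VAF (> 0.5 means the wild-type allele was lost).

#' Restrict paired site depths to informative germline-heterozygous sites
#'
#' A site enters LOH testing only when the germline genotype is credibly
#' heterozygous: germline VAF within `het_band` and germline depth at
#' least `min_depth`.
#'
#' @param sites Site-depth `data.frame` (see [read_site_depths]).
#' @param het_band Admissible germline VAF interval (default `c(0.3, 0.7)`).
#' @param min_depth Minimum germline depth (default 10).
#' @return The informative subset of `sites`.
#' @export
informative_sites <- function(sites, het_band = c(0.3, 0.7), min_depth = 10) {
  gd <- sites$germ_ref + sites$germ_alt
  gvaf <- ifelse(gd > 0, sites$germ_alt / gd, NA_real_)
  keep <- !is.na(gvaf) & gd >= min_depth & gvaf >= het_band[1] & gvaf <= het_band[2]
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Maximal segment-vs-rest t statistic (the circular binary segmentation
## statistic).  Candidate segments are index windows d[(i+1)..j] with
## width >= min_seg, complement >= min_seg, and any non-empty flank
## >= min_seg (so recursion never creates a sub-minimal part).  For each
## candidate the pooled-variance two-sample t between segment and rest is
## computed from cumulative sums, fully vectorized over the candidate
## list.  Returns list(i, j, t); i = NA when no admissible window exists
## or no contrast is non-degenerate.
##
## A plain single-breakpoint recursion was tried first and proved badly
## underpowered for interior LOH segments (a focal segment inflates the
## permutation null on both sides of any single cut), which is exactly
## why the established method tests windows.
segment_candidates <- function(n, min_seg) {
  i <- rep(0:(n - 1), times = n:1)
  j <- sequence(n:1) + i
  keep <- (j - i) >= min_seg & (n - (j - i)) >= min_seg &
    (i == 0 | i >= min_seg) & (j == n | (n - j) >= min_seg)
  list(i = i[keep], j = j[keep])
}

max_t_segment <- function(d, min_seg, cand = NULL) {
  n <- length(d)
  if (n < 2 * min_seg) return(list(i = NA_integer_, j = NA_integer_, t = NA_real_))
  if (is.null(cand)) cand <- segment_candidates(n, min_seg)
  if (length(cand$i) == 0) {
    return(list(i = NA_integer_, j = NA_integer_, t = NA_real_))
  }
  cs <- c(0, cumsum(d))
  cs2 <- c(0, cumsum(d^2))
  w <- cand$j - cand$i
  nr <- n - w
  s1 <- cs[cand$j + 1] - cs[cand$i + 1]
  q1 <- cs2[cand$j + 1] - cs2[cand$i + 1]
  m1 <- s1 / w
  m0 <- (cs[n + 1] - s1) / nr
  ss <- (q1 - w * m1^2) + ((cs2[n + 1] - q1) - nr * m0^2)
  s2 <- pmax(ss, 0) / (n - 2)
  tt <- ifelse(s2 > 0, abs(m1 - m0) / sqrt(s2 * (1 / w + 1 / nr)), 0)
  t_best <- max(tt)
  if (!is.finite(t_best) || t_best <= 0) {
    return(list(i = NA_integer_, j = NA_integer_, t = NA_real_))
  }
  ## a window and its complement give the same t; canonicalize ties to the
  ## narrowest window, then the leftmost
  tied <- which(tt >= t_best * (1 - 1e-12))
  tied <- tied[order(w[tied], cand$i[tied])]
  best <- tied[1]
  list(i = cand$i[best], j = cand$j[best], t = tt[best])
}

## Permutation p-value for the observed max-t: shuffle d, recompute the
## maximal segment t, count exceedances (add-one estimator keeps p > 0).
## Stops early once significance at `alpha` is impossible, which keeps
## clearly-null decisions cheap without changing any accept/reject
## outcome.
perm_segment_p <- function(d, t_obs, min_seg, n_perm, alpha = 1) {
  cand <- segment_candidates(length(d), min_seg)
  limit <- ceiling(alpha * (n_perm + 1)) # exceedances that force p >= alpha
  exceed <- 0L
  done <- 0L
  for (k in seq_len(n_perm)) {
    tp <- max_t_segment(sample(d), min_seg, cand)$t
    done <- k
    if (!is.na(tp) && tp >= t_obs) {
      exceed <- exceed + 1L
      if (exceed >= limit) break
    }
  }
  if (exceed >= limit) return(alpha) # certainly not significant
  (exceed + 1) / (done + 1)
}

#' Test one segment for allelic imbalance
#'
#' Per site, an exact two-sided binomial test of the tumor alternate read
#' count against Binomial(tumor depth, 0.5); site p-values are combined by
#' Fisher's method (-2 sum log p ~ chi-squared with 2m df).  The segment
#' is called imbalanced when the combined p falls below `alpha_loh` AND
#' the mean folded VAF deviation reaches `shift_min`.
#'
#' @param seg_sites Site-depth rows of one segment.
#' @param alpha_loh Segment-level significance threshold (default 0.01).
#' @param shift_min Minimum mean `|VAF - 0.5|` (default 0.15); guards
#'   against statistically significant but biologically negligible shifts.
#' @return List with `mean_shift`, `p_value`, `is_loh`, `affected_allele`
#'   (`"ref_lost"` when alt reads dominate, `"alt_lost"` when reference
#'   reads dominate, `"unknown"` when untestable), and `n_tested`.
#' @export
test_segment_imbalance <- function(seg_sites, alpha_loh = 0.01, shift_min = 0.15) {
  td <- seg_sites$tum_ref + seg_sites$tum_alt
  ok <- td > 0
  if (!any(ok)) {
    return(list(mean_shift = NA_real_, p_value = 1, is_loh = FALSE,
                affected_allele = "unknown", n_tested = 0L))
  }
  alt <- seg_sites$tum_alt[ok]
  dep <- td[ok]
  vaf <- alt / dep
  p_site <- vapply(seq_along(alt), function(i) {
    stats::binom.test(alt[i], dep[i], p = 0.5)$p.value
  }, 1)
  p_site <- pmin(pmax(p_site, .Machine$double.xmin), 1)
  x2 <- -2 * sum(log(p_site))
  p_comb <- stats::pchisq(x2, df = 2 * length(p_site), lower.tail = FALSE)
  mean_shift <- mean(abs(vaf - 0.5))
  list(
    mean_shift = mean_shift,
    p_value = p_comb,
    is_loh = p_comb < alpha_loh && mean_shift >= shift_min,
    affected_allele = if (p_comb < alpha_loh) {
      if (mean(vaf) > 0.5) "ref_lost" else "alt_lost"
    } else {
      "unknown"
    },
    n_tested = length(alt)
  )
}

#' Segment het sites by tumor allelic imbalance
#'
#' Recursive segmentation of the folded tumor VAF deviation along each
#' chromosome, using the circular-binary-segmentation statistic: at every
#' level the index window maximizing the segment-vs-rest two-sample t is
#' located by exhaustive scan over admissible windows, and the split is
#' accepted when a seeded permutation test on that maximal t gives
#' `p < alpha`.  Accepted windows recurse into (up to) three parts; the
#' returned segments partition the informative sites of each chromosome.
#' Each segment is then scored by [test_segment_imbalance].
#'
#' @param sites Informative (germline-het) site depths, see
#'   [informative_sites]; rows are ordered by `chrom`, `pos` internally.
#' @param alpha Split acceptance threshold for the permutation test
#'   (default 0.01).
#' @param min_sites Minimum sites per segment and minimum testable
#'   chromosome size (default 5); smaller chromosomes yield one unsplit
#'   segment flagged untestable.
#' @param n_perm Permutations per split decision (default 1000).
#' @param alpha_loh,shift_min Segment-level calling thresholds, passed to
#'   [test_segment_imbalance].
#' @param seed Integer seed making the permutation draws reproducible.
#' @return `data.frame` of segments: `chrom`, `start`, `end` (1-based
#'   inclusive span of member sites), `n_sites`, `mean_shift`, `p_value`,
#'   `is_loh`, `affected_allele`, `untestable`.
#' @export
segment_vaf <- function(sites, alpha = 0.01, min_sites = 5, n_perm = 1000,
                        alpha_loh = 0.01, shift_min = 0.15, seed = 1L) {
  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    n_sites = integer(0), mean_shift = numeric(0), p_value = numeric(0),
    is_loh = logical(0), affected_allele = character(0),
    untestable = logical(0), stringsAsFactors = FALSE
  )
  if (nrow(sites) == 0) return(empty)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  out <- list()
  for (chrom in unique(sites$chrom)) {
    cs <- sites[sites$chrom == chrom, , drop = FALSE]
    td <- cs$tum_ref + cs$tum_alt
    d <- ifelse(td > 0, abs(cs$tum_alt / td - 0.5), 0)
    bounds <- with_seed(derive_seed(seed, chrom), {
      segment_recurse(d, 1L, nrow(cs), alpha, min_sites, n_perm)
    })
    untestable <- nrow(cs) < min_sites
    for (b in bounds) {
      seg_sites <- cs[b[1]:b[2], , drop = FALSE]
      tst <- test_segment_imbalance(seg_sites, alpha_loh, shift_min)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        start = seg_sites$pos[1],
        end = seg_sites$pos[nrow(seg_sites)],
        n_sites = nrow(seg_sites),
        mean_shift = tst$mean_shift,
        p_value = tst$p_value,
        is_loh = if (untestable) FALSE else tst$is_loh,
        affected_allele = tst$affected_allele,
        untestable = untestable,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Recursive splitter over index range [lo, hi]; returns list of c(lo, hi)
## segment bounds in left-to-right order.  An accepted window splits the
## range into up to three parts (left flank, window, right flank), each
## recursed independently.
segment_recurse <- function(d, lo, hi, alpha, min_sites, n_perm) {
  dd <- d[lo:hi]
  sp <- max_t_segment(dd, min_sites)
  if (is.na(sp$i)) return(list(c(lo, hi)))
  p <- perm_segment_p(dd, sp$t, min_sites, n_perm, alpha)
  if (p >= alpha) return(list(c(lo, hi)))
  bounds <- list()
  a <- lo + sp$i # first index of the window (1-based within d)
  b <- lo + sp$j - 1L # last index of the window
  if (sp$i > 0) {
    bounds <- c(bounds, segment_recurse(d, lo, a - 1L, alpha, min_sites, n_perm))
  }
  bounds <- c(bounds, segment_recurse(d, a, b, alpha, min_sites, n_perm))
  if (b < hi) {
    bounds <- c(bounds, segment_recurse(d, b + 1L, hi, alpha, min_sites, n_perm))
  }
  bounds
}

#' Call LOH per gene from imbalance segments
#'
#' A gene is called LOH when any imbalanced (`is_loh`) segment overlaps
#' its interval.  When a germline first-hit variant of the gene lies
#' inside the supporting segment, the call also records whether the
#' second-hit deletion removed the wild-type allele: the first hit's
#' tumor VAF above 0.5 means the variant-bearing allele was retained.
#'
#' @param segments Segment table from [segment_vaf].
#' @param gene_intervals Interval table from [read_gene_intervals]
#'   (1-based inclusive).
#' @param first_hits Optional `data.frame` of germline first hits with
#'   columns `gene`, `chrom`, `pos` and `tumor_vaf` (tumor VAF of the
#'   germline variant; `NA` when unknown).
#' @param sample_id Sample label copied into the calls.
#' @return `data.frame` of gene calls: `gene`, `sample_id`, `is_loh`,
#'   supporting-segment coordinates and statistics, and
#'   `retains_germline_variant` (logical, `NA` when no located first hit).
#' @export
call_gene_loh <- function(segments, gene_intervals, first_hits = NULL,
                          sample_id = NA_character_) {
  if (nrow(gene_intervals) == 0) {
    gs_data_error("no gene intervals supplied")
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start, segments$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    gene_intervals$chrom, IRanges::IRanges(gene_intervals$start, gene_intervals$end)
  )
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  out <- data.frame(
    gene = gene_intervals$gene,
    sample_id = sample_id,
    is_loh = FALSE,
    seg_chrom = NA_character_, seg_start = NA_integer_, seg_end = NA_integer_,
    mean_shift = NA_real_, p_value = NA_real_,
    affected_allele = NA_character_,
    retains_germline_variant = NA,
    stringsAsFactors = FALSE
  )
  for (g in seq_len(nrow(gene_intervals))) {
    segs <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == g]
    if (length(segs) == 0) next
    loh_segs <- segs[segments$is_loh[segs]]
    sup <- if (length(loh_segs) > 0) {
      loh_segs[which.min(segments$p_value[loh_segs])]
    } else {
      segs[which.min(segments$p_value[segs])]
    }
    out$is_loh[g] <- length(loh_segs) > 0
    out$seg_chrom[g] <- segments$chrom[sup]
    out$seg_start[g] <- segments$start[sup]
    out$seg_end[g] <- segments$end[sup]
    out$mean_shift[g] <- segments$mean_shift[sup]
    out$p_value[g] <- segments$p_value[sup]
    out$affected_allele[g] <- segments$affected_allele[sup]
  }
  if (!is.null(first_hits) && nrow(first_hits) > 0) {
    for (i in seq_len(nrow(first_hits))) {
      g <- match(first_hits$gene[i], out$gene)
      if (is.na(g) || !out$is_loh[g]) next
      inside <- !is.na(out$seg_chrom[g]) &&
        first_hits$chrom[i] == out$seg_chrom[g] &&
        first_hits$pos[i] >= out$seg_start[g] &&
        first_hits$pos[i] <= out$seg_end[g]
      if (inside && !is.na(first_hits$tumor_vaf[i])) {
        out$retains_germline_variant[g] <- first_hits$tumor_vaf[i] > 0.5
      }
    }
  }
  missing_genes <- setdiff(
    if (is.null(first_hits)) character(0) else first_hits$gene,
    gene_intervals$gene
  )
  if (length(missing_genes) > 0) {
    warning(sprintf(
      "gene(s) absent from interval file, no LOH call made: %s",
      paste(unique(missing_genes), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Write imbalance segments as BED and TSV
#'
#' @param segments Segment table from [segment_vaf].
#' @param prefix Output path prefix; writes `<prefix>.bed` (0-based
#'   half-open, score = mean shift) and `<prefix>.tsv` (full table).
#' @return Character vector of the two paths, invisibly.
#' @export
write_segments <- function(segments, prefix) {
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  utils::write.table(segments, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(
    chrom = segments$chrom,
    start = segments$start - 1L,
    end = segments$end,
    name = ifelse(segments$is_loh, "LOH", "balanced"),
    score = round(segments$mean_shift * 1000)
  )
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}
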