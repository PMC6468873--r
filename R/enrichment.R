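## Rare-variant case-control enrichment: per variant, a 2x2 Fisher exact
## test of alternate-allele counts in a case cohort against a control
## repository; per gene, the fraction of tested variants reaching
## significance.

#' Select variants eligible for enrichment testing
#'
#' Only rare (control allele frequency strictly below `max_af`) and
#' potentially pathogenic (CADD Phred strictly above `min_cadd`) variants
#' are tested; both inequalities are strict, so CADD exactly 15 is
#' excluded.
#'
#' @param variants `data.frame` with columns `control_af` and
#'   `cadd_phred` (plus identifying columns passed through).
#' @param max_af Control allele-frequency cutoff (default 0.001).
#' @param min_cadd CADD Phred cutoff (default 15).
#' @return The eligible subset.
#' @export
select_enrichment_variants <- function(variants, max_af = 0.001, min_cadd = 15) {
  keep <- variants$control_af < max_af & variants$cadd_phred > min_cadd
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test under the "probability ordering" definition: the
#' p-value sums the hypergeometric probabilities of every table with the
#' observed margins whose probability does not exceed that of the
#' observed table (ties included within a relative tolerance of 1e-7).
#' The odds ratio is the plain cross-product `(a d)/(b c)` (`Inf` when
#' `b c = 0` with `a d > 0`); for the all-zero table, `p = 1` and the
#' odds ratio is undefined (`NaN`).
#'
#' @param a,b Case alternate / reference allele counts.
#' @param c,d Control alternate / reference allele counts.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5) # p = 2/252
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    gs_config_error("table entries must be non-negative integers")
  }
  if (all(counts == 0)) {
    return(list(odds_ratio = NaN, p_value = 1))
  }
  m <- a + b # case alleles
  n <- c + d # control alleles
  k <- a + c # total alternate alleles
  lo <- max(0, k - n)
  hi <- min(k, m)
  supp <- lo:hi
  probs <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN # empty cell: infinite or undefined
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Per-variant enrichment tests
#'
#' Runs [fisher_exact_2x2] on each eligible variant's allele counts:
#' case alternate vs reference alleles against control alternate vs
#' reference alleles.
#'
#' @param variants `data.frame` with columns `gene`, `variant_id`,
#'   `case_ac`, `case_an`, `control_ac`, `control_an` (allele counts and
#'   totals).
#' @param alpha Per-variant significance threshold (default 0.05).
#' @return `variants` with added `odds_ratio`, `p_value`, `significant`.
#' @export
test_enrichment <- function(variants, alpha = 0.05) {
  if (nrow(variants) > 0 &&
      (any(variants$case_ac > variants$case_an) ||
         any(variants$control_ac > variants$control_an))) {
    gs_data_error("allele count exceeds allele number")
  }
  res <- lapply(seq_len(nrow(variants)), function(i) {
    fisher_exact_2x2(
      variants$case_ac[i], variants$case_an[i] - variants$case_ac[i],
      variants$control_ac[i], variants$control_an[i] - variants$control_ac[i]
    )
  })
  variants$odds_ratio <- vapply(res, `[[`, 1, "odds_ratio")
  variants$p_value <- vapply(res, `[[`, 1, "p_value")
  variants$significant <- variants$p_value < alpha
  variants
}

#' Gene-level enrichment summary
#'
#' Per gene, the fraction of tested variants significant at `alpha`; a
#' gene is highlighted when STRICTLY more than half of its variants are
#' significant (exactly 50% does not qualify).  Optional
#' Benjamini-Hochberg correction is applied across all variants before
#' the per-gene fractions when `adjust = "BH"`.
#'
#' @param results Per-variant results from [test_enrichment].
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame`: `gene`, `n_tested`, `n_significant`,
#'   `fraction_significant`, `highlighted`.
#' @export
gene_level_summary <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- p < alpha
  genes <- unique(results$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    idx <- results$gene == g
    n <- sum(idx)
    ns <- sum(sig[idx])
    data.frame(
      gene = g, n_tested = n, n_significant = ns,
      fraction_significant = ns / n,
      highlighted = ns / n > 0.5,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
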