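## Germline and somatic SNV/indel filter cascades.
##
## Germline ("first hit") candidates must be adequately covered, rare in a
## population repository and predicted deleterious; somatic ("second hit")
## candidates must additionally be covered in BOTH members of the pair,
## reach a minimum tumor variant allele fraction, and not simply recall a
## germline variant.

#' Filter cascade configuration
#'
#' Thresholds driving the germline and somatic cascades.  Boundary
#' semantics are fixed: depth and VAF thresholds are inclusive
#' (`>= 10x`, `>= 20%`), the germline population-frequency cutoff is a
#' strict `<`, and a missense variant needs at least `min_predictors` of
#' the six pathogenicity tools in favor.  Truncating variants
#' (frameshift/nonsense/splice) bypass predictor scoring.
#'
#' @param min_depth Minimum read depth, germline and tumor (default 10).
#' @param min_tumor_vaf Minimum tumor variant allele fraction for somatic
#'   calls (default 0.20, inclusive).
#' @param min_predictors Minimum number of pathogenicity tools (of 6) a
#'   missense variant must pass (default 3).
#' @param max_pop_af_germline Population allele-frequency cutoff for
#'   germline candidates (default 0.001, strict `<`).
#' @param max_pop_af_enrichment Control allele-frequency cutoff for the
#'   case-control enrichment selection (default 0.001, strict `<`).
#' @param min_cadd_enrichment CADD Phred cutoff for the enrichment
#'   selection (default 15, strict `>`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10L,
                          min_tumor_vaf = 0.20,
                          min_predictors = 3L,
                          max_pop_af_germline = 0.001,
                          max_pop_af_enrichment = 0.001,
                          min_cadd_enrichment = 15) {
  if (min_tumor_vaf < 0 || min_tumor_vaf > 1) {
    gs_config_error("min_tumor_vaf must lie in [0, 1]")
  }
  if (min_predictors < 0 || min_predictors > 6) {
    gs_config_error("min_predictors must lie in 0..6")
  }
  structure(
    list(
      min_depth = as.integer(min_depth),
      min_tumor_vaf = min_tumor_vaf,
      min_predictors = as.integer(min_predictors),
      max_pop_af_germline = max_pop_af_germline,
      max_pop_af_enrichment = max_pop_af_enrichment,
      min_cadd_enrichment = min_cadd_enrichment
    ),
    class = "filter_config"
  )
}

#' Count passing pathogenicity predictors
#'
#' Scores each variant by the number of its six predictor calls that are
#' `TRUE`.  Missing (`NA`) calls count as failures; each tool with any
#' missing call is reported once in a warning.  Scoring is meaningful for
#' missense variants (truncating variants bypass it in the cascades).
#'
#' @param df Variant `data.frame` carrying the [predictor_tools] columns.
#' @return Integer vector `n_pass` (0..6), one per row, with attribute
#'   `passing_tools` (list of character vectors).
#' @export
score_pathogenicity <- function(df) {
  tools <- predictor_tools()
  if (nrow(df) == 0) {
    out <- integer(0)
    attr(out, "passing_tools") <- list()
    return(out)
  }
  miss <- setdiff(tools, names(df))
  calls <- sapply(tools, function(t) {
    v <- if (t %in% miss) rep(NA, nrow(df)) else as.logical(df[[t]])
    v
  })
  calls <- matrix(calls, nrow = nrow(df), dimnames = list(NULL, tools))
  na_tools <- tools[colSums(is.na(calls)) > 0 & nrow(df) > 0]
  if (length(na_tools) > 0) {
    warning(sprintf(
      "missing predictor call(s) treated as fail for tool(s): %s",
      paste(na_tools, collapse = ", ")
    ), call. = FALSE)
  }
  calls[is.na(calls)] <- FALSE
  n_pass <- as.integer(rowSums(calls))
  attr(n_pass, "passing_tools") <- lapply(seq_len(nrow(df)), function(i) tools[calls[i, ]])
  n_pass
}

## Population allele frequency with the "absent from repository = rare"
## convention: allele_number 0 means the variant was never observed, AF 0.
pop_af <- function(df) {
  ifelse(df$pop_allele_number > 0, df$pop_allele_count / df$pop_allele_number, 0)
}

## Evaluate a named list of logical rule vectors; returns keep mask and a
## per-row semicolon-joined trace of failed rules ("" when kept).
apply_rules <- function(rules, n) {
  fail <- matrix(FALSE, nrow = n, ncol = length(rules),
                 dimnames = list(NULL, names(rules)))
  for (r in names(rules)) fail[, r] <- !rules[[r]]
  keep <- rowSums(fail) == 0
  trace <- apply(fail, 1, function(f) paste(names(rules)[f], collapse = ";"))
  list(keep = keep, trace = trace)
}

#' Germline first-hit filter cascade
#'
#' Keeps germline variants that are (i) covered at `>= min_depth`,
#' (ii) rare — population allele frequency strictly below
#' `max_pop_af_germline`, with variants absent from the repository treated
#' as frequency 0 — and (iii) predicted deleterious: truncating, or
#' missense passing at least `min_predictors` of the six tools.
#' Synonymous and unclassified consequences never pass.
#'
#' @param records Germline variant `data.frame`.
#' @param cfg A [filter_config].
#' @param trace If `TRUE`, also return removed records with a
#'   `filter_trace` column naming the rules each failed.
#' @return The surviving records; with `trace = TRUE`, a list
#'   `list(kept, removed)`.
#' @export
filter_germline <- function(records, cfg = filter_config(), trace = FALSE) {
  if (nrow(records) > 0 && !all(records$origin == "germline")) {
    gs_data_error("filter_germline expects origin == 'germline' records")
  }
  n_pass <- suppressWarnings(score_pathogenicity(records))
  rules <- list(
    min_depth = records$depth >= cfg$min_depth,
    rare_in_population = pop_af(records) < cfg$max_pop_af_germline,
    deleterious_consequence = records$consequence == "truncating" |
      (records$consequence == "missense" & n_pass >= cfg$min_predictors)
  )
  res <- apply_rules(rules, nrow(records))
  kept <- records[res$keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (!trace) return(kept)
  removed <- records[!res$keep, , drop = FALSE]
  removed$filter_trace <- res$trace[!res$keep]
  rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Somatic second-hit filter cascade
#'
#' Keeps somatic variants that are covered at `>= min_depth` in BOTH the
#' tumor and the matched germline sample, reach a tumor variant allele
#' fraction of at least `min_tumor_vaf`, are predicted deleterious
#' (truncating, or missense with `>= min_predictors` tools in favor), and
#' are not identical to a germline call of the same sample (same
#' chrom/pos/ref/alt — those are germline variants re-called in the
#' tumor, not somatic events).
#'
#' Matched germline depth comes from a `normal_depth` column when present
#' (as emitted by paired somatic callers); otherwise it is looked up from
#' `germline_records` by site, and sites with no germline information are
#' treated as depth 0 and fail.
#'
#' @param records Somatic variant `data.frame`.
#' @param germline_records Same-sample germline variant `data.frame`
#'   (used for the identity exclusion and as a depth fallback).
#' @param cfg A [filter_config].
#' @param trace If `TRUE`, also return removed records with their
#'   `filter_trace`.
#' @return Surviving records, or `list(kept, removed)` when `trace = TRUE`.
#' @export
filter_somatic <- function(records, germline_records, cfg = filter_config(),
                           trace = FALSE) {
  if (nrow(records) > 0 && !all(records$origin == "somatic")) {
    gs_data_error("filter_somatic expects origin == 'somatic' records")
  }
  site_key <- function(d) paste(d$chrom, d$pos, sep = ":")
  var_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  if (!is.null(records$normal_depth)) {
    germ_depth <- records$normal_depth
  } else {
    idx <- match(site_key(records), site_key(germline_records))
    germ_depth <- ifelse(is.na(idx), 0L, germline_records$depth[idx])
  }
  vaf <- ifelse(records$depth > 0, records$alt_depth / records$depth, 0)
  n_pass <- suppressWarnings(score_pathogenicity(records))
  rules <- list(
    min_tumor_depth = records$depth >= cfg$min_depth,
    min_germline_depth = germ_depth >= cfg$min_depth,
    min_tumor_vaf = vaf >= cfg$min_tumor_vaf,
    deleterious_consequence = records$consequence == "truncating" |
      (records$consequence == "missense" & n_pass >= cfg$min_predictors),
    not_in_germline = !(var_key(records) %in% var_key(germline_records))
  )
  res <- apply_rules(rules, nrow(records))
  kept <- records[res$keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (!trace) return(kept)
  removed <- records[!res$keep, , drop = FALSE]
  removed$filter_trace <- res$trace[!res$keep]
  rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}
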