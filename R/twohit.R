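## Knudson two-hit pairing: a candidate tumor suppressor gene carries a
## deleterious germline variant (first hit) plus a second somatic event in
## the matched tumor — a DIFFERENT somatic SNV/indel, gene-level LOH, or
## both.

#' Pair germline first hits with somatic second hits per gene
#'
#' Builds one candidate row per (gene, sample) having at least one
#' filtered germline hit and at least one second hit.  A somatic variant
#' counts as a second hit only when distinct from the first hit (any of
#' chrom/pos/ref/alt differs); an LOH call counts when `is_loh` is true.
#' Classes: `somatic_snv`, `loh`, or `both` when a gene has second hits
#' of both kinds.  Output is deterministically ordered by (gene, sample).
#'
#' @param germline_hits Filtered germline variants (one sample or a
#'   cohort-level table with `sample_id`).
#' @param somatic_hits Filtered somatic variants.
#' @param loh_calls Gene-level LOH calls from [call_gene_loh] (may be
#'   `NULL` when LOH was not assessed).
#' @return `data.frame` of candidates: `gene`, `sample_id`,
#'   `second_hit_class`, first-hit fields (`first_*`), second-hit variant
#'   fields (`second_*`, `NA` for pure LOH candidates), LOH statistics,
#'   and `wildtype_allele_lost` (from the LOH call, `NA` when unknown).
#' @export
pair_two_hits <- function(germline_hits, somatic_hits, loh_calls = NULL) {
  empty <- data.frame(
    gene = character(0), sample_id = character(0),
    second_hit_class = character(0),
    first_chrom = character(0), first_pos = integer(0),
    first_ref = character(0), first_alt = character(0),
    first_consequence = character(0), first_n_pass = integer(0),
    first_pop_allele_count = integer(0), first_pop_allele_number = integer(0),
    second_chrom = character(0), second_pos = integer(0),
    second_ref = character(0), second_alt = character(0),
    second_consequence = character(0), second_n_pass = integer(0),
    loh_p_value = numeric(0), loh_mean_shift = numeric(0),
    wildtype_allele_lost = logical(0),
    stringsAsFactors = FALSE
  )
  if (nrow(germline_hits) == 0) return(empty)
  g_np <- suppressWarnings(score_pathogenicity(germline_hits))
  s_np <- if (nrow(somatic_hits) > 0) {
    suppressWarnings(score_pathogenicity(somatic_hits))
  } else {
    integer(0)
  }
  keys <- unique(germline_hits[c("gene", "sample_id")])
  keys <- keys[order(keys$gene, keys$sample_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    gene <- keys$gene[i]
    sample <- keys$sample_id[i]
    g_idx <- which(germline_hits$gene == gene & germline_hits$sample_id == sample)
    ## representative first hit: leftmost variant of the gene
    g1 <- g_idx[order(germline_hits$chrom[g_idx], germline_hits$pos[g_idx])][1]
    s_idx <- which(
      somatic_hits$gene == gene & somatic_hits$sample_id == sample &
        !(somatic_hits$chrom == germline_hits$chrom[g1] &
            somatic_hits$pos == germline_hits$pos[g1] &
            somatic_hits$ref == germline_hits$ref[g1] &
            somatic_hits$alt == germline_hits$alt[g1])
    )
    loh <- NULL
    if (!is.null(loh_calls) && nrow(loh_calls) > 0) {
      l_idx <- which(loh_calls$gene == gene &
                       (is.na(loh_calls$sample_id) | loh_calls$sample_id == sample) &
                       loh_calls$is_loh)
      if (length(l_idx) > 0) loh <- loh_calls[l_idx[1], ]
    }
    has_snv <- length(s_idx) > 0
    has_loh <- !is.null(loh)
    if (!has_snv && !has_loh) next
    cls <- if (has_snv && has_loh) "both" else if (has_snv) "somatic_snv" else "loh"
    s1 <- if (has_snv) {
      s_idx[order(somatic_hits$chrom[s_idx], somatic_hits$pos[s_idx])][1]
    } else {
      NA_integer_
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene = gene, sample_id = sample, second_hit_class = cls,
      first_chrom = germline_hits$chrom[g1],
      first_pos = germline_hits$pos[g1],
      first_ref = germline_hits$ref[g1],
      first_alt = germline_hits$alt[g1],
      first_consequence = germline_hits$consequence[g1],
      first_n_pass = g_np[g1],
      first_pop_allele_count = germline_hits$pop_allele_count[g1],
      first_pop_allele_number = germline_hits$pop_allele_number[g1],
      second_chrom = if (has_snv) somatic_hits$chrom[s1] else NA_character_,
      second_pos = if (has_snv) somatic_hits$pos[s1] else NA_integer_,
      second_ref = if (has_snv) somatic_hits$ref[s1] else NA_character_,
      second_alt = if (has_snv) somatic_hits$alt[s1] else NA_character_,
      second_consequence = if (has_snv) somatic_hits$consequence[s1] else NA_character_,
      second_n_pass = if (has_snv) s_np[s1] else NA_integer_,
      loh_p_value = if (has_loh) loh$p_value else NA_real_,
      loh_mean_shift = if (has_loh) loh$mean_shift else NA_real_,
      wildtype_allele_lost = if (has_loh) {
        if (is.na(loh$retains_germline_variant)) NA else loh$retains_germline_variant
      } else {
        NA
      },
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a candidate table
#'
#' Counts candidates per second-hit class, per first-hit type (SNV vs
#' indel, judged from allele lengths), and per sample.  The union obeys
#' inclusion-exclusion: `n_with_somatic_snv + n_with_loh - n_both`
#' equals the total number of candidates.
#'
#' @param candidates Candidate table from [pair_two_hits].
#' @return List with `n_candidates`, `by_class` (named counts of the
#'   disjoint classes), `n_with_somatic_snv`, `n_with_loh`, `n_both`,
#'   `first_hit_type` (SNV/indel counts) and `by_sample`.
#' @export
summarize_candidates <- function(candidates) {
  classes <- c(somatic_snv = 0L, loh = 0L, both = 0L)
  tab <- table(candidates$second_hit_class)
  classes[names(tab)] <- as.integer(tab)
  is_indel <- nchar(candidates$first_ref) != nchar(candidates$first_alt)
  list(
    n_candidates = nrow(candidates),
    by_class = classes,
    n_with_somatic_snv = unname(classes["somatic_snv"] + classes["both"]),
    n_with_loh = unname(classes["loh"] + classes["both"]),
    n_both = unname(classes["both"]),
    first_hit_type = c(
      snv = sum(!is_indel),
      indel = sum(is_indel)
    ),
    by_sample = table(candidates$sample_id)
  )
}

#' Default cancer-function keyword list
#'
#' Cellular functions compatible with a tumor suppressor role in
#' colorectal and general cancer, used to flag (never remove) candidates
#' whose annotated protein function matches.
#'
#' @return Character vector of keywords (matched case-insensitively).
#' @export
cancer_function_keywords <- function() {
  c(
    "DNA repair", "repair", "apoptosis", "autophagy", "cell growth",
    "cell proliferation", "inflammatory response", "cell cycle",
    "angiogenesis", "cell differentiation", "cell adhesion",
    "chromatin"
  )
}

#' DNA-repair keyword subset
#'
#' Keywords identifying DNA-repair functions specifically (double-strand
#' break repair, excision repair, translesion synthesis, ...).
#'
#' @return Character vector of keywords.
#' @export
dna_repair_keywords <- function() {
  c("repair", "translesion")
}

#' Flag candidates whose annotated function matches a keyword list
#'
#' Transparent stand-in for manual functional curation: candidates whose
#' protein-function text (from a user-supplied gene-to-function map)
#' matches any keyword are flagged and sorted first; nothing is removed.
#' Genes absent from the map are left unflagged and reported in the
#' `unmapped_genes` attribute.
#'
#' @param candidates Candidate table (any `data.frame` with a `gene`
#'   column).
#' @param keyword_map Named character vector or two-column `data.frame`
#'   (`gene`, `function_text`) mapping genes to free-text function
#'   descriptions.
#' @param keywords Keyword list (default [cancer_function_keywords]);
#'   matched case-insensitively and literally.
#' @return `candidates` with added columns `function_text` and
#'   `priority_flag`, flagged rows first (stable order otherwise).
#' @export
apply_function_prioritization <- function(candidates,
                                          keyword_map,
                                          keywords = cancer_function_keywords()) {
  if (is.data.frame(keyword_map)) {
    map <- stats::setNames(as.character(keyword_map$function_text), keyword_map$gene)
  } else {
    map <- keyword_map
  }
  txt <- unname(map[candidates$gene])
  flag <- rep(FALSE, nrow(candidates))
  if (length(keywords) > 0 && nrow(candidates) > 0) {
    for (kw in keywords) {
      flag <- flag | grepl(kw, txt, ignore.case = TRUE, fixed = FALSE)
    }
    flag[is.na(txt)] <- FALSE
  }
  out <- candidates
  out$function_text <- ifelse(is.na(txt), "", txt)
  out$priority_flag <- flag
  out <- out[order(!out$priority_flag), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_genes") <- unique(candidates$gene[is.na(txt)])
  out
}

#' Write a candidate table in report layout
#'
#' Mirrors the usual published candidate-table columns: gene, family,
#' HGVS-like variant string, predictor score `n/6` (or `FS` for
#' frameshifts), population frequency `count/number`, and the second-hit
#' class.
#'
#' @param candidates Candidate table from [pair_two_hits].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  is_fs <- candidates$first_consequence == "truncating" &
    nchar(candidates$first_ref) != nchar(candidates$first_alt)
  rep_df <- data.frame(
    gene = candidates$gene,
    family = candidates$sample_id,
    genetic_variant = sprintf(
      "c.%d%s>%s", candidates$first_pos, candidates$first_ref, candidates$first_alt
    ),
    path_tools = ifelse(is_fs, "FS", sprintf("%d/6", candidates$first_n_pass)),
    pop_freq = sprintf(
      "%d/%s", candidates$first_pop_allele_count,
      formatC(candidates$first_pop_allele_number, big.mark = ",", format = "d")
    ),
    second_hit_class = candidates$second_hit_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
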