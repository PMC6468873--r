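## Orchestration: run the full analysis (qc -> filter -> loh -> twohit ->
## signatures -> optional enrichment) over a cohort directory, writing
## per-stage TSVs and a machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param cohort_dir Directory holding `manifest.tsv`, `genes.bed`,
#'   `signatures.tsv` and the per-sample tables (as written by
#'   [generate_cohort], or hand-assembled in the same layout).
#' @param out_dir Output directory.
#' @param filter_cfg A [filter_config].
#' @param qc_threshold Minimum shared >= 10x coverage fraction (default 0.70).
#' @param loh_alpha Split-acceptance alpha for segmentation (default 0.01).
#' @param loh_alpha_call Segment-level LOH alpha (default 0.01).
#' @param loh_shift_min Minimum mean folded VAF shift (default 0.15).
#' @param loh_min_sites Minimum sites per segment (default 5).
#' @param loh_n_perm Permutations per split decision (default 1000).
#' @param signature_path Reference signature matrix TSV; `NULL` (default)
#'   uses `<cohort_dir>/signatures.tsv` when present and otherwise skips
#'   the refitting stage.  Passing a path explicitly makes the stage
#'   mandatory: a missing file is a config error before any compute.
#' @param enrichment_path Optional per-variant case-control TSV; enables
#'   the enrichment stage.
#' @param enrichment_alpha Per-variant alpha (default 0.05).
#' @param keyword_map_path Optional gene-to-function TSV (`gene`,
#'   `function_text`) enabling function prioritization flags.
#' @param seed Seed for the (permutation) randomness (default 1).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_dir, out_dir,
                       filter_cfg = filter_config(),
                       qc_threshold = 0.70,
                       loh_alpha = 0.01, loh_alpha_call = 0.01,
                       loh_shift_min = 0.15, loh_min_sites = 5,
                       loh_n_perm = 1000,
                       signature_path = NULL,
                       enrichment_path = NULL, enrichment_alpha = 0.05,
                       keyword_map_path = NULL,
                       seed = 1L) {
  if (!dir.exists(cohort_dir)) {
    gs_config_error(sprintf("cohort directory not found: %s", cohort_dir))
  }
  for (f in c("manifest.tsv", "genes.bed")) {
    if (!file.exists(file.path(cohort_dir, f))) {
      gs_config_error(sprintf("cohort directory lacks %s", f))
    }
  }
  if (!is.null(enrichment_path) && !file.exists(enrichment_path)) {
    gs_config_error(sprintf("enrichment table not found: %s", enrichment_path))
  }
  if (!is.null(signature_path) && !file.exists(signature_path)) {
    gs_config_error(sprintf("signature matrix not found: %s", signature_path))
  }
  structure(
    list(
      cohort_dir = cohort_dir, out_dir = out_dir, filter_cfg = filter_cfg,
      qc_threshold = qc_threshold,
      loh_alpha = loh_alpha, loh_alpha_call = loh_alpha_call,
      loh_shift_min = loh_shift_min, loh_min_sites = loh_min_sites,
      loh_n_perm = loh_n_perm,
      signature_path = signature_path,
      enrichment_path = enrichment_path, enrichment_alpha = enrichment_alpha,
      keyword_map_path = keyword_map_path,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config]; filter thresholds
#' go under a `filter:` mapping mirroring [filter_config].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) gs_config_error(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  fc <- do.call(filter_config, y$filter %||% list())
  args <- y[setdiff(names(y), "filter")]
  do.call(run_config, c(args, list(filter_cfg = fc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the integrated two-hit pipeline
#'
#' Executes QC, germline/somatic filtering, LOH calling, two-hit pairing,
#' burden/signature profiling and (optionally) case-control enrichment
#' over every QC-passing sample, writing per-stage TSVs under
#' `cfg$out_dir` plus `run_manifest.json` recording the package version,
#' seed and every threshold applied.  Re-running with identical inputs
#' and seed reproduces all outputs.
#'
#' @param cfg A [run_config].
#' @return Invisible report list: `n_samples`, `n_pass_qc`,
#'   `qc` (data.frame), `candidates`, `candidate_summary`, `burden`
#'   (data.frame), `exposures` (matrix or NULL), `loh_calls`,
#'   `enrichment` (or NULL), `output_files`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) gs_config_error("cfg must be a run_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[length(paths) + 1] <<- p
    p
  }

  ## --- qc -------------------------------------------------------------
  manifest <- read_manifest(file.path(cfg$cohort_dir, "manifest.tsv"))
  manifest$qc_pass <- qc_pass(manifest, cfg$qc_threshold)
  emit(manifest, "qc_summary.tsv")
  passing <- manifest[manifest$qc_pass, , drop = FALSE]
  intervals <- read_gene_intervals(file.path(cfg$cohort_dir, "genes.bed"))

  sig_path <- cfg$signature_path %||% file.path(cfg$cohort_dir, "signatures.tsv")
  S <- if (file.exists(sig_path)) read_signature_matrix(sig_path) else NULL

  germ_kept <- list(); soma_kept <- list(); loh_all <- list()
  catalogs <- list(); burden_rows <- list(); expo <- list()

  for (i in seq_len(nrow(passing))) {
    sid <- passing$sample_id[i]
    stage <- "read"
    res <- tryCatch({
      germ <- read_variant_table(file.path(cfg$cohort_dir, passing$germline_path[i]))
      soma <- read_variant_table(file.path(cfg$cohort_dir, passing$tumor_path[i]))
      sites <- read_site_depths(file.path(cfg$cohort_dir, passing$sites_path[i]))

      stage <- "filter"
      gk <- filter_germline(germ, cfg$filter_cfg)
      sk <- filter_somatic(soma, germ, cfg$filter_cfg)

      stage <- "loh"
      inf <- informative_sites(sites, min_depth = cfg$filter_cfg$min_depth)
      segs <- segment_vaf(
        inf, alpha = cfg$loh_alpha, min_sites = cfg$loh_min_sites,
        n_perm = cfg$loh_n_perm, alpha_loh = cfg$loh_alpha_call,
        shift_min = cfg$loh_shift_min, seed = derive_seed(cfg$seed, sid)
      )
      ## tumor VAF of each first hit, looked up among the het sites
      fh <- gk[c("gene", "chrom", "pos")]
      idx <- match(paste(fh$chrom, fh$pos), paste(sites$chrom, sites$pos))
      tdep <- sites$tum_ref[idx] + sites$tum_alt[idx]
      fh$tumor_vaf <- ifelse(!is.na(idx) & tdep > 0, sites$tum_alt[idx] / tdep, NA_real_)
      calls <- call_gene_loh(segs, intervals, first_hits = fh, sample_id = sid)

      stage <- "signatures"
      is_snv <- nchar(soma$ref) == 1 & nchar(soma$alt) == 1
      cat_input <- soma[is_snv, , drop = FALSE]
      if (is.null(cat_input$context)) cat_input$context <- NA_character_
      catalog <- suppressWarnings(build_catalog(cat_input, sample_id = sid))
      burden <- compute_burden(if (catalog$n_snv > 0) catalog else sum(is_snv))
      burden$sample_id <- sid
      fit <- if (!is.null(S) && catalog$n_snv > 0) refit_signatures(catalog, S) else NULL
      list(gk = gk, sk = sk, segs = segs, calls = calls,
           catalog = catalog, burden = burden, fit = fit)
    }, gs_error = function(e) {
      gs_data_error(sprintf("stage '%s' failed for sample %s: %s",
                            stage, sid, conditionMessage(e)))
    })
    germ_kept[[sid]] <- res$gk
    soma_kept[[sid]] <- res$sk
    loh_all[[sid]] <- res$calls
    catalogs[[sid]] <- res$catalog
    burden_rows[[sid]] <- data.frame(
      sample_id = sid, n_snv = res$burden$n_snv,
      mutations_per_mb = res$burden$mutations_per_mb,
      class = res$burden$class, stringsAsFactors = FALSE
    )
    if (!is.null(res$fit)) expo[[sid]] <- res$fit
    write_segments(res$segs, file.path(cfg$out_dir, sprintf("segments_%s", sid)))
    emit(res$calls, sprintf("loh_calls_%s.tsv", sid))
  }

  bind <- function(lst, template) {
    if (length(lst) == 0) template else do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  germ_all <- bind(germ_kept, NULL)
  soma_all <- bind(soma_kept, NULL)
  loh_df <- bind(loh_all, NULL)
  if (!is.null(germ_all)) emit(germ_all, "germline_filtered.tsv")
  if (!is.null(soma_all)) emit(soma_all, "somatic_filtered.tsv")

  ## --- two-hit pairing --------------------------------------------------
  candidates <- if (!is.null(germ_all) && nrow(germ_all) > 0) {
    pair_two_hits(germ_all,
                  if (is.null(soma_all)) germ_all[0, ] else soma_all,
                  loh_df)
  } else {
    pair_two_hits(
      data.frame(gene = character(0), sample_id = character(0))[0, ],
      NULL, NULL
    )
  }
  if (!is.null(cfg$keyword_map_path) && file.exists(cfg$keyword_map_path)) {
    km <- utils::read.delim(cfg$keyword_map_path, stringsAsFactors = FALSE)
    candidates <- apply_function_prioritization(candidates, km)
  }
  emit(candidates, "candidates.tsv")
  write_candidate_table(candidates, file.path(cfg$out_dir, "candidate_table.tsv"))
  summary <- summarize_candidates(candidates)

  ## --- burden & signatures ---------------------------------------------
  burden_df <- bind(burden_rows, NULL)
  if (!is.null(burden_df)) emit(burden_df, "burden.tsv")
  expo_mat <- NULL
  if (length(expo) > 0) {
    expo_mat <- vapply(expo, function(f) f$contributions, numeric(ncol(S)))
    emit(
      data.frame(signature = colnames(S), expo_mat, check.names = FALSE),
      "signature_contributions.tsv"
    )
  }
  if (length(catalogs) > 0) {
    write_catalog_table(catalogs, file.path(cfg$out_dir, "catalogs.tsv"))
  }

  ## --- optional enrichment ---------------------------------------------
  enr <- NULL
  if (!is.null(cfg$enrichment_path)) {
    ev <- utils::read.delim(cfg$enrichment_path, stringsAsFactors = FALSE)
    eligible <- select_enrichment_variants(
      ev, max_af = cfg$filter_cfg$max_pop_af_enrichment,
      min_cadd = cfg$filter_cfg$min_cadd_enrichment
    )
    pv <- test_enrichment(eligible, alpha = cfg$enrichment_alpha)
    gs <- gene_level_summary(pv, alpha = cfg$enrichment_alpha)
    emit(pv, "enrichment_variants.tsv")
    emit(gs, "enrichment_genes.tsv")
    enr <- list(variants = pv, genes = gs)
  }

  run_manifest <- list(
    package = "germsoma",
    version = as.character(utils::packageVersion("germsoma")),
    seed = cfg$seed,
    qc_threshold = cfg$qc_threshold,
    filter = unclass(cfg$filter_cfg),
    loh = list(
      alpha = cfg$loh_alpha, alpha_call = cfg$loh_alpha_call,
      shift_min = cfg$loh_shift_min, min_sites = cfg$loh_min_sites,
      n_perm = cfg$loh_n_perm
    ),
    enrichment_alpha = cfg$enrichment_alpha,
    n_samples = nrow(manifest),
    n_pass_qc = nrow(passing)
  )
  jsonlite::write_json(run_manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (nrow(passing) == 0) {
    warning("no samples passed QC: report is empty", call. = FALSE)
  }
  invisible(list(
    n_samples = nrow(manifest),
    n_pass_qc = nrow(passing),
    qc = manifest,
    candidates = candidates,
    candidate_summary = summary,
    burden = burden_df,
    exposures = expo_mat,
    loh_calls = loh_df,
    enrichment = enr,
    output_files = paths
  ))
}
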