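## Synthetic paired-cohort generator.
##
## Emits, per sample, a germline variant table, a somatic variant table
## (coding candidates plus a genome-wide SNV catalog drawn from a stated
## signature mixture) and paired allele depths at designed het sites,
## together with a manifest, gene intervals (BED), a signature matrix and
## a machine-readable ground truth.  Everything the pipeline consumes is
## produced here, with planted two-hit genes and copy-neutral LOH whose
## expected tumor VAF at purity p is (1 - p/2) on the retained-variant
## haplotype and p/2 on the lost one.

#' Cohort generator configuration
#'
#' The defaults state the emulated study design: 18 paired samples of
#' which 2 tumors fail the shared-coverage QC, tumor cell content 0.75
#' (the middle of the typical 70-80% range for macrodissected FFPE
#' colorectal tumors), mean sequencing depth 100x (Poisson), a 30 Mb
#' callable exome, and copy-neutral LOH as the second-hit mechanism.
#'
#' @param n_samples Number of paired samples (default 18).
#' @param n_genes Genes in the synthetic exome (default 40).
#' @param n_chroms Synthetic contigs the genes are laid out on (default 4).
#' @param exome_mb Callable exome size in Mb (default 30).
#' @param tumor_purity Tumor cell fraction in (0, 1] (default 0.75).
#' @param mean_depth Mean read depth, Poisson (default 100).
#' @param het_sites_per_gene Designed germline-het sites per gene
#'   (default 8).
#' @param planted_twohit `data.frame` with columns `gene`, `sample_id`,
#'   `first_hit_type` (`"snv"`/`"indel"`) and `second_hit_type`
#'   (`"somatic_snv"`/`"loh"`/`"both"`); `NULL` for a default panel of
#'   six planted genes across the first samples.
#' @param n_germline_only,n_somatic_only Negative-control genes carrying
#'   only a first or only a second hit (default 3 each).
#' @param signature_matrix 96 x K signature matrix; `NULL` for a
#'   synthetic well-separated 5-signature matrix.
#' @param signature_mixture Mixture proportions over signatures used for
#'   every sample's somatic catalog (default 0.8/0.2 on the first two
#'   signatures, a dominant clock-like process plus a minor one).
#' @param burden_per_mb Per-sample somatic burden (recycled; default 30
#'   mutations/Mb, a typical non-hypermutated colorectal exome).
#' @param n_lowqc_tumors Tumors given a failing QC fraction (default 2).
#' @param base_error Uniform sequencing base-error rate added to site
#'   VAFs (default 0; binomial sampling is the only noise).
#' @param seed Master seed; every random draw derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 18L,
                          n_genes = 40L,
                          n_chroms = 4L,
                          exome_mb = 30,
                          tumor_purity = 0.75,
                          mean_depth = 100,
                          het_sites_per_gene = 8L,
                          planted_twohit = NULL,
                          n_germline_only = 3L,
                          n_somatic_only = 3L,
                          signature_matrix = NULL,
                          signature_mixture = NULL,
                          burden_per_mb = 30,
                          n_lowqc_tumors = 2L,
                          base_error = 0,
                          seed = 1L) {
  if (tumor_purity <= 0 || tumor_purity > 1) {
    gs_config_error("tumor_purity must lie in (0, 1]")
  }
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  if (is.null(planted_twohit)) {
    planted_twohit <- data.frame(
      gene = genes[1:6],
      sample_id = sample_ids[c(1, 2, 3, 4, 5, 6) %% n_samples + 1],
      first_hit_type = c("snv", "snv", "snv", "indel", "snv", "snv"),
      second_hit_type = c("somatic_snv", "loh", "loh", "loh", "both", "loh"),
      stringsAsFactors = FALSE
    )
  }
  if (!all(planted_twohit$gene %in% genes)) {
    gs_config_error("planted gene outside the synthetic gene set")
  }
  if (!all(planted_twohit$sample_id %in% sample_ids)) {
    gs_config_error("planted sample_id outside the cohort")
  }
  if (length(unique(planted_twohit$gene)) +
        n_germline_only + n_somatic_only > n_genes) {
    gs_config_error("more planted genes than genes in the exome")
  }
  if (is.null(signature_matrix)) {
    signature_matrix <- synthetic_signature_matrix(5L, seed = derive_seed(seed, "sigs"))
  }
  k <- ncol(signature_matrix)
  if (is.null(signature_mixture)) {
    signature_mixture <- c(0.8, 0.2, rep(0, k - 2))
  }
  if (abs(sum(signature_mixture) - 1) > 1e-8) {
    gs_config_error("signature_mixture must sum to 1")
  }
  burden <- rep_len(burden_per_mb, n_samples)
  structure(
    list(
      n_samples = as.integer(n_samples), sample_ids = sample_ids,
      n_genes = as.integer(n_genes), genes = genes,
      n_chroms = as.integer(n_chroms), exome_mb = exome_mb,
      tumor_purity = tumor_purity, mean_depth = mean_depth,
      het_sites_per_gene = as.integer(het_sites_per_gene),
      planted_twohit = planted_twohit,
      n_germline_only = as.integer(n_germline_only),
      n_somatic_only = as.integer(n_somatic_only),
      signature_matrix = signature_matrix,
      signature_mixture = signature_mixture,
      burden_per_mb = burden,
      n_lowqc_tumors = as.integer(n_lowqc_tumors),
      base_error = base_error,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Synthetic well-separated signature matrix
#'
#' K signatures, each concentrating 85% of its probability mass on its
#' own block of channels (Gamma-weighted within the block, a thin uniform
#' floor elsewhere), so refitting can be validated against planted
#' mixtures without any external signature catalog.
#'
#' @param k Number of signatures (default 5).
#' @param seed Seed for the Gamma draws.
#' @return 96 x k column-stochastic matrix with channel rownames.
#' @export
synthetic_signature_matrix <- function(k = 5L, seed = 1L) {
  with_seed(seed, {
    channels <- sbs96_channels()
    block <- split(seq_along(channels), cut(seq_along(channels), k, labels = FALSE))
    S <- sapply(seq_len(k), function(j) {
      w <- rep(0.15 / (96 - length(block[[j]])), 96)
      g <- stats::rgamma(length(block[[j]]), shape = 2)
      w[block[[j]]] <- 0.85 * g / sum(g)
      w / sum(w)
    })
    rownames(S) <- channels
    colnames(S) <- sprintf("SIG%d", seq_len(k))
    S
  })
}

## Gene layout: contiguous blocks of genes per contig, 10 kb genes spaced
## 50 kb apart, het sites evenly spaced within each gene.
gene_layout <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  idx <- seq_len(cfg$n_genes) - 1L
  chrom <- sprintf("chr%d", idx %/% per_chrom + 1L)
  within <- idx %% per_chrom
  start <- within * 50000L + 10001L
  data.frame(
    gene = cfg$genes, chrom = chrom,
    start = start, end = start + 9999L,
    stringsAsFactors = FALSE
  )
}

het_positions <- function(layout, h) {
  do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    data.frame(
      gene = layout$gene[i], chrom = layout$chrom[i],
      pos = layout$start[i] + round(seq(0, 9999, length.out = h)),
      site_index = seq_len(h),
      stringsAsFactors = FALSE
    )
  }))
}

blank_variant_row <- function(sample_id, chrom, pos, ref, alt, origin, gene,
                              consequence, depth, alt_depth,
                              predictors = rep(FALSE, 6), cadd = 0,
                              pop_ac = 0L, pop_an = 0L) {
  row <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, origin = origin, gene = gene,
    consequence = consequence, depth = as.integer(depth),
    alt_depth = as.integer(alt_depth),
    stringsAsFactors = FALSE
  )
  tools <- predictor_tools()
  for (i in seq_along(tools)) row[[tools[i]]] <- predictors[i]
  row$cadd_phred <- cadd
  row$pop_allele_count <- as.integer(pop_ac)
  row$pop_allele_number <- as.integer(pop_an)
  row
}

rbinom1 <- function(size, prob) stats::rbinom(1, size, prob)

#' Generate a synthetic paired cohort on disk
#'
#' Writes, under `dir`: `germline_<id>.tsv`, `somatic_<id>.tsv`,
#' `sites_<id>.tsv` per sample, `manifest.tsv`, `genes.bed`,
#' `signatures.tsv` and `ground_truth.json`.  Deterministic given the
#' config seed: identical runs produce byte-identical files.
#'
#' Germline het sites draw alt reads ~ Binomial(depth, 0.5); tumor alt
#' reads ~ Binomial(depth, v) with v = 0.5 at balanced sites and, inside
#' planted copy-neutral LOH at purity p, v = (1 + p)/2 on the retained
#' haplotype or (1 - p)/2 on the lost one (phase random per site, except the
#' first-hit variant site where the wild-type allele is always the lost
#' one).  Somatic catalogs hold exactly `round(burden_per_mb * exome_mb)`
#' SNVs per sample with channels drawn from the configured signature
#' mixture.
#'
#' @param cfg A [cohort_config].
#' @param dir Output directory (created if needed).
#' @return Invisible list with `dir`, `manifest` (data.frame) and
#'   `ground_truth` (list, also serialized as JSON).
#' @export
generate_cohort <- function(cfg, dir) {
  if (!inherits(cfg, "cohort_config")) gs_config_error("cfg must be a cohort_config")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- gene_layout(cfg)
  write_gene_intervals(layout, file.path(dir, "genes.bed"))
  write_signature_matrix(cfg$signature_matrix, file.path(dir, "signatures.tsv"))
  hets <- het_positions(layout, cfg$het_sites_per_gene)
  ## copy-neutral LOH at purity p: tumor cells carry 2 copies of the
  ## retained allele and 0 of the lost one, stroma stays 1/1, so the
  ## retained-allele VAF is (1+p)/2 and the lost-allele VAF (1-p)/2
  ## (0.875 / 0.125 at p = 0.75).
  p <- cfg$tumor_purity
  v_high <- (1 + p) / 2
  v_low <- (1 - p) / 2

  used_genes <- unique(cfg$planted_twohit$gene)
  free_genes <- setdiff(cfg$genes, used_genes)
  germline_only_genes <- free_genes[seq_len(cfg$n_germline_only)]
  somatic_only_genes <- free_genes[cfg$n_germline_only + seq_len(cfg$n_somatic_only)]
  go_samples <- cfg$sample_ids[(seq_len(cfg$n_germline_only) - 1L) %% cfg$n_samples + 1L]
  so_samples <- cfg$sample_ids[(seq_len(cfg$n_somatic_only) - 1L) %% cfg$n_samples + 1L]

  manifest <- data.frame(
    sample_id = cfg$sample_ids,
    germline_path = sprintf("germline_%s.tsv", cfg$sample_ids),
    tumor_path = sprintf("somatic_%s.tsv", cfg$sample_ids),
    sites_path = sprintf("sites_%s.tsv", cfg$sample_ids),
    qc_shared_ge10x_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- list(
    planted_twohit = cfg$planted_twohit,
    germline_only = data.frame(gene = germline_only_genes, sample_id = go_samples,
                               stringsAsFactors = FALSE),
    somatic_only = data.frame(gene = somatic_only_genes, sample_id = so_samples,
                              stringsAsFactors = FALSE),
    signature_mixture = stats::setNames(
      as.numeric(cfg$signature_mixture), colnames(cfg$signature_matrix)
    ),
    burden_per_mb = stats::setNames(as.numeric(cfg$burden_per_mb), cfg$sample_ids),
    tumor_purity = p,
    expected_loh_vaf = c(v_low, v_high),
    lowqc_samples = character(0),
    seed = cfg$seed
  )

  with_seed(cfg$seed, {
    lowqc <- if (cfg$n_lowqc_tumors > 0) {
      sort(sample(cfg$sample_ids, cfg$n_lowqc_tumors))
    } else {
      character(0)
    }
    truth$lowqc_samples <- lowqc
    manifest$qc_shared_ge10x_fraction <- round(ifelse(
      cfg$sample_ids %in% lowqc,
      stats::runif(cfg$n_samples, 0.45, 0.65),
      stats::runif(cfg$n_samples, 0.85, 0.99)
    ), 4)

    for (si in seq_len(cfg$n_samples)) {
      sid <- cfg$sample_ids[si]
      planted <- cfg$planted_twohit[cfg$planted_twohit$sample_id == sid, , drop = FALSE]
      loh_genes <- planted$gene[planted$second_hit_type %in% c("loh", "both")]
      snv2_genes <- planted$gene[planted$second_hit_type %in% c("somatic_snv", "both")]
      g_first <- planted
      if (any(go_samples == sid)) {
        g_first <- rbind(g_first, data.frame(
          gene = germline_only_genes[go_samples == sid], sample_id = sid,
          first_hit_type = "snv", second_hit_type = "none",
          stringsAsFactors = FALSE
        ))
      }

      ## --- germline variants -------------------------------------------
      germ <- list()
      first_hit_pos <- stats::setNames(integer(0), character(0))
      for (gi in seq_len(nrow(g_first))) {
        gene <- g_first$gene[gi]
        lay <- layout[layout$gene == gene, ]
        pos <- hets$pos[hets$gene == gene & hets$site_index == 3L]
        first_hit_pos[gene] <- pos
        depth <- stats::rpois(1, cfg$mean_depth)
        alt_d <- rbinom1(depth, 0.5)
        if (g_first$first_hit_type[gi] == "indel") {
          germ[[length(germ) + 1]] <- blank_variant_row(
            sid, lay$chrom, pos, "CT", "C", "germline", gene, "truncating",
            depth, alt_d, cadd = 35, pop_ac = 0L, pop_an = 60706L
          )
        } else {
          germ[[length(germ) + 1]] <- blank_variant_row(
            sid, lay$chrom, pos, "C", "T", "germline", gene, "missense",
            depth, alt_d, predictors = rep(TRUE, 6), cadd = 28.3,
            pop_ac = 0L, pop_an = 60706L
          )
        }
      }
      ## background germline calls the cascade must remove
      bg_genes <- sample(cfg$genes, 30, replace = TRUE)
      for (bi in seq_len(30)) {
        gene <- bg_genes[bi]
        lay <- layout[layout$gene == gene, ]
        pos <- lay$start + 7L + bi
        depth <- stats::rpois(1, cfg$mean_depth)
        alt_d <- rbinom1(depth, 0.5)
        kind <- bi %% 4L
        germ[[length(germ) + 1]] <- switch(as.character(kind),
          "0" = blank_variant_row( # synonymous
            sid, lay$chrom, pos, "G", "A", "germline", gene, "synonymous",
            depth, alt_d, cadd = 2.1, pop_ac = 0L, pop_an = 60706L
          ),
          "1" = blank_variant_row( # common missense
            sid, lay$chrom, pos, "A", "G", "germline", gene, "missense",
            depth, alt_d, predictors = rep(TRUE, 6), cadd = 25.0,
            pop_ac = 3000L, pop_an = 60000L
          ),
          "2" = blank_variant_row( # weakly supported missense (1/6)
            sid, lay$chrom, pos, "C", "G", "germline", gene, "missense",
            depth, alt_d, predictors = c(TRUE, rep(FALSE, 5)), cadd = 8.4,
            pop_ac = 1L, pop_an = 60706L
          ),
          "3" = blank_variant_row( # rare truncating but poorly covered
            sid, lay$chrom, pos, "T", "A", "germline", gene, "truncating",
            5L, rbinom1(5L, 0.5), cadd = 33, pop_ac = 0L, pop_an = 60706L
          )
        )
      }
      germ_df <- do.call(rbind, germ)
      germ_df <- germ_df[order(germ_df$chrom, germ_df$pos), , drop = FALSE]
      write_variant_table(germ_df, file.path(dir, sprintf("germline_%s.tsv", sid)))

      ## --- somatic variants --------------------------------------------
      soma <- list()
      for (gene in snv2_genes) {
        lay <- layout[layout$gene == gene, ]
        pos <- hets$pos[hets$gene == gene & hets$site_index == 6L] + 3L
        depth <- stats::rpois(1, cfg$mean_depth)
        row <- blank_variant_row(
          sid, lay$chrom, pos, "C", "A", "somatic", gene, "missense",
          depth, rbinom1(depth, p / 2),
          predictors = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE), cadd = 24.0
        )
        row$normal_depth <- stats::rpois(1, cfg$mean_depth)
        row$context <- "ACA"
        soma[[length(soma) + 1]] <- row
      }
      if (any(so_samples == sid)) {
        for (gene in somatic_only_genes[so_samples == sid]) {
          lay <- layout[layout$gene == gene, ]
          depth <- stats::rpois(1, cfg$mean_depth)
          row <- blank_variant_row(
            sid, lay$chrom, lay$start + 55L, "C", "G", "somatic", gene, "missense",
            depth, rbinom1(depth, p / 2),
            predictors = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), cadd = 22.5
          )
          row$normal_depth <- stats::rpois(1, cfg$mean_depth)
          row$context <- "GCT"
          soma[[length(soma) + 1]] <- row
        }
      }
      ## background somatic calls the cascade must remove
      bg2_genes <- sample(cfg$genes, 12, replace = TRUE)
      for (bi in seq_len(12)) {
        gene <- bg2_genes[bi]
        lay <- layout[layout$gene == gene, ]
        pos <- lay$start + 500L + bi
        depth <- stats::rpois(1, cfg$mean_depth)
        kind <- bi %% 3L
        row <- switch(as.character(kind),
          "0" = blank_variant_row( # subthreshold VAF
            sid, lay$chrom, pos, "T", "C", "somatic", gene, "missense",
            depth, rbinom1(depth, 0.05),
            predictors = rep(TRUE, 6), cadd = 26
          ),
          "1" = blank_variant_row( # synonymous
            sid, lay$chrom, pos, "G", "T", "somatic", gene, "synonymous",
            depth, rbinom1(depth, p / 2), cadd = 1.2
          ),
          "2" = blank_variant_row( # poorly covered in the normal
            sid, lay$chrom, pos, "A", "C", "somatic", gene, "missense",
            depth, rbinom1(depth, p / 2),
            predictors = rep(TRUE, 6), cadd = 27
          )
        )
        row$normal_depth <- if (kind == 2L) 4L else stats::rpois(1, cfg$mean_depth)
        row$context <- c("ATA", "TGT", "CAG")[kind + 1L]
        soma[[length(soma) + 1]] <- row
      }
      ## a germline variant re-called in the tumor (must be excluded)
      if (nrow(g_first) > 0) {
        gref <- germ_df[germ_df$gene == g_first$gene[1] &
                          germ_df$pos == first_hit_pos[g_first$gene[1]], ][1, ]
        row <- blank_variant_row(
          sid, gref$chrom, gref$pos, gref$ref, gref$alt, "somatic",
          gref$gene, gref$consequence, gref$depth, gref$alt_depth,
          predictors = unlist(gref[predictor_tools()]), cadd = gref$cadd_phred,
          pop_ac = gref$pop_allele_count, pop_an = gref$pop_allele_number
        )
        row$normal_depth <- stats::rpois(1, cfg$mean_depth)
        row$context <- "ACA"
        soma[[length(soma) + 1]] <- row
      }
      special <- do.call(rbind, soma)
      n_special_snv <- sum(nchar(special$ref) == 1 & nchar(special$alt) == 1)

      ## genome-wide catalog completing the stated burden exactly
      n_total <- round(cfg$burden_per_mb[si] * cfg$exome_mb)
      n_cat <- max(0L, n_total - n_special_snv)
      probs <- as.numeric(cfg$signature_matrix %*% cfg$signature_mixture)
      ch_counts <- as.integer(stats::rmultinom(1, n_cat, probs))
      ch <- rep(sbs96_channels(), ch_counts)
      if (length(ch) > 0) {
        five <- substr(ch, 1, 1)
        refb <- substr(ch, 3, 3)
        altb <- substr(ch, 5, 5)
        three <- substr(ch, 7, 7)
        chrom_span <- max(layout$end) + 10000L
        cat_depth <- stats::rpois(length(ch), cfg$mean_depth)
        cat_df <- data.frame(
          sample_id = sid,
          chrom = sample(sprintf("chr%d", seq_len(cfg$n_chroms)), length(ch), replace = TRUE),
          pos = chrom_span + sample.int(1000000L, length(ch), replace = TRUE),
          ref = refb, alt = altb, origin = "somatic", gene = "",
          consequence = "other", depth = cat_depth,
          alt_depth = stats::rbinom(length(ch), cat_depth, p / 2),
          stringsAsFactors = FALSE
        )
        for (tool in predictor_tools()) cat_df[[tool]] <- FALSE
        cat_df$cadd_phred <- 0
        cat_df$pop_allele_count <- 0L
        cat_df$pop_allele_number <- 0L
        cat_df$normal_depth <- stats::rpois(length(ch), cfg$mean_depth)
        cat_df$context <- paste0(five, refb, three)
        soma_df <- rbind(special, cat_df)
      } else {
        soma_df <- special
      }
      soma_df <- soma_df[order(soma_df$chrom, soma_df$pos), , drop = FALSE]
      write_variant_table(soma_df, file.path(dir, sprintf("somatic_%s.tsv", sid)))

      ## --- het-site allele depths --------------------------------------
      sdf <- hets
      gd <- stats::rpois(nrow(sdf), cfg$mean_depth)
      td <- stats::rpois(nrow(sdf), cfg$mean_depth)
      in_loh <- sdf$gene %in% loh_genes
      retain_alt <- stats::runif(nrow(sdf)) < 0.5 # phase of the retained haplotype
      fh_gene <- sdf$gene %in% names(first_hit_pos)
      at_first_hit <- fh_gene & sdf$pos == unname(first_hit_pos[
        ifelse(fh_gene, sdf$gene, NA_character_)
      ])
      at_first_hit[is.na(at_first_hit)] <- FALSE
      retain_alt[at_first_hit] <- TRUE # wild-type allele is the lost one
      v <- ifelse(in_loh, ifelse(retain_alt, v_high, v_low), 0.5)
      if (cfg$base_error > 0) {
        v <- pmin(pmax(v * (1 - cfg$base_error) + (1 - v) * cfg$base_error, 0), 1)
      }
      sdf$germ_ref <- NA_integer_
      sdf$germ_alt <- stats::rbinom(nrow(sdf), gd, 0.5)
      sdf$germ_ref <- gd - sdf$germ_alt
      sdf$tum_alt <- stats::rbinom(nrow(sdf), td, v)
      sdf$tum_ref <- td - sdf$tum_alt
      write_site_depths(
        sdf[c("chrom", "pos", "germ_ref", "germ_alt", "tum_ref", "tum_alt")],
        file.path(dir, sprintf("sites_%s.tsv", sid))
      )
    }
  })

  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(list(dir = dir, manifest = manifest, ground_truth = truth))
}

#' Study-shaped reference cohort configuration
#'
#' The fixture emulating the shape of a familial-CRC paired-exome study:
#' 18 samples of which 2 tumors fail QC; among the 16 passing samples,
#' exactly 5 are hypermutated (>= 90 mutations/Mb), 1 of them
#' ultrahypermutated (> 500/Mb), the cohort median burden is 58.8
#' mutations/Mb, and the mixture is dominated by a clock-like signature.
#' Burdens include the worked-example values 96.9, 61.0 and 30.8
#' mutations/Mb.
#'
#' @param seed Master seed (default 20190313).
#' @return A [cohort_config].
#' @export
study_cohort_config <- function(seed = 20190313L) {
  passing_burdens <- c(
    18.5, 22.4, 30.8, 41.2, 47.6, 52.3, 56.1, 58.8,
    58.8, 61.0, 68.4, 96.9, 104.2, 131.5, 182.7, 520.6
  )
  ## low-QC tumors are drawn inside generate_cohort from the same seed;
  ## reproduce the draw here so their (discarded) burdens slot in place.
  sample_ids <- sprintf("S%02d", 1:18)
  lowqc <- with_seed(seed, sort(sample(sample_ids, 2)))
  burdens <- numeric(18)
  burdens[sample_ids %in% lowqc] <- c(44.0, 49.5)
  burdens[!sample_ids %in% lowqc] <- passing_burdens
  cohort_config(
    n_samples = 18L,
    burden_per_mb = burdens,
    n_lowqc_tumors = 2L,
    seed = seed
  )
}

#' Generate a synthetic case-control enrichment table
#'
#' Per gene, `n_variants` rare coding variants with allele counts in a
#' case cohort (default 1006 patients, 2012 alleles) and a control
#' repository (default 60706 exomes, 121412 alleles).  Genes listed in
#' `enriched_genes` receive case allele counts drawn at 40x the control
#' rate; the rest share the control rate (null).
#'
#' @param genes Character vector of gene names.
#' @param enriched_genes Subset of `genes` to enrich in cases.
#' @param n_variants Variants per gene (default 4).
#' @param case_an,control_an Allele numbers (defaults 2012 / 121412).
#' @param control_rate Per-allele control frequency (default 2e-5).
#' @param seed Seed.
#' @return `data.frame` ready for [test_enrichment], with `control_af`
#'   and `cadd_phred` columns for [select_enrichment_variants].
#' @export
generate_enrichment_table <- function(genes, enriched_genes = character(0),
                                      n_variants = 4L, case_an = 2012L,
                                      control_an = 121412L,
                                      control_rate = 2e-5, seed = 1L) {
  with_seed(seed, {
    rows <- do.call(rbind, lapply(genes, function(g) {
      rate <- if (g %in% enriched_genes) control_rate * 40 else control_rate
      data.frame(
        gene = g,
        variant_id = sprintf("%s_v%d", g, seq_len(n_variants)),
        case_ac = stats::rbinom(n_variants, case_an, rate),
        case_an = case_an,
        control_ac = stats::rbinom(n_variants, control_an, control_rate),
        control_an = control_an,
        cadd_phred = round(stats::runif(n_variants, 16, 35), 1),
        stringsAsFactors = FALSE
      )
    }))
    rows$control_af <- rows$control_ac / rows$control_an
    rows
  })
}
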