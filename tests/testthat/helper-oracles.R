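# Independent oracles: written as naive per-record / brute-force
# implementations that never share code with the package paths they check.

# Exact two-sided binomial p (probability ordering) by direct summation.
oracle_binom_p <- function(x, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Hypergeometric enumeration of the 2x2 exact test using choose() only.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  total <- choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x) choose(m, x) * choose(n, k - x) / total, 1)
  p_obs <- choose(m, a) * choose(n, k - a) / total
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive per-record germline cascade (loops and if/else only).
oracle_filter_germline <- function(records, cfg) {
  keep <- logical(nrow(records))
  tools <- c("phylop", "sift", "polyphen2", "mutationtaster", "lrt", "cadd15")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    af <- if (r$pop_allele_number > 0) r$pop_allele_count / r$pop_allele_number else 0
    np <- 0
    for (t in tools) if (isTRUE(r[[t]])) np <- np + 1
    deleterious <- r$consequence == "truncating" ||
      (r$consequence == "missense" && np >= cfg$min_predictors)
    keep[i] <- r$depth >= cfg$min_depth &&
      af < cfg$max_pop_af_germline &&
      deleterious
  }
  records[keep, , drop = FALSE]
}

# Naive per-record somatic cascade.
oracle_filter_somatic <- function(records, germ, cfg) {
  keep <- logical(nrow(records))
  tools <- c("phylop", "sift", "polyphen2", "mutationtaster", "lrt", "cadd15")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    gd <- if (!is.null(r$normal_depth) && !is.na(r$normal_depth)) {
      r$normal_depth
    } else {
      gd0 <- 0
      for (j in seq_len(nrow(germ))) {
        if (germ$chrom[j] == r$chrom && germ$pos[j] == r$pos) gd0 <- germ$depth[j]
      }
      gd0
    }
    vaf <- if (r$depth > 0) r$alt_depth / r$depth else 0
    np <- 0
    for (t in tools) if (isTRUE(r[[t]])) np <- np + 1
    deleterious <- r$consequence == "truncating" ||
      (r$consequence == "missense" && np >= cfg$min_predictors)
    in_germ <- FALSE
    for (j in seq_len(nrow(germ))) {
      if (germ$chrom[j] == r$chrom && germ$pos[j] == r$pos &&
            germ$ref[j] == r$ref && germ$alt[j] == r$alt) {
        in_germ <- TRUE
      }
    }
    keep[i] <- r$depth >= cfg$min_depth && gd >= cfg$min_depth &&
      vaf >= cfg$min_tumor_vaf && deleterious && !in_germ
  }
  records[keep, , drop = FALSE]
}

# Brute-force segment-vs-rest max-t by double loop with mean()/var().
oracle_max_t_segment <- function(d, min_seg) {
  n <- length(d)
  best <- list(i = NA_integer_, j = NA_integer_, t = -Inf)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      w <- j - i
      if (w < min_seg || (n - w) < min_seg) next
      if (i != 0 && i < min_seg) next
      if (j != n && (n - j) < min_seg) next
      seg <- d[(i + 1):j]
      rest <- d[-((i + 1):j)]
      ss <- sum((seg - mean(seg))^2) + sum((rest - mean(rest))^2)
      s2 <- ss / (n - 2)
      if (s2 <= 0) next
      t <- abs(mean(seg) - mean(rest)) / sqrt(s2 * (1 / w + 1 / (n - w)))
      better <- t > best$t * (1 + 1e-12)
      tie <- !better && t >= best$t * (1 - 1e-12)
      narrower <- tie && (w < (best$j - best$i) ||
                            (w == (best$j - best$i) && i < best$i))
      if (better || (tie && narrower)) best <- list(i = i, j = j, t = t)
    }
  }
  if (!is.finite(best$t)) best$t <- NA_real_
  best
}
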