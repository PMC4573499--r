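#' Rank-based quantile normalization of editing levels
#'
#' Maps a per-site vector of editing levels across strains onto standard
#' normal quantiles: value with (average, tie-sharing) rank `r` among `n`
#' non-missing values becomes `qnorm((r - 0.5) / n)`. This is a monotone
#' transform of the ranks; missing values stay missing. The subsequent
#' linear-model scan therefore sees an (approximately) Gaussian phenotype
#' regardless of the raw level distribution.
#'
#' @param levels Numeric vector (one editing site across strains).
#' @return Normalized vector of the same length and names; all-equal
#'   inputs return all-NA with a warning (zero variance carries no
#'   mappable signal).
#' @export
normalize_editing_levels <- function(levels) {
  obs <- !is.na(levels)
  out <- rep(NA_real_, length(levels))
  names(out) <- names(levels)
  n <- sum(obs)
  if (n < 2L || stats::var(levels[obs]) == 0) {
    warning("site skipped: fewer than 2 values or zero variance")
    return(out)
  }
  r <- rank(levels[obs], ties.method = "average")
  out[obs] <- stats::qnorm((r - 0.5) / n)
  out
}

# vectorized simple-regression scan of one phenotype against the columns
# of a permuted-phenotype matrix for a single genotype vector.
# x: genotype (no NA), Y: n x k phenotype matrix (no NA). Returns p (k).
ols_p_matrix <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0 || n < 3L) return(rep(1, ncol(Y)))
  sxy <- as.vector(crossprod(xc, Y))
  syy <- colSums(Y^2) - n * colMeans(Y)^2
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 0)
  r2 <- pmin(r2, 1 - 1e-15)
  tt <- sqrt(r2 * (n - 2) / (1 - r2))
  2 * stats::pt(-tt, df = n - 2)
}

# full OLS summary for one variant (returns beta, se, t, p, n)
ols_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (n < 3L || sxx == 0)
    return(c(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_, n = n))
  beta <- sum(xc * yc) / sxx
  res <- yc - beta * xc
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tt <- if (se > 0) beta / se else 0
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  c(beta = beta, se = se, t = tt, p = p, n = n)
}

# deterministic small integer hash of a string, < 2^30
string_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 1073741789
  as.integer((h + seed * 2654435) %% 1073741789)
}

#' Cis (or genome-wide) linear-model association scan for one site
#'
#' Fits covariate-free simple linear regressions of normalized editing
#' levels on each variant's haploid genotype. A variant is tested only if
#' its minor allele is carried by at least `min_minor` of the strains with
#' an editing measurement and at least `min_obs` complete observations
#' remain; strains with a missing call are dropped for that variant only.
#'
#' @param site_levels Named numeric vector of normalized levels (names =
#'   strain IDs).
#' @param genotypes A `genotype_matrix`.
#' @param gene Gene ID restricting the scan (cis mode); `NULL` scans every
#'   variant (genome mode), where `p < genome_threshold` is flagged
#'   (Bonferroni-style genome-wide significance).
#' @param min_minor Minimum minor-allele strains among measured strains
#'   (default 4).
#' @param min_obs Minimum complete observations (default 8).
#' @param genome_threshold Genome-wide significance threshold
#'   (default 1e-8).
#' @return Data frame (variant_id, beta, se, t, p, n, genome_wide), one
#'   row per tested variant; zero rows when none is testable.
#' @export
cis_association_scan <- function(site_levels, genotypes, gene = NULL,
                                 min_minor = 4L, min_obs = 8L,
                                 genome_threshold = 1e-8) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- if (is.null(gene)) seq_len(nrow(genotypes$variants))
         else which(genotypes$variants$gene_id == gene)
  measured <- names(site_levels)[!is.na(site_levels)]
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    vid <- genotypes$variants$variant_id[idx[k]]
    g <- genotypes$calls[idx[k], measured]
    gg <- g[!is.na(g)]
    if (length(gg) < min_obs) next
    mac <- min(sum(gg == 1L), sum(gg == 0L))
    if (mac < min_minor) next
    fit <- ols_fit(g, site_levels[measured])
    if (is.na(fit[["p"]])) next
    rows[[k]] <- data.frame(variant_id = vid, beta = fit[["beta"]],
                            se = fit[["se"]], t = fit[["t"]], p = fit[["p"]],
                            n = as.integer(fit[["n"]]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(variant_id = character(0), beta = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  out$genome_wide <- is.null(gene) & out$p < genome_threshold
  out
}

#' Permutation empirical p-value for a site's best cis variant
#'
#' Records the minimum nominal p over the site's testable variants, then
#' permutes the strain labels of the phenotype `n_perm` times, rescans the
#' same variant set for each permutation, and places the observed minimum
#' within the null minima using the add-one estimator
#' `(1 + #\{null <= observed\}) / (1 + n_perm)` (never exactly zero; ties
#' counted conservatively).
#'
#' @param site_levels Named numeric vector of normalized levels.
#' @param genotypes A `genotype_matrix`.
#' @param gene Gene ID for the cis scan (`NULL` = all variants).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; the permutation stream is a pure function of
#'   (seed, site id) when `site_id` is given.
#' @param site_id Optional site identifier mixed into the seed.
#' @param exclude_variants Variant IDs removed from the scan (used by the
#'   secondary-QTL scan).
#' @inheritParams cis_association_scan
#' @return List with `p_min`, `p_empirical`, `best_variant`, `n_tested`
#'   and the vector `null_min_p`; `NULL` when no variant is testable.
#' @export
permutation_empirical_p <- function(site_levels, genotypes, gene = NULL,
                                    n_perm = 10000L, seed = 1L,
                                    site_id = NULL, min_minor = 4L,
                                    min_obs = 8L,
                                    exclude_variants = character(0)) {
  assoc <- cis_association_scan(site_levels, genotypes, gene = gene,
                                min_minor = min_minor, min_obs = min_obs)
  assoc <- assoc[!assoc$variant_id %in% exclude_variants, , drop = FALSE]
  if (!nrow(assoc)) return(NULL)
  p_min <- min(assoc$p)
  best <- assoc$variant_id[which.min(assoc$p)]

  measured <- names(site_levels)[!is.na(site_levels)]
  y <- site_levels[measured]
  m <- length(y)
  sd_seed <- if (is.null(site_id)) seed else string_seed(seed, site_id)
  perms <- with_seed(sd_seed, {
    vapply(seq_len(n_perm), function(i) sample.int(m), integer(m))
  })
  Yp <- base::matrix(y[perms], nrow = m, ncol = n_perm)

  vrows <- match(assoc$variant_id, genotypes$variants$variant_id)
  null_min <- rep(1, n_perm)
  for (r in vrows) {
    g <- genotypes$calls[r, measured]
    ok <- !is.na(g)
    pvals <- ols_p_matrix(g[ok], Yp[ok, , drop = FALSE])
    null_min <- pmin(null_min, pvals)
  }
  p_emp <- (1 + sum(null_min <= p_min)) / (1 + n_perm)
  list(p_min = p_min, p_empirical = p_emp, best_variant = best,
       n_tested = nrow(assoc), null_min_p = null_min, assoc = assoc)
}

#' Storey q-values for permutation empirical p-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` at fixed `lambda = 0.5`,
#' clamped to `[1/m, 1]`, then applies the step-up
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. Forcing `pi0 = 1` yields
#' exactly the Benjamini-Hochberg adjusted p-values.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param pi0 Null proportion; estimated when `NULL`.
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalue_fdr <- function(p, pi0 = NULL, lambda = 0.5) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / ((1 - lambda) * m)
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Effect size of an edQTL on the raw editing scale
#'
#' Half the absolute difference in mean (non-normalized) editing level
#' between the two homozygote genotype classes.
#'
#' @param levels_raw Numeric vector of raw editing levels per strain.
#' @param genotype Haploid genotype vector ({0, 1, NA}) per strain.
#' @return Non-negative fraction, or NA when a genotype class has no
#'   measured strain.
#' @export
effect_size <- function(levels_raw, genotype) {
  ok <- !is.na(levels_raw) & !is.na(genotype)
  g <- genotype[ok]; y <- levels_raw[ok]
  if (!any(g == 0L) || !any(g == 1L)) return(NA_real_)
  abs(mean(y[g == 1L]) - mean(y[g == 0L])) / 2
}

# residualize y on genotype g (with intercept); strains with missing g
# become NA. Residuals are exactly orthogonal to g on the complete cases.
regress_out <- function(y, g) {
  out <- rep(NA_real_, length(y))
  names(out) <- names(y)
  ok <- !is.na(y) & !is.na(g)
  if (sum(ok) < 3L || stats::var(g[ok]) == 0) return(out)
  fit <- stats::lm.fit(cbind(1, g[ok]), y[ok])
  out[ok] <- fit$residuals
  out
}

#' Map editing QTLs by permutation-calibrated cis association
#'
#' The top-level fitting function. For every editing site measured in the
#' matrix: normalize levels across strains ([normalize_editing_levels()]),
#' scan cis variants in the site's gene with covariate-free linear models
#' ([cis_association_scan()]), calibrate the minimum p by label
#' permutation ([permutation_empirical_p()]), and control FDR across sites
#' with Storey q-values ([qvalue_fdr()]). For sites whose primary edQTL
#' passes the widest FDR threshold, the primary genotype is regressed out
#' and the scan plus permutations rerun (excluding the primary variant and
#' its perfect proxies, r-squared = 1) to call secondary edQTLs. Effect
#' sizes are half homozygote-mean differences on the raw editing scale;
#' variant-site distances are signed by transcription orientation
#' (negative = upstream).
#'
#' @param editing An `editing_matrix` (raw levels).
#' @param genotypes A `genotype_matrix` on the same strains.
#' @param n_perm Permutations per site (default 10000).
#' @param seed Integer seed for the permutation streams.
#' @param fdr FDR thresholds used for calling (default `c(0.05, 0.10)`).
#' @param secondary Whether to scan for secondary edQTLs (default TRUE).
#' @inheritParams cis_association_scan
#' @return An object of class `edqtl`: list with `table` (one row per
#'   site/rank: site_id, variant_id, rank, beta, n, p_min, p_empirical, q,
#'   significant at each threshold, effect_size, distance), `n_perm`,
#'   `fdr`, `seed` and `call`.
#' @seealso [summary.edqtl()], [plot.edqtl()], [shared_site_association()]
#' @export
edqtl_map <- function(editing, genotypes, n_perm = 10000L, seed = 1L,
                      fdr = c(0.05, 0.10), min_minor = 4L, min_obs = 8L,
                      secondary = TRUE) {
  stopifnot(inherits(editing, "editing_matrix"),
            inherits(genotypes, "genotype_matrix"))
  common <- intersect(editing$strains, genotypes$strains)
  if (length(common) < min_obs) stop("fewer than min_obs shared strains")
  sites <- editing$sites
  rows <- list()
  sec_candidates <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    raw <- editing$level[sid, common]
    if (sum(!is.na(raw)) < 2L || isTRUE(stats::var(raw, na.rm = TRUE) == 0)) next
    y <- normalize_editing_levels(raw)
    perm <- permutation_empirical_p(y, genotypes, gene = sites$gene_id[i],
                                    n_perm = n_perm, seed = seed,
                                    site_id = sid, min_minor = min_minor,
                                    min_obs = min_obs)
    if (is.null(perm)) next
    vrow <- match(perm$best_variant, genotypes$variants$variant_id)
    g <- genotypes$calls[vrow, common]
    es <- effect_size(raw, g)
    beta <- perm$assoc$beta[perm$assoc$variant_id == perm$best_variant]
    dist <- signed_distance(genotypes$variants$pos[vrow], sites$pos[i],
                            sites$strand[i])
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sid, variant_id = perm$best_variant, rank = "primary",
      beta = beta, n = as.integer(perm$assoc$n[perm$assoc$variant_id == perm$best_variant]),
      p_min = perm$p_min, p_empirical = perm$p_empirical,
      effect_size = es, distance = dist, stringsAsFactors = FALSE)
    sec_candidates[[sid]] <- list(i = i, y = y, raw = raw,
                                  primary = perm$best_variant)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no site had a testable variant")
  tab$q <- qvalue_fdr(tab$p_empirical)
  for (a in fdr) tab[[sprintf("sig_fdr%02d", round(100 * a))]] <- tab$q < a

  if (secondary) {
    sec_rows <- list()
    call_thresh <- max(fdr)
    called <- tab$site_id[tab$q < call_thresh]
    for (sid in called) {
      info <- sec_candidates[[sid]]
      i <- info$i
      vrow <- match(info$primary, genotypes$variants$variant_id)
      gprim <- genotypes$calls[vrow, common]
      resid <- regress_out(info$y, gprim)
      if (all(is.na(resid))) next
      # exclude the primary variant and perfect proxies (r^2 = 1)
      gene_idx <- which(genotypes$variants$gene_id == sites$gene_id[i])
      proxies <- genotypes$variants$variant_id[gene_idx][vapply(
        gene_idx, function(k) {
          r2 <- ld_r2(genotypes$calls[k, common], gprim)
          !is.na(r2) && r2 >= 1 - 1e-12
        }, logical(1))]
      perm <- permutation_empirical_p(resid, genotypes,
                                      gene = sites$gene_id[i],
                                      n_perm = n_perm, seed = seed,
                                      site_id = paste0(sid, ":secondary"),
                                      min_minor = min_minor, min_obs = min_obs,
                                      exclude_variants = unique(c(info$primary, proxies)))
      if (is.null(perm)) next
      vrow2 <- match(perm$best_variant, genotypes$variants$variant_id)
      g2 <- genotypes$calls[vrow2, common]
      sec_rows[[length(sec_rows) + 1L]] <- data.frame(
        site_id = sid, variant_id = perm$best_variant, rank = "secondary",
        beta = perm$assoc$beta[perm$assoc$variant_id == perm$best_variant],
        n = as.integer(perm$assoc$n[perm$assoc$variant_id == perm$best_variant]),
        p_min = perm$p_min, p_empirical = perm$p_empirical,
        effect_size = effect_size(info$raw, g2),
        distance = signed_distance(genotypes$variants$pos[vrow2],
                                   sites$pos[i], sites$strand[i]),
        stringsAsFactors = FALSE)
    }
    if (length(sec_rows)) {
      sec <- do.call(rbind, sec_rows)
      sec$q <- qvalue_fdr(sec$p_empirical)
      for (a in fdr) sec[[sprintf("sig_fdr%02d", round(100 * a))]] <- sec$q < a
      tab <- rbind(tab, sec)
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = as.integer(n_perm), fdr = fdr,
                 seed = as.integer(seed), n_sites = nrow(sites),
                 call = match.call()),
            class = "edqtl")
}

# signed genomic distance in transcription orientation:
# positive = variant transcriptionally downstream of the site
signed_distance <- function(variant_pos, site_pos, strand) {
  d <- variant_pos - site_pos
  ifelse(strand == "-", -d, d)
}

#' @export
print.edqtl <- function(x, ...) {
  tab <- x$table
  cat(sprintf("edQTL scan: %d sites scanned, %d permutations per site (seed %d)\n",
              x$n_sites, x$n_perm, x$seed))
  for (a in x$fdr) {
    col <- sprintf("sig_fdr%02d", round(100 * a))
    cat(sprintf("  FDR %d%%: %d primary, %d secondary edQTLs\n", round(100 * a),
                sum(tab[[col]] & tab$rank == "primary"),
                sum(tab[[col]] & tab$rank == "secondary")))
  }
  invisible(x)
}

#' Summarize an edQTL scan
#'
#' @param object An `edqtl` fit.
#' @param ... Unused.
#' @return The underlying results table, invisibly, after printing counts
#'   and the effect-size distribution of significant calls.
#' @export
summary.edqtl <- function(object, ...) {
  print(object)
  tab <- object$table
  col <- sprintf("sig_fdr%02d", round(100 * max(object$fdr)))
  sig <- tab[tab[[col]], , drop = FALSE]
  if (nrow(sig)) {
    cat("Effect sizes of significant edQTLs (raw editing-level units):\n")
    print(summary(sig$effect_size))
  }
  invisible(tab)
}

#' @export
coef.edqtl <- function(object, ...) {
  stats::setNames(object$table$beta,
                  paste(object$table$site_id, object$table$variant_id, sep = ":"))
}

#' Diagnostic plots for an edQTL scan
#'
#' Left: histogram of permutation empirical p-values (flat under the
#' null, spiked near zero in the presence of real edQTLs). Right: effect
#' size against signed distance to the editing site for significant calls.
#'
#' @param x An `edqtl` fit.
#' @param ... Passed to `hist`.
#' @export
plot.edqtl <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(tab$p_empirical[tab$rank == "primary"], breaks = 20,
                 main = "Empirical p-values", xlab = "p", ...)
  col <- sprintf("sig_fdr%02d", round(100 * max(x$fdr)))
  sig <- tab[tab[[col]], , drop = FALSE]
  if (nrow(sig)) {
    graphics::plot(sig$distance, sig$effect_size,
                   xlab = "signed distance to site (bp)",
                   ylab = "effect size", main = "Significant edQTLs")
  }
  invisible(x)
}

#' Associations of called edQTLs with other editing sites in the same gene
#'
#' For each called edQTL, tests its variant against every other editing
#' site in the same gene (nominal linear-model p), annotating each pair by
#' the genomic distance between the two editing sites, binned at <1 kb,
#' 1-10 kb and 10-50 kb.
#'
#' @param fit An `edqtl` fit (or its `table`).
#' @param editing The `editing_matrix` used for mapping.
#' @param genotypes The `genotype_matrix` used for mapping.
#' @param bins Distance bin edges in bp (default `c(1e3, 1e4, 5e4)`).
#' @return Data frame (variant_id, site_id, other_site, p, distance,
#'   distance_bin).
#' @export
shared_site_association <- function(fit, editing, genotypes,
                                    bins = c(1e3, 1e4, 5e4)) {
  tab <- if (inherits(fit, "edqtl")) fit$table else fit
  common <- intersect(editing$strains, genotypes$strains)
  sites <- editing$sites
  out <- list()
  for (r in seq_len(nrow(tab))) {
    vid <- tab$variant_id[r]
    vrow <- match(vid, genotypes$variants$variant_id)
    gene <- genotypes$variants$gene_id[vrow]
    g <- genotypes$calls[vrow, common]
    origin <- sites[sites$site_id == tab$site_id[r], , drop = FALSE]
    others <- sites[sites$gene_id == gene & sites$site_id != tab$site_id[r], ,
                    drop = FALSE]
    for (k in seq_len(nrow(others))) {
      y <- normalize_editing_levels(editing$level[others$site_id[k], common])
      f <- ols_fit(g, y)
      d <- abs(others$pos[k] - origin$pos[1])
      bin <- if (d < bins[1]) sprintf("<%g kb", bins[1] / 1e3)
             else if (d < bins[2]) sprintf("%g-%g kb", bins[1] / 1e3, bins[2] / 1e3)
             else if (d < bins[3]) sprintf("%g-%g kb", bins[2] / 1e3, bins[3] / 1e3)
             else sprintf(">=%g kb", bins[3] / 1e3)
      out[[length(out) + 1L]] <- data.frame(
        variant_id = vid, site_id = tab$site_id[r],
        other_site = others$site_id[k], p = f[["p"]], distance = d,
        distance_bin = bin, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(variant_id = character(0), site_id = character(0),
                      other_site = character(0), p = numeric(0),
                      distance = numeric(0), distance_bin = character(0)))
  do.call(rbind, out)
}
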