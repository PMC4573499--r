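#' Classify an edQTL variant relative to the edited duplex
#'
#' A variant is `within_duplex` when its genomic position falls inside the
#' stem's editing-side interval or the ECS interval of the site's accepted
#' prediction, `distal` otherwise, and `unresolved` when the site has no
#' ECS prediction (such edQTLs are excluded from structural analyses).
#'
#' @param variant One-row data frame or list with chrom, pos.
#' @param prediction The site's `ecs_prediction`, or `NULL`.
#' @return One of "within_duplex", "distal", "unresolved".
#' @export
classify_variant_location <- function(variant, prediction) {
  if (is.null(prediction)) return("unresolved")
  if (!identical(variant$chrom, prediction$site$chrom)) return("distal")
  inside <- function(iv) variant$pos >= iv[1] && variant$pos <= iv[2]
  if (inside(prediction$edit_interval) || inside(prediction$ecs_interval))
    "within_duplex" else "distal"
}

#' Linkage disequilibrium r-squared between two haploid genotype vectors
#'
#' Squared Pearson correlation of haploid-coded calls over the strains
#' where both variants are called.
#'
#' @param a,b Integer vectors in {0, 1, NA}, same strains.
#' @return Fraction in \[0, 1\], or NA when either vector is constant (or
#'   fewer than 2 shared calls remain).
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Select control variants for structural comparisons
#'
#' Duplex mode: variants located inside predicted edited duplexes (edit
#' side or ECS) that are not edQTLs and whose maximum r-squared against
#' any edQTL in the same gene is at most `max_r2` (the boundary is
#' inclusive: r-squared exactly 0.05 passes). Distal-matched mode:
#' variants in the same genes as distal edQTLs, outside the primary
#' duplex, with the same LD clearance, randomly sampled down to
#' `n_sample` with the given seed.
#'
#' @param genotypes A `genotype_matrix`.
#' @param edqtl_variants Character vector of edQTL variant IDs.
#' @param predictions Named list of `ecs_prediction` objects (names =
#'   site IDs); used for duplex membership.
#' @param mode "duplex" or "distal-matched".
#' @param distal_genes Genes of distal edQTLs (distal-matched mode).
#' @param max_r2 LD clearance threshold (default 0.05, inclusive).
#' @param n_sample Sample size in distal-matched mode (NULL = all).
#' @param seed Seed for the distal-matched sampling.
#' @return Character vector of selected variant IDs (possibly empty, with
#'   a warning).
#' @export
select_control_variants <- function(genotypes, edqtl_variants, predictions,
                                    mode = c("duplex", "distal-matched"),
                                    distal_genes = NULL, max_r2 = 0.05,
                                    n_sample = NULL, seed = 1L) {
  mode <- match.arg(mode)
  vars <- genotypes$variants
  in_duplex <- rep(FALSE, nrow(vars))
  for (p in predictions) {
    if (is.null(p)) next
    hit <- vars$chrom == p$site$chrom &
      ((vars$pos >= p$edit_interval[1] & vars$pos <= p$edit_interval[2]) |
         (vars$pos >= p$ecs_interval[1] & vars$pos <= p$ecs_interval[2]))
    in_duplex <- in_duplex | hit
  }
  if (mode == "duplex") {
    cand <- which(in_duplex & !vars$variant_id %in% edqtl_variants)
  } else {
    if (is.null(distal_genes)) stop("distal_genes required in distal-matched mode")
    cand <- which(vars$gene_id %in% distal_genes & !in_duplex &
                    !vars$variant_id %in% edqtl_variants)
  }
  qtl_rows <- match(intersect(edqtl_variants, vars$variant_id), vars$variant_id)
  keep <- vapply(cand, function(k) {
    same_gene <- qtl_rows[vars$gene_id[qtl_rows] == vars$gene_id[k]]
    if (!length(same_gene)) return(TRUE)
    r2 <- vapply(same_gene, function(q)
      ld_r2(genotypes$calls[k, ], genotypes$calls[q, ]), numeric(1))
    all(is.na(r2) | r2 <= max_r2)
  }, logical(1))
  out <- vars$variant_id[cand[keep]]
  if (mode == "distal-matched" && !is.null(n_sample) && length(out) > n_sample)
    out <- with_seed(seed, sample(out, n_sample))
  if (!length(out)) warning("no control variants survive the filters")
  out
}

# transcript-oriented subsequence of a duplex interval, with a local
# substitution applied at `sub_pos` (genomic) when inside
oriented_segment <- function(contig, iv, strand, sub_pos = NULL, sub_base = NULL) {
  w <- oriented_window(contig, iv[1], iv[2], strand)
  seqs <- w$seq
  local <- NA_integer_
  if (!is.null(sub_pos) && sub_pos >= w$start && sub_pos <= w$end) {
    local <- w$to_local(sub_pos)
    base <- if (strand == "-") unname(dna_complement[[toupper(sub_base)]])
            else toupper(sub_base)
    substring(seqs, local, local) <- base
  }
  list(seq = seqs, sub_local = local)
}

#' Compare the two alleles of a within-duplex variant structurally
#'
#' Builds the allele-specific duplex construct (editing-side stem strand +
#' 100-nt adenosine linker + ECS, in transcript orientation) for both
#' alleles, folds each with the built-in engine, and reports
#' `delta_g = G(high) - G(low)`: the free energy of the lower-edited
#' allele subtracted from the higher-edited allele (negative when the
#' higher-editing allele is more stable). The higher-editing allele is
#' the one whose homozygote class has the larger mean raw editing level
#' (ties resolved to the reference allele with a warning). Base-pairing
#' status at the variant and the signed stem position are read from the
#' higher-editing allele's structure. Comparisons with an effect size
#' below `effect_gate` (default 0.025) are flagged `gated = FALSE` so the
#' headline set can be restricted while the full set is retained.
#'
#' @param variant One-row data frame with variant_id, chrom, pos, ref, alt.
#' @param prediction The site's accepted `ecs_prediction`.
#' @param genome Named character vector of contig sequences.
#' @param levels_raw Named numeric vector of raw editing levels at the
#'   site (names = strains).
#' @param genotype Named haploid genotype vector for the variant.
#' @param linker Linker length (default 100 nt).
#' @param effect_gate Effect-size gate for the headline set (default
#'   0.025).
#' @return A list of class `structural_comparison`: variant_id, site_id,
#'   location_class, is_base_paired, delta_g, signed_position,
#'   allele_high, allele_low, effect_size, gated, and the two folded
#'   structures.
#' @export
compare_alleles <- function(variant, prediction, genome, levels_raw,
                            genotype, linker = 100L, effect_gate = 0.025) {
  loc <- classify_variant_location(variant, prediction)
  if (!identical(loc, "within_duplex"))
    stop("variant is not within the edited duplex")
  contig <- genome[[variant$chrom]]
  strand <- prediction$site$strand
  build <- function(base) {
    e <- oriented_segment(contig, prediction$edit_interval, strand,
                          variant$pos, base)
    c_ <- oriented_segment(contig, prediction$ecs_interval, strand,
                           variant$pos, base)
    st <- duplex_fold(e$seq, c_$seq, linker = linker)
    n1 <- nchar(e$seq)
    var_local <- if (!is.na(e$sub_local)) e$sub_local
                 else if (!is.na(c_$sub_local)) n1 + linker + c_$sub_local
                 else NA_integer_
    list(structure = st, var_local = var_local, n_edit = n1)
  }
  ok <- !is.na(levels_raw) & !is.na(genotype)
  m0 <- mean(levels_raw[ok][genotype[ok] == 0L])
  m1 <- mean(levels_raw[ok][genotype[ok] == 1L])
  if (is.nan(m0) || is.nan(m1)) stop("a homozygote class has no measured strain")
  if (m0 == m1) warning("tied class means; reference allele taken as higher-editing")
  high_base <- if (m1 > m0) variant$alt else variant$ref
  low_base <- if (m1 > m0) variant$ref else variant$alt
  hi <- build(high_base)
  lo <- build(low_base)
  if (is.na(hi$var_local))
    stop("internal error: variant does not map into the allele construct")
  delta_g <- hi$structure$energy - lo$structure$energy
  is_paired <- hi$structure$pairs[hi$var_local] > 0L
  es <- effect_size(levels_raw, genotype)
  structure(list(
    variant_id = variant$variant_id, site_id = prediction$site$site_id,
    location_class = loc, is_base_paired = is_paired, delta_g = delta_g,
    signed_position = signed_position(variant, prediction),
    allele_high = high_base, allele_low = low_base,
    effect_size = es, gated = !is.na(es) && es >= effect_gate,
    structure_high = hi$structure, structure_low = lo$structure),
    class = "structural_comparison")
}

#' @export
print.structural_comparison <- function(x, ...) {
  cat(sprintf(
    "Allelic comparison %s @ %s: high allele %s, delta G = %.2f kcal/mol, %s, position %+d, effect %.3f%s\n",
    x$variant_id, x$site_id, x$allele_high, x$delta_g,
    if (x$is_base_paired) "base-paired" else "unpaired",
    x$signed_position, x$effect_size, if (x$gated) "" else " (below gate)"))
  invisible(x)
}

#' Signed stem position of a within-duplex variant
#'
#' Base-pair distance along the stem from the editing site (position 0):
#' editing-side positions transcriptionally downstream of the site are
#' positive, upstream negative; an ECS position inherits the sign and
#' magnitude of its paired editing-side position. Variants falling in a
#' bulge take the index of the nearest stem pair.
#'
#' @param variant One-row data frame with chrom, pos.
#' @param prediction The site's accepted `ecs_prediction`.
#' @return Signed integer stem position.
#' @export
signed_position <- function(variant, prediction) {
  stem <- prediction$stem
  struct <- prediction$structure
  # local coordinate of the variant inside the folded construct/window
  local <- local_position_of(variant$pos, prediction)
  if (is.na(local)) stop("variant does not map into the folded region")
  edit_pos <- if (stem$anchor_side == "left") stem$left_positions
              else rev(stem$right_positions)
  # index along the stem (1 = outermost pair in 5'->3' edit-side order)
  i0 <- which.min(abs(sort(edit_pos) - stem$anchor))
  edit_sorted <- sort(edit_pos)
  on_edit <- local >= min(edit_sorted) - 0L & local <= max(edit_sorted) &
    in_interval(local, if (stem$anchor_side == "left") stem$left else stem$right)
  if (on_edit) {
    iv <- which.min(abs(edit_sorted - local))
    return(iv - i0)
  }
  # ECS side: use the paired edit-side base (nearest stem pair for bulges)
  other_sorted <- sort(if (stem$anchor_side == "left") stem$right_positions
                       else stem$left_positions)
  nearest <- other_sorted[which.min(abs(other_sorted - local))]
  partner <- struct$pairs[nearest]
  iv <- which.min(abs(edit_sorted - partner))
  iv - i0
}

in_interval <- function(x, iv) x >= iv[1] & x <= iv[2]

# map a genomic position into the local coordinates of a prediction's
# folded sequence (proximal: the window; distal: site flank or candidate)
local_position_of <- function(pos, prediction) {
  strand <- prediction$site$strand
  if (prediction$approach == "proximal") {
    w <- prediction$window
    if (pos < w[1] || pos > w[2]) return(NA_integer_)
    if (strand == "-") w[2] - pos + 1L else pos - w[1] + 1L
  } else {
    # distal: construct = [site +/- flank] + linker + [buffered candidate];
    # affine maps derived from the stored genomic stem intervals
    ei <- prediction$edit_interval
    stem <- prediction$stem
    el <- if (stem$anchor_side == "left") stem$left else stem$right
    cl <- if (stem$anchor_side == "left") stem$right else stem$left
    if (in_interval(pos, ei)) {
      if (strand == "-") el[1] + (ei[2] - pos) else el[1] + (pos - ei[1])
    } else if (in_interval(pos, prediction$ecs_interval)) {
      ci <- prediction$ecs_interval
      if (strand == "-") cl[1] + (ci[2] - pos) else cl[1] + (pos - ci[1])
    } else NA_integer_
  }
}

#' Fisher test for base-pairing enrichment in edQTLs versus controls
#'
#' Two-sided Fisher's exact test on the 2x2 table of group (edQTL /
#' control) by base-paired status.
#'
#' @param qtl_paired Logical vector: base-paired status of edQTL variants.
#' @param control_paired Logical vector for control variants.
#' @return List with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
pairing_enrichment_test <- function(qtl_paired, control_paired) {
  tab <- rbind(qtl = c(paired = sum(qtl_paired), unpaired = sum(!qtl_paired)),
               control = c(sum(control_paired), sum(!control_paired)))
  if (any(rowSums(tab) == 0L)) return(list(odds_ratio = NA_real_,
                                           p = NA_real_, table = tab))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' One-sided Mann-Whitney test on allelic free-energy differences
#'
#' Tests whether the edQTL group's `delta_g` values (free energy of the
#' lower-edited allele subtracted from the higher-edited allele) are
#' stochastically smaller (more negative, i.e. higher-editing allele more
#' stable) than the control group's. Exact for small samples without
#' ties; normal approximation with tie correction otherwise.
#'
#' @param qtl_dg Numeric vector of edQTL delta-G values.
#' @param control_dg Numeric vector for control variants.
#' @return List with `p`, `U` (statistic for the edQTL group) and the
#'   alternative used.
#' @export
delta_g_test <- function(qtl_dg, control_dg) {
  stopifnot(length(qtl_dg) > 0L, length(control_dg) > 0L)
  if (length(unique(c(qtl_dg, control_dg))) == 1L)
    return(list(p = 1, U = length(qtl_dg) * length(control_dg) / 2,
                alternative = "less"))
  wt <- suppressWarnings(stats::wilcox.test(qtl_dg, control_dg,
                                            alternative = "less"))
  list(p = wt$p.value, U = unname(wt$statistic), alternative = "less")
}

#' Find secondary dsRNA stems around a distal variant
#'
#' Folds the transcript-strand region within `window` bp of the variant
#' and returns every maximal stem meeting the length/bulge cutoffs whose
#' paired strands contain the variant position.
#'
#' @param variant One-row data frame with variant_id, chrom, pos.
#' @param genome Named character vector of contig sequences.
#' @param window Half-window (default 200 bp).
#' @param min_pairs,max_bulge Stem cutoffs (defaults 20 bp / 8 nt).
#' @param strand Transcript strand of the gene (default "+").
#' @param site_pos Optional position of the associated editing site, for
#'   the recorded distance.
#' @param fold_fun Folding engine (default built-in [fold_mfe()]).
#' @return List of `secondary_stem` objects (possibly empty), each with
#'   `variant_id`, `stem` (genomic-interval annotated) and
#'   `distance_to_editing_site`.
#' @export
find_distal_stems <- function(variant, genome, window = 200L,
                              min_pairs = 20L, max_bulge = 8L,
                              strand = "+", site_pos = NA_integer_,
                              fold_fun = fold_mfe) {
  contig <- genome[[variant$chrom]]
  if (is.null(contig)) stop("contig not found: ", variant$chrom)
  w <- oriented_window(contig, variant$pos - window, variant$pos + window,
                       strand)
  struct <- fold_fun(w$seq)
  vlocal <- w$to_local(variant$pos)
  stems <- enumerate_stems(struct, min_pairs = min_pairs,
                           max_bulge = max_bulge)
  out <- list()
  for (st in stems) {
    if (!(in_interval(vlocal, st$left) || in_interval(vlocal, st$right))) next
    gstart <- sort(c(w$to_genomic(st$left[1]), w$to_genomic(st$right[2])))
    out[[length(out) + 1L]] <- structure(list(
      variant_id = variant$variant_id, stem = st,
      genomic_span = gstart,
      distance_to_editing_site =
        if (is.na(site_pos)) NA_real_ else abs(variant$pos - site_pos)),
      class = "secondary_stem")
  }
  out
}

#' Count editing sites in windows centred on variants
#'
#' @param variants Data frame with chrom, pos (one row per variant).
#' @param sites Data frame with chrom, pos (editing sites).
#' @param windows Even window widths in bp (sites within window/2 of the
#'   variant, same chromosome, are counted).
#' @return Matrix (variants x windows) of counts.
#' @export
editing_site_window_frequency <- function(variants, sites,
                                          windows = c(200L, 1000L, 2000L)) {
  if (any(windows %% 2L != 0L)) stop("windows must be even widths (centred)")
  out <- matrix(0L, nrow = nrow(variants), ncol = length(windows),
                dimnames = list(variants$variant_id,
                                paste0("w", windows)))
  for (i in seq_len(nrow(variants))) {
    same <- sites$chrom == variants$chrom[i]
    d <- abs(sites$pos[same] - variants$pos[i])
    out[i, ] <- vapply(windows, function(wd) sum(d <= wd / 2), integer(1))
  }
  out
}
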