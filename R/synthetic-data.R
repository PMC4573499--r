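#' Simulation configuration for synthetic editing datasets
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' emulate the statistical structure of a DGRP-style mmPCR-seq study: 131
#' homozygous inbred strains measured in 2 biological replicates, deep
#' targeted coverage, biallelic cis variants, and per-site editing levels
#' in \[0, 1\] with additive genotype effects.
#'
#' Effects use the half-difference convention: a planted effect `e` shifts
#' the editing level of the alternate homozygote by `2 e`, so the standard
#' effect-size estimator (half the difference between homozygote class
#' means) recovers `e` directly.
#'
#' @param n_strains Number of inbred strains (>= 8; default 131).
#' @param n_sites Number of editing sites, one per simulated gene locus.
#' @param n_variants_per_gene Cis variants per gene (>= 1).
#' @param maf_range Range of minor-allele sampling frequencies, in (0, 0.5].
#' @param baseline_editing_range Range of per-site baseline editing levels.
#' @param effect_sizes Planted per-site effects (editing-level units,
#'   half-difference convention), recycled across sites; 0 plants no effect.
#' @param noise_sd Gaussian noise s.d. on the editing-level scale.
#' @param coverage_mean Mean read coverage per site/strain/replicate (>= 1).
#' @param n_replicates Biological replicates per strain (default 2).
#' @param stem_length_range Range of planted duplex stem lengths (bp).
#' @param max_planted_bulge Largest planted bulge size (nt; 0 disables
#'   bulges).
#' @param ecs_offset_range Range of hairpin loop lengths between the edit
#'   side and the ECS (nt, >= 3).
#' @param flank_length Length of random flanking sequence on each side.
#' @param disrupt_fraction Fraction of planted causal variants placed
#'   inside the planted stem (the rest are distal, in the flanks).
#' @param seed Integer seed; all generation is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 131L, n_sites = 20L,
                       n_variants_per_gene = 8L,
                       maf_range = c(0.1, 0.5),
                       baseline_editing_range = c(0.2, 0.8),
                       effect_sizes = 0.1, noise_sd = 0.05,
                       coverage_mean = 500, n_replicates = 2L,
                       stem_length_range = c(22L, 32L),
                       max_planted_bulge = 3L,
                       ecs_offset_range = c(10L, 60L),
                       flank_length = 120L,
                       disrupt_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains), n_sites = as.integer(n_sites),
              n_variants_per_gene = as.integer(n_variants_per_gene),
              maf_range = as.numeric(maf_range),
              baseline_editing_range = as.numeric(baseline_editing_range),
              effect_sizes = as.numeric(effect_sizes),
              noise_sd = as.numeric(noise_sd),
              coverage_mean = as.numeric(coverage_mean),
              n_replicates = as.integer(n_replicates),
              stem_length_range = as.integer(stem_length_range),
              max_planted_bulge = as.integer(max_planted_bulge),
              ecs_offset_range = as.integer(ecs_offset_range),
              flank_length = as.integer(flank_length),
              disrupt_fraction = as.numeric(disrupt_fraction),
              seed = as.integer(seed))
  if (cfg$n_strains < 8L) stop("n_strains must be >= 8")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$coverage_mean < 1) stop("coverage_mean must be >= 1")
  if (any(cfg$baseline_editing_range < 0) || any(cfg$baseline_editing_range > 1))
    stop("baseline_editing_range must lie within [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dna_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param x Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(rev(unname(dna_complement[chars])), collapse = "")
}

# TRUE if some k-mer of `a` has its reverse complement inside `b`
has_rc_kmer <- function(a, b, k = 12L) {
  if (nchar(a) < k) return(FALSE)
  rc <- reverse_complement(a)
  kmers <- substring(rc, seq_len(nchar(rc) - k + 1L),
                     seq_len(nchar(rc) - k + 1L) + k - 1L)
  any(vapply(unique(kmers), function(km) grepl(km, b, fixed = TRUE), logical(1)))
}

# random flank that cannot seed a competing helix against `context`
random_flank <- function(n, context, k = 12L, max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    f <- random_dna(n)
    if (!has_rc_kmer(f, paste0(context, f), k)) return(f)
  }
  f
}

#' Generate a haploid-coded genotype matrix for an inbred-strain panel
#'
#' Each variant's alternate-allele sampling frequency is drawn uniformly
#' from `maf_range` and strain calls are independent Bernoulli draws, so
#' realized frequencies fluctuate binomially around the drawn value.
#' Inbred lines are effectively homozygous, hence the haploid {0, 1}
#' coding.
#'
#' @param config A [sim_config()].
#' @param n_variants Number of variants; defaults to
#'   `n_sites * n_variants_per_gene`.
#' @return A `genotype_matrix`: list with `variants` (data frame:
#'   variant_id, chrom, pos, gene_id, ref, alt) and `calls` (variants x
#'   strains integer matrix in {0, 1, NA}).
#' @export
generate_genotypes <- function(config, n_variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_variants))
    n_variants <- config$n_sites * config$n_variants_per_gene
  with_seed(config$seed + 101L, {
    maf <- stats::runif(n_variants, config$maf_range[1], config$maf_range[2])
    calls <- matrix(stats::rbinom(n_variants * config$n_strains, 1L,
                                  rep(maf, config$n_strains)),
                    nrow = n_variants, ncol = config$n_strains)
    gene <- rep(sprintf("g%03d", seq_len(config$n_sites)),
                each = config$n_variants_per_gene)[seq_len(n_variants)]
    variants <- data.frame(
      variant_id = sprintf("v%05d", seq_len(n_variants)),
      chrom = gene,
      pos = 50L * (seq_len(n_variants) - 1L) %% config$n_variants_per_gene + 1L,
      gene_id = gene, ref = "A", alt = "G",
      stringsAsFactors = FALSE)
    genotype_matrix(variants, calls,
                    strains = sprintf("strain%03d", seq_len(config$n_strains)))
  })
}

#' Construct a genotype matrix object
#'
#' @param variants Data frame with columns variant_id, chrom, pos, gene_id,
#'   ref, alt.
#' @param calls Integer matrix (variants x strains) in {0, 1, NA}.
#' @param strains Character vector of strain IDs.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, calls, strains) {
  stopifnot(nrow(variants) == nrow(calls), length(strains) == ncol(calls))
  if (any(!is.na(calls) & !calls %in% c(0L, 1L)))
    stop("calls must be haploid-coded {0, 1, NA}")
  rownames(calls) <- variants$variant_id
  colnames(calls) <- strains
  structure(list(variants = variants, calls = calls, strains = strains),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d biallelic variants x %d strains (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Generate a locus containing a planted editing duplex
#'
#' Builds a hairpin locus: random left flank, editing-side stem strand
#' (with the edited A forced at mid-stem), a loop of `ecs_offset` nt, the
#' reverse-complement ECS strand (with optional planted bulges), and a
#' random right flank. The loop and 10-nt buffers flanking the stem are
#' poly-A (A cannot pair with A), pinning the planted helix ends, and
#' flanks are rejection-sampled against reverse-complement 8-mers of the
#' core. For stems of 12+ bp the assembled locus is additionally verified
#' by round-trip: it must fold (under the built-in MFE engine) into a
#' hairpin whose extracted stem matches the recorded truth intervals
#' within 2 nt; flanks are resampled (deterministically from the seed)
#' until this holds.
#'
#' @param spec List with `stem_len` (>= 5), optional `bulges` (data frame
#'   with columns after_pair, size, side in {"ecs", "edit"}), `ecs_offset`
#'   (loop length, >= 3), optional `intronic` flag and `flank` lengths
#'   (length-2 integer).
#' @param seed Integer seed.
#' @param verify Round-trip verification switch (default TRUE).
#' @return List with `sequence` (DNA string), `site_pos` (1-based position
#'   of the edited A), `stem5` and `stem3` (1-based inclusive truth
#'   intervals of the edit-side and ECS strands), `ecs` (= `stem3`),
#'   `loop` interval and the input `spec`.
#' @export
generate_duplex_locus <- function(spec, seed = 1L, verify = TRUE) {
  stem_len <- as.integer(spec$stem_len)
  if (is.null(stem_len) || stem_len < 5L) stop("stem_len must be >= 5")
  ecs_offset <- as.integer(if (is.null(spec$ecs_offset)) 40L else spec$ecs_offset)
  if (ecs_offset < 3L) stop("ecs offset too small to accommodate a hairpin loop")
  flank <- if (is.null(spec$flank)) c(120L, 120L) else as.integer(spec$flank)
  bulges <- spec$bulges
  if (is.null(bulges)) bulges <- data.frame(after_pair = integer(0),
                                            size = integer(0),
                                            side = character(0))
  if (any(bulges$after_pair < 1L | bulges$after_pair >= stem_len))
    stop("bulge after_pair must be inside the stem")

  build <- function(sub_seed) with_seed(sub_seed, {
    site_pair <- ceiling(stem_len / 2)
    pair_bases <- sample(c("A", "C", "G", "T"), stem_len, replace = TRUE)
    pair_bases[site_pair] <- "A"
    # edit-side strand 5' -> 3', inserting edit-side bulges between pairs
    edit_parts <- character(0); site_pos_local <- NA_integer_
    for (k in seq_len(stem_len)) {
      edit_parts <- c(edit_parts, pair_bases[k])
      if (k == site_pair) site_pos_local <- sum(nchar(edit_parts))
      b <- bulges[bulges$after_pair == k & bulges$side == "edit", , drop = FALSE]
      if (nrow(b)) edit_parts <- c(edit_parts, random_dna(sum(b$size)))
    }
    edit_strand <- paste(edit_parts, collapse = "")
    # ECS strand: complements in reverse pair order, with ECS-side bulges
    ecs_parts <- character(0)
    for (k in rev(seq_len(stem_len))) {
      ecs_parts <- c(ecs_parts, unname(dna_complement[pair_bases[k]]))
      b <- bulges[bulges$after_pair == k - 1L & bulges$side == "ecs", , drop = FALSE]
      if (nrow(b) && k > 1L) ecs_parts <- c(ecs_parts, random_dna(sum(b$size)))
    }
    ecs_strand <- paste(ecs_parts, collapse = "")
    # poly-A loop and stem-end buffers pin the planted helix boundaries
    loop <- strrep("A", ecs_offset)
    buf <- strrep("A", 10L)
    core <- paste0(edit_strand, loop, ecs_strand)
    left <- paste0(random_flank(max(0L, flank[1] - 10L), core, k = 8L), buf)
    right <- paste0(buf, random_flank(max(0L, flank[2] - 10L),
                                      paste0(left, core), k = 8L))
    seqs <- paste0(left, core, right)
    stem5_start <- nchar(left) + 1L
    stem5_end <- nchar(left) + nchar(edit_strand)
    stem3_start <- stem5_end + nchar(loop) + 1L
    stem3_end <- stem3_start + nchar(ecs_strand) - 1L
    list(sequence = seqs,
         site_pos = nchar(left) + site_pos_local,
         stem5 = c(stem5_start, stem5_end),
         stem3 = c(stem3_start, stem3_end),
         ecs = c(stem3_start, stem3_end),
         loop = c(stem5_end + 1L, stem3_start - 1L),
         spec = list(stem_len = stem_len, bulges = bulges,
                     ecs_offset = ecs_offset,
                     intronic = isTRUE(spec$intronic)))
  })

  recovers_truth <- function(loc) {
    st <- extract_stem_at(fold_mfe(loc$sequence), loc$site_pos,
                          min_pairs = 1L, max_bulge = 8L)
    if (is.null(st)) return(FALSE)
    slack <- 2L
    need_pairs <- stem_len - (if (nrow(bulges)) 1L else 0L)
    ok <- st$n_pairs >= need_pairs &&
      all(abs(st$left - loc$stem5) <= slack) &&
      all(abs(st$right - loc$ecs) <= slack)
    if (ok && nrow(bulges)) ok <- st$max_bulge <= max(bulges$size) + 1L
    ok
  }

  if (!verify || stem_len < 12L) return(build(seed))
  for (try in 0:39) {
    loc <- build(seed + 100003L * try)
    if (recovers_truth(loc)) return(loc)
  }
  warning("planted duplex could not be verified by round-trip after 40 draws")
  loc
}

#' Generate editing levels with planted additive genotype effects
#'
#' `level(strain, site) = clamp(baseline + 2 * effect * g + N(0, noise_sd),
#' 0, 1)` with `g` the strain's haploid genotype at the site's causal
#' variant, so homozygote class means differ by `2 * effect` and the
#' half-difference effect-size estimator recovers `effect`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param truth List with `qtl_assignments`, a data frame (variant_id,
#'   site_id, effect); sites absent from it get no genetic effect.
#' @param config A [sim_config()]; `baseline` may be supplied per site via
#'   `truth$baselines` (named vector), otherwise drawn from
#'   `baseline_editing_range`.
#' @param site_ids Site identifiers; default `s001 ... s<n_sites>`.
#' @return An `editing_matrix` (see [editing_matrix()]) with no missing
#'   values.
#' @export
generate_editing_levels <- function(genotypes, truth, config,
                                    site_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(site_ids)) site_ids <- sprintf("s%03d", seq_len(config$n_sites))
  qa <- truth$qtl_assignments
  if (!is.null(qa) && nrow(qa) &&
      !all(qa$variant_id %in% genotypes$variants$variant_id))
    stop("truth references variants absent from the genotype matrix")
  with_seed(config$seed + 202L, {
    baselines <- truth$baselines
    if (is.null(baselines)) {
      baselines <- stats::runif(length(site_ids),
                                config$baseline_editing_range[1],
                                config$baseline_editing_range[2])
      names(baselines) <- site_ids
    }
    n <- config$n_strains
    lev <- matrix(NA_real_, nrow = length(site_ids), ncol = n,
                  dimnames = list(site_ids, genotypes$strains))
    for (s in site_ids) {
      mu <- rep(baselines[[s]], n)
      if (!is.null(qa) && nrow(qa)) {
        row <- qa[qa$site_id == s, , drop = FALSE]
        for (r in seq_len(nrow(row))) {
          g <- genotypes$calls[row$variant_id[r], ]
          g[is.na(g)] <- 0L
          mu <- mu + 2 * row$effect[r] * g
        }
      }
      lev[s, ] <- pmin(1, pmax(0, mu + stats::rnorm(n, 0, config$noise_sd)))
    }
    sites <- data.frame(chrom = sub("s", "g", site_ids), pos = 1L,
                        strand = "+", gene_id = sub("s", "g", site_ids),
                        site_id = site_ids, stringsAsFactors = FALSE)
    editing_matrix(sites, genotypes$strains, lev)
  })
}

#' Sample per-replicate read counts from editing levels
#'
#' Total counts are Poisson around `coverage_mean`; G counts are
#' `Binomial(total, level)`, independently per replicate, emulating
#' saturating targeted amplicon sequencing.
#'
#' @param levels An `editing_matrix` of true levels in \[0, 1\].
#' @param config A [sim_config()].
#' @return Data frame (site_id, strain, replicate, g_count, total_count).
#' @export
generate_read_counts <- function(levels, config) {
  stopifnot(inherits(levels, "editing_matrix"))
  lv <- levels$level
  if (any(lv < 0 | lv > 1, na.rm = TRUE)) stop("levels must be in [0, 1]")
  with_seed(config$seed + 303L, {
    grid <- expand.grid(site_id = rownames(lv), strain = colnames(lv),
                        replicate = seq_len(config$n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    p <- lv[cbind(grid$site_id, grid$strain)]
    total <- stats::rpois(nrow(grid), config$coverage_mean)
    g <- ifelse(is.na(p), NA_integer_, stats::rbinom(nrow(grid), total, p))
    grid$g_count <- g
    grid$total_count <- total
    grid[!is.na(grid$g_count), , drop = FALSE]
  })
}

#' Simulate a complete synthetic editing study
#'
#' Builds a coherent dataset: one gene locus per editing site, each with a
#' planted dsRNA duplex containing the site; cis variants per gene, one of
#' which is causal (with effect recycled from `config$effect_sizes`) and is
#' placed either inside the planted stem (disrupting) or in the flanks
#' (distal) according to `disrupt_fraction`; strain genotypes; editing
#' levels with the planted effects; and per-replicate read counts. Every
#' locus sits on its own contig named by its gene.
#'
#' @param config A [sim_config()].
#' @return An object of class `edscape_sim`: list with `config`, `genome`
#'   (named character vector of contig sequences), `sites` (data frame),
#'   `genotypes`, `levels`, `counts` and `truth` (qtl_assignments,
#'   duplex_specs, disrupting_variants, baselines).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_sites <- config$n_sites
  gene_ids <- sprintf("g%03d", seq_len(n_sites))
  site_ids <- sprintf("s%03d", seq_len(n_sites))
  effects <- rep_len(config$effect_sizes, n_sites)

  loci <- vector("list", n_sites)
  with_seed(config$seed + 404L, {
    stem_lens <- sample(seq(config$stem_length_range[1],
                            config$stem_length_range[2]), n_sites, replace = TRUE)
    n_bulges <- if (config$max_planted_bulge > 0L)
      sample(0:2, n_sites, replace = TRUE) else rep(0L, n_sites)
    locus_seeds <- sample.int(2^30, n_sites)
    disrupting <- stats::runif(n_sites) < config$disrupt_fraction
  })
  for (i in seq_len(n_sites)) {
    bulges <- NULL
    if (n_bulges[i] > 0L) {
      bulges <- with_seed(locus_seeds[i] + 7L, data.frame(
        after_pair = sample(seq(3L, stem_lens[i] - 3L), n_bulges[i]),
        size = sample(seq_len(config$max_planted_bulge), n_bulges[i],
                      replace = TRUE),
        side = sample(c("ecs", "edit"), n_bulges[i], replace = TRUE),
        stringsAsFactors = FALSE))
    }
    loci[[i]] <- generate_duplex_locus(
      list(stem_len = stem_lens[i], bulges = bulges,
           ecs_offset = with_seed(locus_seeds[i] + 8L,
                                  sample(seq(config$ecs_offset_range[1],
                                             config$ecs_offset_range[2]), 1L)),
           flank = rep(config$flank_length, 2L)),
      seed = locus_seeds[i])
  }
  genome <- vapply(loci, `[[`, character(1), "sequence")
  names(genome) <- gene_ids

  sites <- data.frame(
    chrom = gene_ids,
    pos = vapply(loci, `[[`, numeric(1), "site_pos"),
    strand = "+", gene_id = gene_ids, site_id = site_ids,
    stringsAsFactors = FALSE)

  # variants: one causal per gene plus background variants
  nv <- config$n_variants_per_gene
  var_rows <- list()
  with_seed(config$seed + 505L, {
    for (i in seq_len(n_sites)) {
      loc <- loci[[i]]
      len <- nchar(loc$sequence)
      stem_pos <- c(seq2(loc$stem5[1], loc$stem5[2]),
                    seq2(loc$stem3[1], loc$stem3[2]))
      flank_pos <- setdiff(seq_len(len),
                           seq2(loc$stem5[1] - 10L, loc$stem3[2] + 10L))
      causal_pos <- if (disrupting[i]) {
        cand <- setdiff(stem_pos, loc$site_pos)
        cand[sample.int(length(cand), 1L)]
      } else flank_pos[sample.int(length(flank_pos), 1L)]
      other_pos <- sample(setdiff(flank_pos, causal_pos), nv - 1L)
      pos <- c(causal_pos, other_pos)
      ref <- substring(loc$sequence, pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
      var_rows[[i]] <- data.frame(
        variant_id = sprintf("v%03d_%02d", i, seq_len(nv)),
        chrom = gene_ids[i], pos = pos, gene_id = gene_ids[i],
        ref = ref, alt = unname(alt), causal = c(TRUE, rep(FALSE, nv - 1L)),
        stringsAsFactors = FALSE)
    }
  })
  variants <- do.call(rbind, var_rows)
  genotypes <- with_seed(config$seed + 606L, {
    maf <- stats::runif(nrow(variants), config$maf_range[1], config$maf_range[2])
    calls <- matrix(stats::rbinom(nrow(variants) * config$n_strains, 1L,
                                  rep(maf, config$n_strains)),
                    nrow = nrow(variants))
    genotype_matrix(variants[, c("variant_id", "chrom", "pos", "gene_id",
                                 "ref", "alt")],
                    calls, sprintf("strain%03d", seq_len(config$n_strains)))
  })

  # the disrupted (alternate) allele of a stem variant loses pairing and
  # with it editing, so planted within-duplex effects point downward
  qtl_assignments <- data.frame(
    variant_id = variants$variant_id[variants$causal],
    site_id = site_ids,
    effect = ifelse(disrupting, -abs(effects), effects),
    stringsAsFactors = FALSE)
  qtl_assignments <- qtl_assignments[qtl_assignments$effect != 0, , drop = FALSE]

  duplex_specs <- data.frame(
    site_id = site_ids, gene_id = gene_ids,
    stem_len = stem_lens,
    max_planted_bulge = vapply(loci, function(l)
      if (nrow(l$spec$bulges)) max(l$spec$bulges$size) else 0L, numeric(1)),
    ecs_offset = vapply(loci, function(l) l$spec$ecs_offset, numeric(1)),
    stem5_start = vapply(loci, function(l) l$stem5[1], numeric(1)),
    stem5_end = vapply(loci, function(l) l$stem5[2], numeric(1)),
    ecs_start = vapply(loci, function(l) l$ecs[1], numeric(1)),
    ecs_end = vapply(loci, function(l) l$ecs[2], numeric(1)),
    intronic = FALSE, stringsAsFactors = FALSE)

  truth <- list(qtl_assignments = qtl_assignments,
                duplex_specs = duplex_specs,
                disrupting_variants = variants$variant_id[variants$causal][disrupting])

  levels <- generate_editing_levels(genotypes, truth, config,
                                    site_ids = site_ids)
  levels$sites <- sites # genomic coordinates, not placeholders
  counts <- generate_read_counts(levels, config)

  structure(list(config = config, genome = genome, sites = sites,
                 genotypes = genotypes, levels = levels, counts = counts,
                 truth = truth),
            class = "edscape_sim")
}

#' @export
print.edscape_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic editing study: %d sites / %d strains / %d replicates, ",
    "%d variants (%d planted edQTLs, %d stem-disrupting)\n"),
    nrow(x$sites), x$config$n_strains, x$config$n_replicates,
    nrow(x$genotypes$variants), nrow(x$truth$qtl_assignments),
    length(x$truth$disrupting_variants)))
  invisible(x)
}
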