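# small deterministic FNV-1a style hash of the pipeline parameters,
# echoed in every output header for provenance
config_hash <- function(params) {
  txt <- paste(deparse(params[order(names(params))]), collapse = "")
  h <- 2166136261 %% 2^30
  for (v in utf8ToInt(txt)) h <- (bitwXor(as.integer(h), v) * 16777619) %% 2^30
  sprintf("%08x", as.integer(h))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full editing cis-regulation pipeline on a dataset directory
#'
#' Executes the stages in order -- quantify (count table to filtered
#' editing matrix), map-qtl (permutation-calibrated edQTL scan),
#' predict-ecs (proximal ECS per mapped site), qtl-structure (duplex
#' classification and allelic free-energy comparison of significant
#' edQTLs) and distal-stems (secondary stems around distal edQTLs) -- on
#' the files produced by [write_dataset()] (or equivalently formatted
#' inputs): `counts.tsv`, `sites.bed`, `genotypes.vcf`, `genome.fa`.
#' Every output TSV carries a header line with the parameter hash and
#' seed; a rerun with the same inputs and seed is byte-identical.
#'
#' @param input_dir Directory with the input files.
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations per site (default 1000 at desk scale).
#' @param seed Integer seed.
#' @param fdr FDR thresholds (default `c(0.05, 0.10)`).
#' @param min_strains Minimum measured strains per site (default 35).
#' @param min_coverage Per-replicate coverage floor (default 50).
#' @param window Folding half-window for ECS prediction (default 200 bp).
#' @param min_pairs,max_bulge Stem cutoffs (defaults 20 bp / 8 nt).
#' @return Invisibly, a list with the in-memory stage results
#'   (`editing`, `fit`, `predictions`, `comparisons`, `distal_stems`) and
#'   the output paths.
#' @export
run_pipeline <- function(input_dir, out_dir, n_perm = 1000L, seed = 1L,
                         fdr = c(0.05, 0.10), min_strains = 35L,
                         min_coverage = 50L, window = 200L,
                         min_pairs = 20L, max_bulge = 8L) {
  params <- list(n_perm = n_perm, seed = seed, fdr = fdr,
                 min_strains = min_strains, min_coverage = min_coverage,
                 window = window, min_pairs = min_pairs,
                 max_bulge = max_bulge)
  for (f in c("counts.tsv", "sites.bed", "genotypes.vcf", "genome.fa")) {
    if (!file.exists(file.path(input_dir, f)))
      stop("missing input file: ", f)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(params)
  hdr <- c(sprintf("edscape run: config=%s seed=%d", hash, seed),
           sprintf("params: %s", paste(names(params), unlist(lapply(
             params, paste, collapse = ",")), sep = "=", collapse = " ")))

  sites <- stage("quantify", read_sites_bed(file.path(input_dir, "sites.bed")))
  counts <- stage("quantify", read_counts_tsv(file.path(input_dir, "counts.tsv")))
  editing <- stage("quantify", build_editing_matrix(
    counts, sites = sites, min_strains = min_strains,
    min_coverage = min_coverage))
  write_editing_tsv(editing, file.path(out_dir, "editing_matrix.tsv"),
                    header_lines = hdr)
  message(sprintf("quantify: %d/%d sites retained across %d strains",
                  nrow(editing$level), length(unique(counts$site_id)),
                  length(editing$strains)))

  genotypes <- stage("map-qtl",
                     read_vcf_genotypes(file.path(input_dir, "genotypes.vcf")))
  fit <- stage("map-qtl", edqtl_map(editing, genotypes, n_perm = n_perm,
                                    seed = seed, fdr = fdr))
  tab <- fit$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) round(x, 8))
  con <- file(file.path(out_dir, "edqtl.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message(sprintf("map-qtl: %d sites mapped, %d edQTLs at FDR %d%%",
                  sum(fit$table$rank == "primary"),
                  sum(fit$table[[sprintf("sig_fdr%02d", round(100 * max(fdr)))]]),
                  round(100 * max(fdr))))

  genome <- stage("predict-ecs",
                  read_genome_fasta(file.path(input_dir, "genome.fa")))
  predictions <- stage("predict-ecs", {
    out <- list()
    for (i in seq_len(nrow(editing$sites))) {
      s <- editing$sites[i, , drop = FALSE]
      out[[s$site_id]] <- predict_proximal_ecs(
        s, genome, window = window, min_pairs = min_pairs,
        max_bulge = max_bulge)
    }
    out
  })
  pred_tab <- do.call(rbind, lapply(names(predictions), function(sid) {
    p <- predictions[[sid]]
    if (is.null(p)) {
      data.frame(site_id = sid, accepted = FALSE, ecs_start = NA_integer_,
                 ecs_end = NA_integer_, n_pairs = NA_integer_,
                 max_bulge = NA_integer_, distance = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(site_id = sid, accepted = TRUE,
                 ecs_start = p$ecs_interval[1], ecs_end = p$ecs_interval[2],
                 n_pairs = p$stem$n_pairs, max_bulge = p$stem$max_bulge,
                 distance = p$distance, stringsAsFactors = FALSE)
    }
  }))
  con <- file(file.path(out_dir, "ecs_predictions.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(pred_tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  message(sprintf("predict-ecs: ECS found for %d/%d sites",
                  sum(pred_tab$accepted), nrow(pred_tab)))

  sig_col <- sprintf("sig_fdr%02d", round(100 * max(fdr)))
  sig <- fit$table[fit$table[[sig_col]], , drop = FALSE]
  common <- intersect(editing$strains, genotypes$strains)
  comparisons <- stage("qtl-structure", {
    out <- list()
    for (r in seq_len(nrow(sig))) {
      sid <- sig$site_id[r]
      pred <- predictions[[sid]]
      vrow <- match(sig$variant_id[r], genotypes$variants$variant_id)
      variant <- genotypes$variants[vrow, , drop = FALSE]
      cls <- classify_variant_location(variant, pred)
      rec <- list(variant_id = variant$variant_id, site_id = sid,
                  location_class = cls, is_base_paired = NA,
                  delta_g = NA_real_, signed_position = NA_integer_,
                  effect_size = sig$effect_size[r], gated = NA)
      if (identical(cls, "within_duplex")) {
        cmp <- compare_alleles(variant, pred, genome,
                               editing$level[sid, common],
                               genotypes$calls[vrow, common])
        rec[c("is_base_paired", "delta_g", "signed_position", "gated")] <-
          cmp[c("is_base_paired", "delta_g", "signed_position", "gated")]
      }
      out[[length(out) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(variant_id = character(0), site_id = character(0),
                 location_class = character(0), is_base_paired = logical(0),
                 delta_g = numeric(0), signed_position = integer(0),
                 effect_size = numeric(0), gated = logical(0))
  })
  con <- file(file.path(out_dir, "structural_comparisons.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(comparisons, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  distal <- comparisons[comparisons$location_class == "distal", , drop = FALSE]
  distal_stems <- stage("distal-stems", {
    out <- list()
    for (r in seq_len(nrow(distal))) {
      vrow <- match(distal$variant_id[r], genotypes$variants$variant_id)
      variant <- genotypes$variants[vrow, , drop = FALSE]
      spos <- editing$sites$pos[editing$sites$site_id == distal$site_id[r]]
      stems <- find_distal_stems(variant, genome, window = window,
                                 min_pairs = min_pairs,
                                 max_bulge = max_bulge,
                                 site_pos = spos[1])
      for (st in stems)
        out[[length(out) + 1L]] <- data.frame(
          variant_id = st$variant_id, site_id = distal$site_id[r],
          n_pairs = st$stem$n_pairs, max_bulge = st$stem$max_bulge,
          span_start = st$genomic_span[1], span_end = st$genomic_span[2],
          distance_to_site = st$distance_to_editing_site,
          stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(variant_id = character(0), site_id = character(0),
                 n_pairs = integer(0), max_bulge = integer(0),
                 span_start = integer(0), span_end = integer(0),
                 distance_to_site = numeric(0))
  })
  con <- file(file.path(out_dir, "secondary_stems.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(distal_stems, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  message(sprintf("qtl-structure: %d within-duplex, %d distal; distal-stems: %d stems",
                  sum(comparisons$location_class == "within_duplex"),
                  nrow(distal), nrow(distal_stems)))

  jsonlite::write_json(
    list(config = hash, seed = seed, params = params,
         n_sites = nrow(editing$level),
         n_edqtl = sum(fit$table[[sig_col]]),
         n_ecs = sum(pred_tab$accepted)),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(editing = editing, fit = fit, predictions = predictions,
                 comparisons = comparisons, distal_stems = distal_stems,
                 out_dir = out_dir))
}
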