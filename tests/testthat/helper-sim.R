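# shared fixture builders (all generated in code, seeded)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# minimal accepted ECS-prediction stub for interval-based operations
mock_prediction <- function(chrom, site_pos, ecs_interval,
                            edit_interval = NULL, strand = "+") {
  structure(list(
    site = list(chrom = chrom, pos = site_pos, strand = strand,
                site_id = paste0(chrom, "_site")),
    approach = "proximal", stem = NULL, structure = NULL,
    window = c(1L, 10000L),
    ecs_interval = as.integer(ecs_interval),
    edit_interval = as.integer(
      if (is.null(edit_interval)) c(site_pos - 5L, site_pos + 5L)
      else edit_interval),
    distance = NA_integer_, accepted = TRUE,
    cutoffs = c(min_pairs = 20L, max_bulge = 8L)), class = "ecs_prediction")
}

# replicate count table for one site measured in `n_strains` strains
counts_for_site <- function(site_id, n_strains, level = 0.4, coverage = 100,
                            n_rep = 2) {
  grid <- expand.grid(strain = sprintf("st%03d", seq_len(n_strains)),
                      replicate = seq_len(n_rep),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(site_id = site_id, strain = grid$strain,
             replicate = grid$replicate,
             g_count = round(level * coverage), total_count = coverage,
             stringsAsFactors = FALSE)
}

# genotype matrix built directly from a call matrix
gm_from_calls <- function(calls, gene_id = "g001", pos = NULL) {
  nv <- nrow(calls)
  variants <- data.frame(
    variant_id = sprintf("v%02d", seq_len(nv)), chrom = gene_id,
    pos = if (is.null(pos)) 10L * seq_len(nv) else pos,
    gene_id = gene_id, ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(variants, calls, sprintf("st%03d", seq_len(ncol(calls))))
}

# editing matrix for given level matrix (sites x strains)
em_from_levels <- function(lev, gene_id = "g001", pos = NULL) {
  sites <- data.frame(
    chrom = gene_id,
    pos = if (is.null(pos)) 100L * seq_len(nrow(lev)) else pos,
    strand = "+", gene_id = gene_id,
    site_id = sprintf("s%02d", seq_len(nrow(lev))), stringsAsFactors = FALSE)
  editing_matrix(sites, sprintf("st%03d", seq_len(ncol(lev))), lev)
}

# contig with a planted distal (intron-like) ECS: the editing-side stem
# strand sits at `site_offset`, its reverse complement `gap` bp further
# downstream, separated by unpairable poly-A spacers and low-complement
# random filler; the conservation track is 1.0 exactly over the ECS.
plant_distal_locus <- function(stem_len = 25, gap = 1500, seed = 1) {
  set.seed(seed)
  pair_bases <- sample(c("A", "C", "G", "T"), stem_len, TRUE)
  site_pair <- ceiling(stem_len / 2)
  pair_bases[site_pair] <- "A"
  edit_strand <- paste(pair_bases, collapse = "")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ecs_strand <- paste(rev(unname(comp[pair_bases])), collapse = "")
  left <- rand_dna(100)
  mid <- rand_dna(gap - 20L)
  right <- rand_dna(100)
  seqs <- paste0(left, edit_strand, strrep("A", 10), mid, strrep("A", 10),
                 ecs_strand, right)
  ecs_start <- nchar(left) + stem_len + 10L + nchar(mid) + 10L + 1L
  track <- numeric(nchar(seqs))
  # conserved block comfortably wider than the 51-nt smoothing window,
  # so the smoothed score stays >= 0.9 across the ECS
  track[max(1L, ecs_start - 45L):min(nchar(seqs), ecs_start + stem_len + 44L)] <- 1
  list(sequence = seqs,
       site_pos = nchar(left) + site_pair,
       ecs = c(ecs_start, ecs_start + stem_len - 1L),
       track = track)
}
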