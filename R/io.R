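#' Read a haploid-coded genotype matrix from a VCF
#'
#' Keeps biallelic SNVs only; multi-allelic and indel records are skipped
#' (counts logged as a message). For inbred lines, GT `0/0` maps to 0,
#' `1/1` to 1, and heterozygous or missing calls to NA. A `GENE=` INFO
#' key, when present, provides the gene assignment; otherwise the
#' chromosome name is used (one-locus-per-contig convention).
#'
#' @param path VCF file (v4.x, GT format field required).
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped) message(n_skipped, " non-SNV or multi-allelic records skipped")
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv, , drop = FALSE]
  gene <- sub("^.*GENE=([^;]+).*$", "\\1", fix$INFO)
  gene[!grepl("GENE=", fix$INFO)] <- fix$CHROM[!grepl("GENE=", fix$INFO)]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% c("0/0", "0")] <- 0L
  code[norm %in% c("1/1", "1")] <- 1L
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS), gene_id = gene,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(variants, code, colnames(gt))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Haploid-coded calls are written as inbred-style homozygous diploid
#' genotypes (`0/0` / `1/1`; missing as `./.`), with the gene assignment
#' in a `GENE=` INFO key.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  gt <- genotypes$calls
  body <- matrix("./.", nrow(gt), ncol(gt))
  body[!is.na(gt) & gt == 0L] <- "0/0"
  body[!is.na(gt) & gt == 1L] <- "1/1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=edscape",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene assignment\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$strains), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i)
      paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
              ".", "PASS", paste0("GENE=", v$gene_id[i]), "GT", body[i, ]),
            collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read editing sites from a BED6 file
#'
#' Sites are single bases: `end - start` must be 1. BED's 0-based
#' half-open coordinates become the internal 1-based position
#' (`start + 1`); the strand column is required. The BED name field is
#' the site ID; the gene is taken from the chromosome name unless a
#' `gene_map` is provided.
#'
#' @param path BED6 file.
#' @param gene_map Optional named character vector site_id -> gene_id.
#' @return Data frame (chrom, pos, strand, gene_id, site_id).
#' @export
read_sites_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:6])
  if (ncol(raw) < 6L) stop("BED6 required: missing strand column")
  if (any(!raw$strand %in% c("+", "-"))) stop("BED strand must be + or -")
  if (any(raw$start >= raw$end)) stop("BED interval with start >= end")
  if (any(raw$end - raw$start != 1L))
    stop("editing sites must be single bases (end - start == 1)")
  data.frame(chrom = raw$chrom, pos = raw$start + 1L, strand = raw$strand,
             gene_id = raw$chrom, site_id = raw$name,
             stringsAsFactors = FALSE)
}

#' @rdname read_sites_bed
#' @param sites Data frame with chrom, pos, strand, site_id.
#' @export
write_sites_bed <- function(sites, path) {
  utils::write.table(
    data.frame(sites$chrom, sites$pos - 1L, sites$pos, sites$site_id, 0L,
               sites$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write the replicate count table
#'
#' TSV with columns site_id, strain, replicate, g_count, total_count.
#'
#' @param path File path.
#' @return `read_counts_tsv()` returns the data frame.
#' @export
read_counts_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_counts_tsv
#' @param counts The count table data frame.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @export
write_counts_tsv <- function(counts, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write an editing matrix as TSV
#'
#' Long-format TSV (site_id, chrom, pos, strand, gene_id, strain, level)
#' with 1-based coordinates; levels are written to 6 decimals.
#'
#' @param path File path.
#' @return `read_editing_tsv()` returns an `editing_matrix`.
#' @export
read_editing_tsv <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
  sites <- unique(long[, c("chrom", "pos", "strand", "gene_id", "site_id")])
  strains <- sort(unique(long$strain))
  lev <- matrix(NA_real_, nrow(sites), length(strains),
                dimnames = list(sites$site_id, strains))
  lev[cbind(long$site_id, long$strain)] <- long$level
  editing_matrix(sites, strains, lev)
}

#' @rdname read_editing_tsv
#' @param matrix An `editing_matrix`.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @export
write_editing_tsv <- function(matrix, path, header_lines = character(0)) {
  stopifnot(inherits(matrix, "editing_matrix"))
  lv <- matrix$level
  long <- expand.grid(site_id = rownames(lv), strain = colnames(lv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$level <- round(lv[cbind(long$site_id, long$strain)], 6)
  long <- long[!is.na(long$level), , drop = FALSE]
  ann <- matrix$sites[match(long$site_id, matrix$sites$site_id),
                      c("chrom", "pos", "strand", "gene_id")]
  out <- cbind(long["site_id"], ann, long[c("strain", "level")])
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genome FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a plain named
#' character vector of contig sequences.
#'
#' @param path File path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of contig sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a conservation track (bedGraph or fixed-step wiggle)
#'
#' Returns per-base scores for each contig. bedGraph intervals are
#' 0-based half-open; fixedStep wiggle declarations use 1-based starts.
#'
#' @param path Track file.
#' @param contig_lengths Named integer vector giving each contig's length
#'   (uncovered positions are 0).
#' @return Named list of per-base numeric vectors.
#' @export
read_conservation <- function(path, contig_lengths) {
  first <- readLines(path, n = 5L)
  fmt <- if (any(grepl("^(fixedStep|variableStep)", first))) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  out <- lapply(contig_lengths, function(n) numeric(n))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  scores <- gr$score
  for (i in seq_along(scores)) {
    chrom <- chroms[i]
    if (!chrom %in% names(out)) next
    a <- starts[i]
    b <- min(ends[i], length(out[[chrom]]))
    if (a <= b) out[[chrom]][a:b] <- scores[i]
  }
  out
}

#' @rdname read_conservation
#' @param track Named list of per-base numeric vectors.
#' @export
write_conservation_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read gene or intron intervals from GFF3
#'
#' @param path GFF3 file.
#' @param feature Feature type to keep (e.g. "gene", "intron"); NULL keeps
#'   all records.
#' @return Data frame (gene_id, chrom, start, end, strand), 1-based
#'   inclusive coordinates.
#' @export
read_genes_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature)) gr <- gr[gr$type %in% feature]
  ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the components of an [simulate_dataset()] result as the
#' external formats the pipeline readers consume: `genotypes.vcf`,
#' `genome.fa`, `sites.bed`, `counts.tsv`, `levels.tsv` and `truth.json`.
#' Reading the files back reproduces the in-memory objects.
#'
#' @param sim An `edscape_sim`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "edscape_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_sites_bed(sim$sites, file.path(dir, "sites.bed"))
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_editing_tsv(sim$levels, file.path(dir, "levels.tsv"))
  jsonlite::write_json(
    list(qtl_assignments = sim$truth$qtl_assignments,
         duplex_specs = sim$truth$duplex_specs,
         disrupting_variants = sim$truth$disrupting_variants,
         seed = sim$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
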